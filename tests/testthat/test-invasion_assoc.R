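test_that("invasion group stats match hand ANOVA and handle degenerate groups", {
  p <- invasion_profile(sprintf("c%d", 1:6), c(1, 2, 3, 4, 5, 6),
                        rep(c("g1", "g2"), each = 3))
  st <- invasion_group_stats(p)
  expect_equal(st$F, 13.5)  # between SS 13.5 (df 1), within MS 1 (df 4)
  expect_equal(st$df, c(1, 4))
  expect_equal(st$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(sum(st$deviations$deviation), 0)

  same <- invasion_profile(sprintf("c%d", 1:6), c(1, 2, 3, 1, 2, 3),
                           rep(c("g1", "g2"), each = 3))
  st2 <- invasion_group_stats(same)
  expect_equal(st2$F, 0)
  expect_equal(st2$p, 1)

  single <- invasion_profile(sprintf("c%d", 1:3), c(1, 2, 3), rep("g1", 3))
  expect_error(invasion_group_stats(single), ">= 2 groups")

  # size-1 group excluded with warning, remaining groups analysed
  p3 <- invasion_profile(sprintf("c%d", 1:7), c(1, 2, 3, 4, 5, 6, 99),
                         c("g1", "g1", "g1", "g2", "g2", "g2", "g3"))
  expect_warning(st3 <- invasion_group_stats(p3), "size 1")
  expect_equal(st3$F, 13.5)
})

test_that("invasion group stats agree with the ANOVA oracle on random data", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    ni <- sample(2:8, k, replace = TRUE)
    g <- rep(sprintf("g%d", seq_len(k)), ni)
    v <- abs(rnorm(length(g), 500, 200))
    st <- invasion_group_stats(invasion_profile(seq_along(g), v, g))
    orc <- anova_oracle(v, g)
    expect_equal(st$F, orc$F, tolerance = 1e-10)
    expect_equal(st$p, orc$p, tolerance = 1e-10)
  }
})

test_that("correlate_profile handles exact, derived and degenerate cases", {
  y <- c(1, 3, 2, 4)
  ex <- tiny_expr(rbind(y, c(1, 2, 3, 4), c(7, 7, 7, 7)), samples = sprintf("S%d", 1:4))
  out <- correlate_profile(ex, setNames(y, sprintf("S%d", 1:4)), transform = FALSE)
  expect_equal(nrow(out), 2)  # constant probe dropped
  expect_equal(out$r[out$item_id == "P1"], 1)
  expect_equal(out$r[out$item_id == "P2"], 0.8)  # covariance 4 / sqrt(5*5)
  expect_equal(out$n_used, c(4, 4))
})

test_that("correlate_profile matches the brute-force Pearson oracle", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    X <- matrix(rnorm(3 * n), 3, n)
    if (i %% 3 == 0) X[1, sample(n, 2)] <- NA  # exercise pairwise-complete
    y <- rnorm(n)
    ex <- tiny_expr(X)
    out <- correlate_profile(ex, y, transform = FALSE)
    for (j in seq_len(nrow(out))) {
      row <- which(sprintf("P%d", 1:3) == out$item_id[j])
      orc <- pearson_oracle(X[row, ], y)
      expect_equal(out$r[j], orc$r, tolerance = 1e-12)
      expect_equal(out$p_two_sided[j], orc$p, tolerance = 1e-12)
      expect_equal(out$n_used[j], orc$n)
    }
  }
})

test_that("FDR estimator reproduces the two-stage formula", {
  est <- estimate_confirmation_fdr(2417, 0.025, 744)
  expect_equal(est$fdr, 2417 * 0.025 / 744)
  expect_equal(round(est$fdr, 2), 0.08)
  expect_true(is.na(estimate_confirmation_fdr(100, 0.025, 0)$fdr))
})

make_records <- function(ids, r, p) {
  data.frame(item_id = ids, r = r, p_two_sided = p, n_used = 53,
             stringsAsFactors = FALSE)
}

test_that("two-stage selection applies threshold, sign and best-partner rules", {
  pairs <- data.frame(probe_a = c("a1", "a2", "a3", "a3"),
                      probe_b = c("b1", "b2", "b3", "b4"),
                      gene_symbol = c("G1", "G2", "G3", "G3"),
                      stringsAsFactors = FALSE)
  disc <- make_records(c("a1", "a2", "a3"), c(0.5, 0.6, 0.4),
                       c(0.001, 0.001, 0.001))
  conf <- make_records(c("b1", "b2", "b3", "b4"), c(0.45, -0.5, 0.3, 0.6),
                       c(0.01, 0.01, 0.04, 0.001))
  res <- two_stage_ia_selection(disc, conf, pairs, p_disc = 0.05, p_conf = 0.025)
  tb <- res$table
  # a1: retained (same sign, p_conf 0.01 < 2*0.025)
  expect_true("a1" %in% tb$probe_discovery)
  # a2: rejected on the sign rule despite small p
  expect_false("a2" %in% tb$probe_discovery)
  # a3: best same-sign partner is b4 (|r| = 0.6)
  expect_equal(tb$probe_confirm[tb$probe_discovery == "a3"], "b4")
  expect_equal(res$fdr$m_confirm_tested, 3L)
  expect_equal(res$fdr$k_passed, 2L)
  expect_equal(res$fdr$fdr, 3 * 0.025 / 2)
  expect_true(all(tb$direction == sign(tb$r_discovery)))
  expect_true(all(tb$direction == sign(tb$r_confirm)))

  # stage-1 threshold: p_discovery filtered out
  disc2 <- make_records("a1", 0.5, 0.2)
  res2 <- two_stage_ia_selection(disc2, conf, pairs)
  expect_equal(nrow(res2$table), 0)
  expect_true(is.na(res2$fdr$fdr))
})

test_that("tightening either threshold never enlarges the IA set", {
  set.seed(21)
  sim <- simulate_cell_line_panel(n_lines = 40, n_probes_a = 300,
                                  n_probes_b = 300, n_planted = 30,
                                  effect_r = 0.5, seed = 77)
  icc <- setNames(sim$invasion$icc, sim$invasion$cell_line)
  rd <- correlate_profile(sim$expr_a, icc)
  rc <- correlate_profile(sim$expr_b, icc)
  pairs <- match_probes(sim$expr_a, sim$expr_b, sim$probe_map)
  base <- two_stage_ia_selection(rd, rc, pairs, 0.05, 0.025)
  for (pd in c(0.01, 0.03)) {
    tight <- two_stage_ia_selection(rd, rc, pairs, pd, 0.025)
    expect_true(all(tight$table$probe_discovery %in% base$table$probe_discovery))
  }
  for (pc in c(0.005, 0.015)) {
    tight <- two_stage_ia_selection(rd, rc, pairs, 0.05, pc)
    expect_true(all(tight$table$probe_discovery %in% base$table$probe_discovery))
  }
})

test_that("partition_by_sign splits, conserves and orders", {
  tb <- fake_ia_table(c(1, -1, 1))
  pp <- partition_by_sign(tb)
  expect_equal(nrow(pp$negative), 1)
  expect_equal(nrow(pp$positive), 2)

  allpos <- partition_by_sign(fake_ia_table(c(1, 1)))
  expect_equal(nrow(allpos$negative), 0)

  set.seed(9)
  for (i in 1:10) {
    dirs <- sample(c(-1, 1), sample(3:40, 1), replace = TRUE)
    pp <- partition_by_sign(fake_ia_table(dirs, r_abs = runif(length(dirs), 0.2, 0.9)))
    expect_equal(nrow(pp$negative) + nrow(pp$positive), length(dirs))
    expect_false(any(pp$negative$probe_discovery %in% pp$positive$probe_discovery))
    expect_false(is.unsorted(rev(abs(pp$positive$r_discovery))))
  }
  expect_error(partition_by_sign(fake_ia_table(numeric())), "empty")
})
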