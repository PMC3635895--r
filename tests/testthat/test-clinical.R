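test_that("compare_groups matches the Welch oracle and degenerate cases", {
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)

  set.seed(31)
  sep <- compare_groups(c(rnorm(4, 0, 1e-3), rnorm(4, 1, 1e-3)),
                        rep(c("a", "b"), each = 4))
  expect_lt(sep$p_two_sided, 0.01)

  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    got <- compare_groups(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
    orc <- welch_oracle(x, y)
    expect_equal(got$t_statistic, orc$t, tolerance = 1e-10)
    expect_equal(got$df, orc$df, tolerance = 1e-10)
    expect_equal(got$p_two_sided, orc$p, tolerance = 1e-10)
  }
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("overlap removal re-tests on the reduced panel", {
  set.seed(32)
  rs <- data.frame(sample_id = sprintf("s%d", 1:12),
                   score = rnorm(12), group = "low", stringsAsFactors = FALSE)
  lab <- rep(c("sens", "res"), each = 6)
  base <- compare_groups(rs, lab)
  keep_all <- remove_overlap_and_retest(rs, lab, character())
  expect_equal(keep_all$t_statistic, base$t_statistic)
  red <- remove_overlap_and_retest(rs, lab, c("s1", "s7"))
  expect_equal(red$n, c(5, 5))
  expect_equal(attr(red, "removed"), c("s1", "s7"))
  expect_error(remove_overlap_and_retest(rs, lab, sprintf("s%d", 1:5)), ">= 2")
})

test_that("KM estimate matches hand product-limit and empirical survival", {
  ch <- cohort_table(data.frame(patient_id = c("p1", "p2", "p3"),
                                time = c(1, 2, 3), event = c(1, 1, 1)))
  rep1 <- km_logrank(ch, rep("all", 3))
  expect_equal(rep1$km$survival, c(2/3, 1/3, 0))
  expect_equal(rep1$km$n_risk, c(3, 2, 1))

  # no censoring: KM == empirical survival function (random instances)
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    tt <- sample(1:50, n, replace = TRUE)
    ch <- cohort_table(data.frame(patient_id = seq_len(n), time = tt,
                                  event = rep(1, n)))
    got <- km_logrank(ch, rep("g", n))$km
    orc <- km_oracle(tt, rep(1, n))
    expect_equal(got$survival, orc$survival, tolerance = 1e-12)
    ecdf_surv <- vapply(orc$time, function(t) mean(tt > t), numeric(1))
    expect_equal(orc$survival, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("log-rank matches the hypergeometric O-E/V oracle", {
  # identical groups -> chi-square 0
  ch <- cohort_table(data.frame(patient_id = sprintf("p%d", 1:6),
                                time = rep(c(1, 2, 3), 2),
                                event = rep(1, 6)))
  expect_equal(km_logrank(ch, rep(c("a", "b"), 3))$logrank_chi2, 0,
               tolerance = 1e-12)

  set.seed(34)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    tt <- runif(n, 0.1, 20) + rep(c(0, 1.5), length.out = n)
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) next
    g <- rep(c("a", "b"), length.out = n)
    if (min(table(g[ev == 1])) < 1) next
    ch <- cohort_table(data.frame(patient_id = seq_len(n), time = tt, event = ev))
    got <- suppressWarnings(km_logrank(ch, g))
    orc <- logrank_oracle(tt, ev, g)
    expect_equal(got$logrank_chi2, orc$chi2, tolerance = 1e-10)
    expect_equal(got$logrank_p, orc$p, tolerance = 1e-10)
  }
})

test_that("log-rank p is uniform under permuted labels", {
  set.seed(35)
  n <- 40
  tt <- rexp(n, 0.05)
  ev <- rbinom(n, 1, 0.8)
  ch <- cohort_table(data.frame(patient_id = seq_len(n), time = tt, event = ev))
  ps <- replicate(400, {
    g <- sample(rep(c("a", "b"), each = n / 2))
    suppressWarnings(km_logrank(ch, g)$logrank_p)
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox regression matches the grid oracle and recovers planted effects", {
  # 4-subject worked example, single covariate, no ties
  tt <- c(2, 4, 6, 9); ev <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  ch <- cohort_table(data.frame(patient_id = 1:4, time = tt, event = ev, x = x))
  expect_error(cox_multivariate(ch, "x"), "too few events")  # default guard
  fit <- cox_multivariate(ch, "x", guard = FALSE)
  expect_equal(fit$coefficients$coef[1], cox_grid_oracle(tt, ev, x),
               tolerance = 1e-4)

  # planted continuous effect recovered within +-0.1
  ch2 <- simulate_survival_cohort(2000, log(2), censoring_rate = 0.25, seed = 91)
  genes <- attr(ch2, "gene_cols")
  X <- t(as.matrix(as.data.frame(ch2)[, genes])); colnames(X) <- ch2$patient_id
  rs <- compute_risk_score(X, genes)
  ch2$zscore <- as.numeric(scale(rs$score))
  fit2 <- cox_multivariate(ch2, c("zscore", "age", "stage"))
  b <- fit2$coefficients
  expect_false(fit2$flagged)
  expect_equal(b$coef[b$variable == "zscore"], log(2), tolerance = 0.1)
  expect_equal(b$hr, exp(b$coef), tolerance = 1e-10)
  # null covariates stay null-ish
  expect_gt(b$p[b$variable == "age"], 0.001)

  # null binary covariate: coefficient ~ 0
  ch3 <- simulate_survival_cohort(400, 0, censoring_rate = 0.2, seed = 92)
  ch3$flag <- rep(c(0, 1), 200)
  fit3 <- cox_multivariate(ch3, "flag")
  expect_lt(abs(fit3$coefficients$coef[1]), 0.3)

  expect_error(cox_multivariate(ch3, "nope"), "unknown covariate")
  ch3$const <- 1
  expect_error(cox_multivariate(ch3, "const"), "constant")
})

test_that("Cox sign agrees with the log-rank direction for a binary covariate", {
  set.seed(36)
  for (i in 1:10) {
    ch <- simulate_survival_cohort(120, log(2.5), censoring_rate = 0.2,
                                   seed = 200 + i, dichotomize_effect = TRUE)
    genes <- attr(ch, "gene_cols")
    X <- t(as.matrix(as.data.frame(ch)[, genes])); colnames(X) <- ch$patient_id
    rs <- compute_risk_score(X, genes)
    ch$hi <- as.numeric(rs$group == "high")
    fit <- cox_multivariate(ch, "hi")
    orc <- logrank_oracle(ch$time, ch$event, factor(ch$hi, levels = c(1, 0)))
    # high-risk group has more observed events than expected -> positive beta
    expect_equal(sign(fit$coefficients$coef[1]), sign(orc$o_minus_e))
  }
})

test_that("control cohort runs isolate failures and summarise specificity", {
  treated <- simulate_survival_cohort(150, log(3), seed = 61,
                                      dichotomize_effect = TRUE)
  control <- simulate_survival_cohort(150, 0, seed = 62)
  genes <- attr(treated, "gene_cols")
  allcens <- control
  allcens$event <- 0L
  res <- control_cohort_run(list(tr = treated, ct = control, bad = allcens),
                            treated = c(TRUE, FALSE, FALSE), genes = genes)
  expect_equal(nrow(res$summary), 3)
  expect_equal(res$summary$status[3], "all observations censored")
  expect_true(is.na(res$summary$logrank_p[3]))
  expect_lt(res$summary$logrank_p[1], 0.05)

  one <- control_cohort_run(list(only = control), treated = FALSE, genes = genes)
  expect_equal(nrow(one$summary), 1)
})
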