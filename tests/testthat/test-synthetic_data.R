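test_that("cell-line panel generator is deterministic and honours counts", {
  a <- simulate_cell_line_panel(n_lines = 20, n_probes_a = 50, n_probes_b = 40,
                                n_planted = 10, effect_r = 0.5, seed = 42)
  b <- simulate_cell_line_panel(n_lines = 20, n_probes_a = 50, n_probes_b = 40,
                                n_planted = 10, effect_r = 0.5, seed = 42)
  expect_identical(a$expr_a$values, b$expr_a$values)
  expect_identical(a$expr_b$values, b$expr_b$values)
  expect_identical(a$invasion$icc, b$invasion$icc)
  expect_equal(dim(a$expr_a$values), c(50L, 20L))
  expect_equal(dim(a$expr_b$values), c(40L, 20L))
  expect_equal(nrow(a$probe_map), 40)  # 1:1 on the smaller platform
  expect_equal(nrow(a$truth$planted), 10)
  expect_true(all(a$truth$planted$sign %in% c(-1, 1)))
  expect_true(all(a$invasion$icc > 0))
  expect_equal(length(unique(a$invasion$tissue_group)), 8)

  none <- simulate_cell_line_panel(n_lines = 20, n_probes_a = 30, n_probes_b = 30,
                                   n_planted = 0, seed = 1)
  expect_equal(nrow(none$truth$planted), 0)

  expect_error(simulate_cell_line_panel(n_probes_a = 10, n_probes_b = 10,
                                        n_planted = 11), "exceeds")

  mm <- simulate_cell_line_panel(n_lines = 20, n_probes_a = 100, n_probes_b = 100,
                                 n_planted = 5, seed = 3, mm_frac = 0.1)
  expect_equal(nrow(mm$probe_map), 110)
  expect_true(any(duplicated(mm$probe_map$probe_a)))
})

test_that("planted probes recover the population correlation at large n", {
  sim <- simulate_cell_line_panel(n_lines = 500, n_probes_a = 60, n_probes_b = 60,
                                  n_planted = 25, effect_r = 0.7, seed = 101)
  z <- sim$truth$latent_invasion
  pl <- sim$truth$planted
  for (platform in c("probe_a", "probe_b")) {
    X <- if (platform == "probe_a") sim$expr_a$values else sim$expr_b$values
    r <- vapply(seq_len(nrow(pl)), function(i)
      cor(X[pl[[platform]][i], ], z), numeric(1))
    expect_true(all(abs(r - 0.7 * pl$sign) < 0.1))
  }
  # non-planted probes are null
  null_probes <- setdiff(probe_ids(sim$expr_a), pl$probe_a)
  rn <- vapply(null_probes, function(p) cor(sim$expr_a$values[p, ], z), numeric(1))
  expect_lt(max(abs(rn)), 0.2)
  # ICC is driven by the same latent
  expect_gt(cor(log(sim$invasion$icc), z), 0.9)
})

test_that("drug panel plants class-signed associations and inactive drugs", {
  sim <- simulate_cell_line_panel(n_lines = 500, n_probes_a = 40, n_probes_b = 40,
                                  n_planted = 8, effect_r = 0.6, seed = 7,
                                  n_signature = 8)
  gl <- setNames(sim$truth$planted$drug_loading, sim$truth$planted$probe_a)
  dp <- simulate_drug_panel(
    n_drugs = 106,
    class_sizes = c(tubulin_binding = 9, targeted_therapy = 8, alkylating = 30,
                    antimetabolite = 30, topoisomerase = 29),
    n_inactive = 7,
    assoc_spec = list(latent = sim$truth$latent_drug,
                      classes = list(tubulin_binding = list(sign = -1, effect_r = 0.95),
                                     targeted_therapy = list(sign = 1, effect_r = 0.95)),
                      gene_loadings = gl),
    seed = 8)
  S <- dp$panel$sensitivity
  const <- apply(S, 1, function(v) max(v) == min(v))
  expect_equal(sum(const), 7)
  expect_equal(dim(S), c(106L, 500L))
  # sample gene-drug correlations near the recorded planted population value
  tr <- dp$truth
  got <- vapply(seq_len(nrow(tr)), function(i)
    cor(sim$expr_a$values[tr$probe[i], ], S[tr$drug[i], ]), numeric(1))
  expect_true(all(abs(got - tr$pop_r) < 0.1))
  expect_true(all(tr$pop_r[grepl("targeted", tr$drug)] > 0))
  expect_true(all(tr$pop_r[grepl("tubulin", tr$drug)] < 0))

  # empty assoc: all correlations null
  dp0 <- simulate_drug_panel(n_drugs = 10, class_sizes = c(x = 10),
                             cell_lines = sim$invasion$cell_line, seed = 9)
  r0 <- apply(dp0$panel$sensitivity, 1, function(v)
    cor(v, sim$truth$latent_drug))
  expect_lt(max(abs(r0)), 0.15)
  expect_equal(nrow(dp0$truth), 0)

  expect_error(simulate_drug_panel(5, c(a = 2, b = 2)), "class_sizes sum")
  # same seed -> identical panel
  dp2 <- simulate_drug_panel(n_drugs = 10, class_sizes = c(x = 10),
                             cell_lines = sim$invasion$cell_line, seed = 9)
  expect_identical(dp0$panel$sensitivity, dp2$panel$sensitivity)
})

test_that("validation panel plants the standardised score shift", {
  # Monte-Carlo: mean standardized score difference ~ planted shift
  diffs <- vapply(1:300, function(k) {
    vp <- simulate_validation_panel(15, 15, score_shift = 1.5, seed = 1000 + k)
    sc <- colMeans(vp$expr)
    (mean(sc[vp$labels == "sensitive"]) - mean(sc[vp$labels == "resistant"])) *
      sqrt(nrow(vp$expr))
  }, numeric(1))
  expect_equal(mean(diffs), 1.5, tolerance = 0.1)

  vp0 <- simulate_validation_panel(3, 4, 0, seed = 5)
  expect_equal(dim(vp0$expr), c(8L, 7L))
  expect_equal(unname(table(vp0$labels)["sensitive"]), 3L)

  # degenerate 1+1 panel: generator fine, t-test refuses
  vp1 <- simulate_validation_panel(1, 1, 1, seed = 6)
  expect_equal(ncol(vp1$expr), 2)
  expect_error(compare_groups(colMeans(vp1$expr), vp1$labels), ">= 2")
})

test_that("survival cohort generator meets its contracts", {
  ch <- simulate_survival_cohort(300, log(2), censoring_rate = 0.4, seed = 21)
  expect_s3_class(ch, "cohort_table")
  expect_equal(nrow(ch), 300)
  expect_true(all(ch$time > 0))
  expect_equal(mean(ch$event == 0), 0.4, tolerance = 0.1)
  expect_true(all(c("age", "stage", "nodal", "er") %in% names(ch)))

  nocens <- simulate_survival_cohort(50, 0.5, censoring_rate = 0, seed = 22)
  expect_true(all(nocens$event == 1))

  a <- simulate_survival_cohort(60, 0, seed = 3)
  b <- simulate_survival_cohort(60, 0, seed = 3)
  expect_identical(a$time, b$time)
  expect_error(simulate_survival_cohort(5, 0), ">= 10")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cell_line_panel(n_lines = 10, n_probes_a = 20,
                                     n_probes_b = 20, n_planted = 2, seed = 1))
  invisible(simulate_survival_cohort(20, 0, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("simulation truth CSV round-trips the planted structure", {
  sim <- simulate_cell_line_panel(n_lines = 15, n_probes_a = 30, n_probes_b = 30,
                                  n_planted = 6, seed = 12, n_signature = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulation_truth(list(planted = sim$truth$planted), f)
  tr <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(tr), 6)
  expect_setequal(tr$item, sim$truth$planted$probe_a)
  expect_true(all(tr$kind == "ia_probe"))
})
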