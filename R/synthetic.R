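# Run expr under a local RNG seeded with `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a cell-line panel with planted invasion-associated probes
#'
#' Generates the full discovery substrate: two probe-mapped expression
#' platforms, an invasion profile and recorded ground truth. One latent
#' invasion variable `z` per cell line drives both the invaded cell count
#' (ICC, log-normal with small tissue-group offsets so within-group variance
#' dominates between-group variance) and the planted probes, which have
#' population correlation `±effect_r` with `z` on both platforms with
#' matching sign. An independent latent `d` represents the drug-response
#' axis: the first `n_signature` planted probes additionally load on `d`
#' with loading `drug_loading` and get an inflated raw-scale standard
#' deviation (`sig_sd_scale`), emulating the empirical fact that informative
#' marker genes are high-variance. Non-planted probes are independent noise.
#' Platform B applies an independent per-probe affine distortion (scale and
#' offset), so cross-platform agreement is a matter of sign, not value.
#'
#' @param n_lines,n_groups Cell lines and tissue groups (defaults 53 and 8).
#' @param n_probes_a,n_probes_b Probes per platform.
#' @param n_planted Number of invasion-correlated probe pairs to plant.
#' @param effect_r Planted population correlation magnitude, in (0,1).
#' @param seed Integer seed; same seed, same output.
#' @param n_signature How many planted probes also load on the drug latent
#'   (default 0).
#' @param drug_loading Loading of signature probes on the drug latent.
#' @param sig_sd_scale Raw-scale SD multiplier for signature probes.
#' @param mm_frac Fraction of mapped genes receiving an extra spurious
#'   many-to-many map row (default 0 = strict 1:1).
#' @param chip_a_frac Fraction of platform-A probes assigned to the primary
#'   chip (`"chipA"`); signature probes are always on it.
#' @return List: `expr_a`, `expr_b` ([expression_matrix()]), `probe_map`,
#'   `invasion` ([invasion_profile()]), `membership` (probe/chip table for
#'   [filter_platform()]), `truth` (latents + planted table).
#' @export
simulate_cell_line_panel <- function(n_lines = 53, n_groups = 8,
                                     n_probes_a = 2000, n_probes_b = 2000,
                                     n_planted = 50, effect_r = 0.6,
                                     seed = 1, n_signature = 0,
                                     drug_loading = 0.63, sig_sd_scale = 2.5,
                                     mm_frac = 0, chip_a_frac = 0.85) {
  stopifnot(n_lines > 0, n_groups > 0, n_probes_a > 0, n_probes_b > 0)
  n_pair <- min(n_probes_a, n_probes_b)
  if (n_planted > n_pair) stop_ivs("n_planted (%d) exceeds mapped probes (%d)",
                                   n_planted, n_pair)
  if (n_signature > n_planted) stop_ivs("n_signature exceeds n_planted")
  stopifnot(effect_r > 0 || n_planted == 0, effect_r < 1)
  if (n_signature > 0 && effect_r^2 + drug_loading^2 >= 1) {
    stop_ivs("effect_r^2 + drug_loading^2 must be < 1")
  }
  with_seed(seed, {
    lines <- sprintf("CL%02d", seq_len(n_lines))
    # tissue groups of near-equal size; log-normal ICC with small group
    # offsets (between-group sd 0.15 << within-group sd 0.8)
    grp <- sort(rep_len(seq_len(n_groups), n_lines))
    gnames <- sprintf("T%d", seq_len(n_groups))
    z <- stats::rnorm(n_lines)
    d <- stats::rnorm(n_lines)
    offs <- stats::rnorm(n_groups, 0, 0.15)
    icc <- exp(log(800) + offs[grp] + 0.8 * z)
    invasion <- invasion_profile(lines, icc, gnames[grp])

    planted_idx <- if (n_planted > 0) sort(sample.int(n_pair, n_planted)) else integer()
    sig_idx <- planted_idx[seq_len(n_signature)]
    signs <- integer(n_pair)
    if (n_planted > 0) {
      signs[planted_idx] <- sample(c(-1L, 1L), n_planted, replace = TRUE)
      signs[sig_idx] <- 1L  # signature genes: invasion-promoting by default
    }
    loadings <- numeric(n_pair)
    loadings[sig_idx] <- drug_loading

    gene_sym <- sprintf("GENE%05d", seq_len(max(n_probes_a, n_probes_b)))
    probes_a <- sprintf("A_%05d", seq_len(n_probes_a))
    probes_b <- sprintf("B_%05d", seq_len(n_probes_b))

    make_platform <- function(n_probes, probes) {
      a <- numeric(n_probes); b <- numeric(n_probes)
      a[seq_len(n_pair)] <- effect_r * signs[seq_len(n_pair)]
      b[seq_len(n_pair)] <- loadings[seq_len(n_pair)]
      c2 <- pmax(1 - a^2 - b^2, 0)
      struct <- outer(a, z) + outer(b, d)
      eps <- matrix(stats::rnorm(n_probes * n_lines), n_probes, n_lines)
      raw <- struct + sqrt(c2) * eps
      sdv <- exp(stats::rnorm(n_probes, 0, 0.4))
      if (n_signature > 0) {
        sdv[intersect(sig_idx, seq_len(n_probes))] <- sig_sd_scale
      }
      mu <- stats::rnorm(n_probes, 7, 1)
      vals <- raw * sdv + mu
      dimnames(vals) <- list(probes, lines)
      vals
    }
    expr_a <- expression_matrix(make_platform(n_probes_a, probes_a), "A")
    expr_b <- expression_matrix(make_platform(n_probes_b, probes_b), "B")

    probe_map <- data.frame(probe_a = probes_a[seq_len(n_pair)],
                            probe_b = probes_b[seq_len(n_pair)],
                            gene_symbol = gene_sym[seq_len(n_pair)],
                            stringsAsFactors = FALSE)
    n_mm <- floor(mm_frac * n_pair)
    if (n_mm > 0) {
      pool <- setdiff(seq_len(n_pair), planted_idx)
      src <- sample(pool, min(n_mm, length(pool)))
      tgt <- vapply(src, function(i) sample(setdiff(seq_len(n_pair), i), 1), integer(1))
      probe_map <- rbind(probe_map,
                         data.frame(probe_a = probes_a[src],
                                    probe_b = probes_b[tgt],
                                    gene_symbol = gene_sym[src],
                                    stringsAsFactors = FALSE))
    }

    chip <- ifelse(stats::runif(n_probes_a) < chip_a_frac, "chipA", "chipB")
    chip[intersect(sig_idx, seq_len(n_probes_a))] <- "chipA"
    membership <- data.frame(probe = probes_a, chip = chip,
                             stringsAsFactors = FALSE)

    planted <- data.frame(
      gene = gene_sym[planted_idx],
      probe_a = probes_a[planted_idx],
      probe_b = probes_b[planted_idx],
      sign = signs[planted_idx],
      effect_r = rep(effect_r, length(planted_idx)),
      drug_loading = loadings[planted_idx],
      is_signature = planted_idx %in% sig_idx,
      stringsAsFactors = FALSE)

    list(expr_a = expr_a, expr_b = expr_b, probe_map = probe_map,
         invasion = invasion, membership = membership,
         truth = list(latent_invasion = stats::setNames(z, lines),
                      latent_drug = stats::setNames(d, lines),
                      planted = planted))
  })
}

#' Simulate a drug sensitivity panel with planted gene-drug associations
#'
#' Drugs are grouped into mechanism classes. Classes named in `assoc_spec`
#' load on the drug latent `d` of the matching cell-line panel with a
#' class-specific sign -- the default pipeline world gives targeted-therapy
#' agents sign +1 and tubulin-binding agents sign -1, reproducing the
#' observed mechanism sign-flip. Exactly `n_inactive` drugs (taken from the
#' end of the drug ordering, i.e. from unplanted classes) are constant
#' across all lines. Planted gene-drug population correlations are recorded
#' in the truth as `class_sign * class_effect_r * gene_loading`.
#'
#' @param n_drugs Total number of drugs.
#' @param class_sizes Named integer vector of drugs per mechanism class;
#'   must sum to `n_drugs`.
#' @param n_inactive Number of constant (inactive) drugs.
#' @param assoc_spec `NULL`, or a list with `latent` (named numeric vector
#'   over cell lines, the drug latent `d`), `classes` (named list, each with
#'   `sign` in {-1, +1} and `effect_r` in (0, 1)), and optionally
#'   `gene_loadings` (named signed loadings per probe, used only to record
#'   planted population correlations).
#' @param cell_lines Cell-line IDs (required when `assoc_spec` is `NULL`).
#' @param seed Integer seed.
#' @return List: `panel` (a [drug_panel()]) and `truth` (data frame of
#'   planted drug-probe population correlations, possibly empty, plus the
#'   inactive drug IDs as attribute `inactive`).
#' @export
simulate_drug_panel <- function(n_drugs, class_sizes, n_inactive = 0,
                                assoc_spec = NULL, cell_lines = NULL,
                                seed = 1) {
  if (sum(class_sizes) != n_drugs) {
    stop_ivs("class_sizes sum (%d) != n_drugs (%d)", sum(class_sizes), n_drugs)
  }
  if (n_inactive > n_drugs) stop_ivs("n_inactive exceeds n_drugs")
  if (is.null(cell_lines)) {
    if (is.null(assoc_spec)) stop_ivs("need cell_lines or assoc_spec$latent")
    cell_lines <- names(assoc_spec$latent)
  }
  n_lines <- length(cell_lines)
  classes <- rep(names(class_sizes), class_sizes)
  drug_id <- unlist(lapply(names(class_sizes), function(cl)
    sprintf("%s_%02d", cl, seq_len(class_sizes[[cl]]))))
  planted_classes <- names(assoc_spec$classes %||% list())
  n_planted_drugs <- sum(classes %in% planted_classes)
  if (n_inactive > n_drugs - n_planted_drugs) {
    stop_ivs("n_inactive (%d) exceeds unplanted drugs (%d)",
             n_inactive, n_drugs - n_planted_drugs)
  }
  with_seed(seed, {
    S <- matrix(NA_real_, n_drugs, n_lines, dimnames = list(drug_id, cell_lines))
    d <- if (!is.null(assoc_spec)) assoc_spec$latent[cell_lines] else NULL
    for (i in seq_len(n_drugs)) {
      cl <- classes[i]
      if (cl %in% planted_classes) {
        spec <- assoc_spec$classes[[cl]]
        stopifnot(spec$sign %in% c(-1, 1), spec$effect_r > 0, spec$effect_r < 1)
        S[i, ] <- 5 + spec$sign * spec$effect_r * d +
          sqrt(1 - spec$effect_r^2) * stats::rnorm(n_lines)
      } else {
        S[i, ] <- 5 + stats::rnorm(n_lines)
      }
    }
    inactive <- character()
    if (n_inactive > 0) {
      # constant floor response: the "inactive in all cell lines" pattern
      idx <- seq(n_drugs - n_inactive + 1L, n_drugs)
      S[idx, ] <- 4
      inactive <- drug_id[idx]
    }
    truth <- data.frame(drug = character(), probe = character(),
                        pop_r = numeric(), stringsAsFactors = FALSE)
    if (length(planted_classes) && !is.null(assoc_spec$gene_loadings)) {
      gl <- assoc_spec$gene_loadings
      rows <- lapply(which(classes %in% planted_classes), function(i) {
        spec <- assoc_spec$classes[[classes[i]]]
        data.frame(drug = drug_id[i], probe = names(gl),
                   pop_r = spec$sign * spec$effect_r * as.numeric(gl),
                   stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, rows)
    }
    attr(truth, "inactive") <- inactive
    list(panel = drug_panel(S, classes), truth = truth)
  })
}

#' Simulate a sensitive/resistant validation panel
#'
#' Per-gene expression is standard normal; each signature gene of the
#' sensitive group is mean-shifted by `direction * score_shift / sqrt(g)`,
#' so the average-of-genes risk score differs between groups by
#' `score_shift` standard deviations of the null score.
#'
#' @param n_sensitive,n_resistant Group sizes (positive).
#' @param score_shift Standardised mean score difference to plant.
#' @param seed Integer seed.
#' @param genes Signature gene names (default 8 generic genes).
#' @param direction +1: sensitive group scores higher (targeted-agent
#'   convention); -1 flips it.
#' @return List: `expr` (genes x samples matrix), `labels`
#'   (`"sensitive"`/`"resistant"` per sample), `truth` (per-gene shift and
#'   the planted standardised score difference).
#' @export
simulate_validation_panel <- function(n_sensitive, n_resistant, score_shift,
                                      seed = 1, genes = sprintf("SG%d", 1:8),
                                      direction = 1) {
  stopifnot(n_sensitive > 0, n_resistant > 0, direction %in% c(-1, 1))
  g <- length(genes)
  with_seed(seed, {
    n <- n_sensitive + n_resistant
    ids <- sprintf("V%03d", seq_len(n))
    labels <- c(rep("sensitive", n_sensitive), rep("resistant", n_resistant))
    X <- matrix(stats::rnorm(g * n), g, n, dimnames = list(genes, ids))
    delta <- direction * score_shift / sqrt(g)
    X[, labels == "sensitive"] <- X[, labels == "sensitive"] + delta
    list(expr = X, labels = stats::setNames(labels, ids),
         truth = list(per_gene_shift = delta,
                      score_shift = direction * score_shift))
  })
}

#' Simulate a survival cohort with a planted score effect
#'
#' Signature-gene expression is standard normal; the risk score is the row
#' mean. Event times are exponential with hazard proportional to
#' `exp(log_hr_per_unit_score * x)` where `x` is the standardised score
#' (or, with `dichotomize_effect = TRUE`, the high/low indicator at the
#' cohort mean, matching the mean-threshold grouping the pipeline applies).
#' Censoring is independent uniform on `(0, b)` with `b` solved numerically
#' so the expected censoring fraction equals `censoring_rate`. Clinical
#' covariates (age, sex, stage, nodal status, ER status) are generated
#' independent of the score.
#'
#' @param n Cohort size (>= 10).
#' @param log_hr_per_unit_score Planted log hazard ratio.
#' @param censoring_rate Target censoring fraction in `[0, 1)`.
#' @param covariate_spec `TRUE` (default) to include the standard covariate
#'   block, `FALSE` for none.
#' @param seed Integer seed.
#' @param genes Signature gene column names.
#' @param dichotomize_effect Apply the log-HR to the high/low indicator
#'   instead of the continuous standardised score.
#' @param baseline_hazard Events per month at `x = 0` (default 0.02, median
#'   survival around three years).
#' @return A [cohort_table()] with attribute `truth` (planted log-HR, the
#'   linear predictor variable, and the realised censoring fraction).
#' @export
simulate_survival_cohort <- function(n, log_hr_per_unit_score,
                                     censoring_rate = 0.3,
                                     covariate_spec = TRUE, seed = 1,
                                     genes = sprintf("SG%d", 1:8),
                                     dichotomize_effect = FALSE,
                                     baseline_hazard = 0.02) {
  if (n < 10) stop_ivs("simulate_survival_cohort: n must be >= 10")
  stopifnot(censoring_rate >= 0, censoring_rate < 1)
  g <- length(genes)
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n))
    G <- matrix(stats::rnorm(n * g), n, g, dimnames = list(ids, genes))
    score <- rowMeans(G)
    x <- if (dichotomize_effect) as.numeric(score > mean(score))
         else as.numeric(scale(score))
    lambda <- baseline_hazard * exp(log_hr_per_unit_score * x)
    tt <- stats::rexp(n, rate = lambda)
    if (censoring_rate > 0) {
      # expected censoring fraction for C ~ U(0, b) against Exp(lambda_i)
      cens_frac <- function(b) mean((1 - exp(-lambda * b)) / (lambda * b))
      b <- stats::uniroot(function(b) cens_frac(b) - censoring_rate,
                          lower = 1e-6, upper = 1e6, tol = 1e-8)$root
      cc <- stats::runif(n, 0, b)
      event <- as.integer(tt <= cc)
      time <- pmin(tt, cc)
    } else {
      event <- rep(1L, n)
      time <- tt
    }
    df <- data.frame(patient_id = ids, time = time, event = event,
                     stringsAsFactors = FALSE)
    cov_cols <- character()
    if (isTRUE(covariate_spec)) {
      df$age <- round(stats::rnorm(n, 60, 10))
      df$sex <- sample(c(0L, 1L), n, replace = TRUE)
      df$stage <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      df$nodal <- sample(c(0L, 1L), n, replace = TRUE)
      df$er <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.35, 0.65))
      cov_cols <- c("age", "sex", "stage", "nodal", "er")
    }
    df <- cbind(df, as.data.frame(G))
    out <- cohort_table(df, covariate_cols = cov_cols, gene_cols = genes)
    attr(out, "truth") <- list(log_hr = log_hr_per_unit_score,
                               dichotomized = dichotomize_effect,
                               censoring_observed = mean(event == 0))
    out
  })
}

#' Write simulation ground truth as a plain CSV
#'
#' One row per planted item: `item`, `kind`, `sign`, `effect`.
#'
#' @param truth Truth list from [simulate_cell_line_panel()] (its `planted`
#'   table) and/or a [simulate_drug_panel()] truth data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  rows <- list()
  if (!is.null(truth$planted)) {
    p <- truth$planted
    rows[[1]] <- data.frame(item = p$probe_a, kind = "ia_probe",
                            sign = p$sign, effect = p$effect_r,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(truth$drug_assoc) && nrow(truth$drug_assoc)) {
    da <- truth$drug_assoc
    rows[[length(rows) + 1]] <- data.frame(
      item = paste(da$drug, da$probe, sep = ":"), kind = "gene_drug",
      sign = sign(da$pop_r), effect = abs(da$pop_r),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item = character(), kind = character(),
               sign = numeric(), effect = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
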