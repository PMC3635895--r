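#' Two-group comparison of risk scores
#'
#' Two-sided two-sample t-test (Welch by default; pooled-variance Student
#' optional) between, e.g., drug-sensitive and drug-resistant cell lines.
#'
#' @param scores Numeric vector of risk scores, or a [compute_risk_score()]
#'   table (its `score` column is used).
#' @param labels Factor/character vector of two group labels, aligned with
#'   `scores`.
#' @param var_equal Use the pooled-variance test (default `FALSE` = Welch).
#' @return List (`groups`, `n`, `means`, `mean_difference`, `t_statistic`,
#'   `df`, `p_two_sided`).
#' @export
compare_groups <- function(scores, labels, var_equal = FALSE) {
  if (is.data.frame(scores)) scores <- scores$score
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  gs <- sort(unique(labels))
  if (length(gs) != 2) stop_ivs("compare_groups: need exactly 2 groups, got %d", length(gs))
  x <- scores[labels == gs[1]]
  y <- scores[labels == gs[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop_ivs("compare_groups: both groups need >= 2 observations (got %d, %d)",
             length(x), length(y))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(groups = gs, n = c(length(x), length(y)),
       means = c(mean(x), mean(y)),
       mean_difference = mean(x) - mean(y),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, welch = !var_equal)
}

#' Re-test after removing overlapping samples
#'
#' Removes listed sample IDs (e.g. validation cell lines that also belong to
#' the training panel) and repeats [compare_groups()] on the reduced data.
#'
#' @param scores A [compute_risk_score()] table (needs `sample_id`).
#' @param labels Group labels aligned with `scores` rows.
#' @param exclude Sample IDs to drop.
#' @inheritParams compare_groups
#' @return A [compare_groups()] result with attribute `removed`.
#' @export
remove_overlap_and_retest <- function(scores, labels, exclude,
                                      var_equal = FALSE) {
  stopifnot(is.data.frame(scores), "sample_id" %in% names(scores))
  keep <- !scores$sample_id %in% exclude
  removed <- scores$sample_id[!keep]
  if (length(removed)) {
    ivs_log("INFO", "remove_overlap_and_retest: removed %d sample(s): %s",
            length(removed), paste(removed, collapse = ", "))
  }
  out <- compare_groups(scores[keep, , drop = FALSE], labels[keep],
                        var_equal = var_equal)
  attr(out, "removed") <- removed
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per risk group and the unstratified
#' two-group log-rank chi-square (1 df).
#'
#' @param cohort A [cohort_table()].
#' @param groups Character vector of group labels (e.g. `"high"`/`"low"`)
#'   aligned with cohort rows.
#' @return List with `km` (data frame: `group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `logrank_chi2`, `logrank_p`, `n`, `events`.
#' @export
km_logrank <- function(cohort, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(cohort))
  ev <- tapply(cohort$event, groups, sum)
  if (any(ev == 0)) {
    warning("km_logrank: group(s) with zero events: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  }
  if (sum(cohort$event) < 1) stop_ivs("km_logrank: no events in cohort")
  surv <- survival::Surv(cohort$time, cohort$event)
  fit <- survival::survfit(surv ~ groups)
  sm <- summary(fit)
  grp <- if (is.null(sm$strata)) rep(unique(groups)[1], length(sm$time)) else
    sub("^groups=", "", as.character(sm$strata))
  km <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                   n_event = sm$n.event, survival = sm$surv,
                   stringsAsFactors = FALSE)
  if (length(unique(groups)) == 2) {
    sd <- survival::survdiff(surv ~ groups)
    chi2 <- unname(sd$chisq)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- NA_real_
  }
  list(km = km, logrank_chi2 = chi2, logrank_p = p,
       n = nrow(cohort), events = sum(cohort$event))
}

#' Multivariate Cox proportional hazards regression
#'
#' Partial-likelihood fit (Efron tie handling by default) of survival on the
#' signature score or group plus clinical covariates, with hazard ratios,
#' Wald 95% confidence intervals and p-values per covariate. Complete-case
#' analysis; exclusions are logged. Non-convergence or infinite coefficients
#' (separation) are flagged on the result rather than raised.
#'
#' @param cohort A [cohort_table()].
#' @param covariates Column names to include as predictors (may include a
#'   column added by the caller, e.g. the risk group).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param guard Require `events >= covariates + 5` (default `TRUE`); set
#'   `FALSE` for deliberate small worked examples.
#' @return List with `coefficients` (data frame: `variable`, `coef`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `n`, `events`, `flagged` (logical),
#'   `messages`.
#' @export
cox_multivariate <- function(cohort, covariates, ties = c("efron", "breslow"),
                             guard = TRUE) {
  ties <- match.arg(ties)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop_ivs("cox_multivariate: unknown covariate(s): %s",
                             paste(miss, collapse = ", "))
  dat <- as.data.frame(cohort)[, c("time", "event", covariates), drop = FALSE]
  cc <- stats::complete.cases(dat)
  if (any(!cc)) {
    ivs_log("INFO", "cox_multivariate: excluding %d incomplete case(s)", sum(!cc))
    dat <- dat[cc, , drop = FALSE]
  }
  const <- vapply(covariates, function(v) length(unique(dat[[v]])) < 2, logical(1))
  if (any(const)) stop_ivs("cox_multivariate: constant covariate(s): %s",
                           paste(covariates[const], collapse = ", "))
  if (guard && sum(dat$event) < length(covariates) + 5) {
    stop_ivs("cox_multivariate: too few events (%d) for %d covariates",
             sum(dat$event), length(covariates))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  msgs <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  flagged <- length(msgs) > 0 || anyNA(co[, "coef"]) ||
    any(!is.finite(co[, "coef"])) || any(abs(co[, "coef"]) > 15)
  list(coefficients = data.frame(variable = rownames(co),
                                 coef = co[, "coef"],
                                 hr = ci[, "exp(coef)"],
                                 ci_low = ci[, "lower .95"],
                                 ci_high = ci[, "upper .95"],
                                 p = co[, "Pr(>|z|)"],
                                 stringsAsFactors = FALSE, row.names = NULL),
       n = sm$n, events = sum(dat$event), ties = ties,
       flagged = flagged, messages = msgs)
}

#' Run the survival pipeline over treated and control cohorts
#'
#' Applies score dichotomisation, KM/log-rank and (when feasible) Cox to a
#' list of cohorts, collecting a specificity summary of log-rank p-values by
#' treatment flag. Per-cohort failures are captured, not propagated.
#'
#' @param cohorts Named list of [cohort_table()] objects.
#' @param treated Logical vector (one flag per cohort): treated or control.
#' @param genes Signature gene column names.
#' @param standardize,threshold_rule Passed to [compute_risk_score()].
#' @return List with `reports` (per-cohort [km_logrank()] results, or an
#'   error record) and `summary` (data frame: `cohort`, `treated`, `n`,
#'   `events`, `logrank_p`, `status`).
#' @export
control_cohort_run <- function(cohorts, treated, genes, standardize = TRUE,
                               threshold_rule = "mean") {
  stopifnot(length(cohorts) >= 1, length(treated) == length(cohorts))
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  reports <- vector("list", length(cohorts))
  names(reports) <- nm
  rows <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    ch <- cohorts[[i]]
    res <- tryCatch({
      if (sum(ch$event) < 1) stop("all observations censored")
      X <- t(as.matrix(as.data.frame(ch)[, genes, drop = FALSE]))
      colnames(X) <- ch$patient_id
      rs <- compute_risk_score(X, genes, standardize = standardize,
                               threshold_rule = threshold_rule)
      rep <- km_logrank(ch, rs$group)
      rep$risk_scores <- rs
      rep
    }, error = function(e) structure(list(error = conditionMessage(e)),
                                     class = "ivs_cohort_error"))
    reports[[i]] <- res
    failed <- inherits(res, "ivs_cohort_error")
    rows[[i]] <- data.frame(cohort = nm[i], treated = treated[i],
                            n = nrow(ch), events = sum(ch$event),
                            logrank_p = if (failed) NA_real_ else res$logrank_p,
                            status = if (failed) res$error else "ok",
                            stringsAsFactors = FALSE)
  }
  list(reports = reports, summary = do.call(rbind, rows))
}
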