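#' Remove inactive drugs from a panel
#'
#' A drug is inactive when its sensitivity vector carries no information:
#' entirely missing, fewer than two non-missing values, or constant across
#' cell lines. Removals are logged.
#'
#' @param panel A [drug_panel()].
#' @return The filtered [drug_panel()]; attribute `removed` lists drug IDs.
#' @export
filter_inactive_drugs <- function(panel) {
  S <- panel$sensitivity
  inactive <- apply(S, 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || max(v) == min(v)
  })
  if (all(inactive)) warning("filter_inactive_drugs: all drugs inactive")
  removed <- rownames(S)[inactive]
  if (length(removed)) {
    ivs_log("INFO", "filter_inactive_drugs: removed %d inactive drug(s): %s",
            length(removed), paste(removed, collapse = ", "))
  }
  out <- drug_panel(S[!inactive, , drop = FALSE],
                    panel$info$mechanism_class[!inactive])
  attr(out, "removed") <- removed
  out
}

#' Gene-drug correlation matrix
#'
#' Pearson correlation between each probe's expression profile (typically
#' restricted to invasion-associated probes) and each drug's sensitivity
#' profile over the shared cell lines. Sign convention: positive r means
#' higher expression goes with higher -log10 GI50, i.e. greater sensitivity.
#' Expression rows and, by default, sensitivity rows are normal-scored.
#' Cells with fewer than three complete pairs are missing.
#'
#' @param expr An [expression_matrix()] (rows = probes of interest).
#' @param panel A [drug_panel()].
#' @param transform Normal-score expression and sensitivity first
#'   (default `TRUE`).
#' @return List of three probes x drugs matrices: `r`, `p`, `n`, plus
#'   `drug_info` (the panel's drug/mechanism table restricted to analysed
#'   drugs) and `cell_lines` (the shared universe used).
#' @export
gene_drug_correlations <- function(expr, panel, transform = TRUE) {
  shared <- intersect(sample_ids(expr), colnames(panel$sensitivity))
  if (length(shared) < 3) stop_ivs("gene_drug_correlations: < 3 shared cell lines")
  ivs_log("INFO", "gene_drug_correlations: %d shared cell lines", length(shared))
  X <- expr$values[, shared, drop = FALSE]
  if (transform) X <- normal_score_rows(X)
  S <- panel$sensitivity[, shared, drop = FALSE]
  nd <- nrow(S)
  R <- P <- N <- matrix(NA_real_, nrow(X), nd,
                        dimnames = list(rownames(X), rownames(S)))
  for (j in seq_len(nd)) {
    y <- S[j, ]
    if (transform) {
      yok <- !is.na(y)
      if (sum(yok) >= 3 && stats::sd(y[yok]) > 0) {
        y <- as.numeric(normal_score_transform(y))
      }
    }
    res <- row_pearson(X, y)
    R[, j] <- res$r
    P[, j] <- res$p
    N[, j] <- res$n
  }
  if (anyNA(R)) {
    ivs_log("INFO", "gene_drug_correlations: %d cell(s) missing (insufficient pairs)",
            sum(is.na(R)))
  }
  list(r = R, p = P, n = N, drug_info = panel$info, cell_lines = shared)
}

#' Per-drug counts of significantly correlated probes
#'
#' Counts, for each drug, the probes whose gene-drug correlation p-value is
#' below `alpha` (raw, uncorrected -- the screen-level FDR is handled
#' upstream), and the mean count per mechanism class.
#'
#' @param gd A [gene_drug_correlations()] result.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `per_drug` (data frame `drug_id`, `mechanism_class`,
#'   `n_significant`) and `per_class` (data frame `mechanism_class`,
#'   `mean_count`).
#' @export
count_significant <- function(gd, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  counts <- colSums(gd$p < alpha, na.rm = TRUE)
  per_drug <- data.frame(drug_id = colnames(gd$p),
                         mechanism_class = gd$drug_info$mechanism_class[
                           match(colnames(gd$p), gd$drug_info$drug_id)],
                         n_significant = as.integer(counts),
                         stringsAsFactors = FALSE, row.names = NULL)
  cls <- tapply(per_drug$n_significant, per_drug$mechanism_class, mean)
  list(per_drug = per_drug,
       per_class = data.frame(mechanism_class = names(cls),
                              mean_count = as.vector(cls), row.names = NULL))
}

#' Extract per-drug significant probe sets
#'
#' Convenience accessor used by the signature derivation: the set of probes
#' with p below `alpha` for each requested drug.
#'
#' @inheritParams count_significant
#' @param drugs Drug IDs (default: all).
#' @return Named list of character vectors.
#' @export
significant_probe_sets <- function(gd, alpha = 0.05, drugs = colnames(gd$p)) {
  unknown <- setdiff(drugs, colnames(gd$p))
  if (length(unknown)) stop_ivs("significant_probe_sets: unknown drug(s): %s",
                                paste(unknown, collapse = ", "))
  out <- lapply(drugs, function(d) {
    rownames(gd$p)[which(gd$p[, d] < alpha)]
  })
  names(out) <- drugs
  out
}

#' Drug-drug similarity of gene-drug correlation columns
#'
#' Pearson correlation between the gene-drug correlation columns of pairs of
#' drugs: two drugs whose sensitivities relate to the same genes in the same
#' way score near +1; a mechanism sign-flip (e.g. anti-microtubule versus
#' targeted agents) scores near -1. Cells with fewer than three probes of
#' overlap are missing.
#'
#' @param gd A [gene_drug_correlations()] result.
#' @param drugs Drug subset (default: all columns).
#' @return Symmetric drug x drug correlation matrix with unit diagonal.
#' @export
drug_profile_similarity <- function(gd, drugs = colnames(gd$r)) {
  unknown <- setdiff(drugs, colnames(gd$r))
  if (length(unknown)) stop_ivs("drug_profile_similarity: unknown drug(s): %s",
                                paste(unknown, collapse = ", "))
  A <- gd$r[, drugs, drop = FALSE]
  k <- length(drugs)
  out <- matrix(NA_real_, k, k, dimnames = list(drugs, drugs))
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) { out[i, j] <- 1; next }
      ok <- !is.na(A[, i]) & !is.na(A[, j])
      if (sum(ok) >= 3 && stats::sd(A[ok, i]) > 0 && stats::sd(A[ok, j]) > 0) {
        out[i, j] <- out[j, i] <- stats::cor(A[ok, i], A[ok, j])
      }
    }
  }
  out
}

#' Correlation between the invasion profile and each drug's sensitivity
#'
#' @param invasion An [invasion_profile()].
#' @param panel A [drug_panel()].
#' @param transform Normal-score both profiles first (default `TRUE`).
#' @param alpha Significance flag threshold (default 0.05).
#' @return Data frame (`item_id`, `r`, `p_two_sided`, `n_used`,
#'   `significant`), one row per drug retained; constant drugs are dropped.
#' @export
invasion_drug_correlation <- function(invasion, panel, transform = TRUE,
                                      alpha = 0.05) {
  shared <- intersect(invasion$cell_line, colnames(panel$sensitivity))
  if (length(shared) < 3) stop_ivs("invasion_drug_correlation: < 3 shared cell lines")
  icc <- invasion$icc[match(shared, invasion$cell_line)]
  S <- panel$sensitivity[, shared, drop = FALSE]
  if (transform) {
    icc <- as.numeric(normal_score_transform(icc))
    S <- normal_score_rows(S)
  }
  res <- row_pearson(S, icc)
  keep <- !is.na(res$r)
  if (any(!keep)) {
    ivs_log("INFO", "invasion_drug_correlation: dropped %d drug(s)", sum(!keep))
  }
  data.frame(item_id = rownames(S)[keep], r = res$r[keep],
             p_two_sided = res$p[keep], n_used = res$n[keep],
             significant = res$p[keep] < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
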