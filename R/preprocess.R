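#' Rank-based normal score transformation
#'
#' Maps a numeric vector to standard-normal quantiles by rank: a value with
#' average rank \eqn{r} among the \eqn{m} non-missing observations becomes
#' \eqn{\Phi^{-1}(r/(m+1))} (the van der Waerden convention). Ties share an
#' average rank and therefore the same output; missing values stay missing.
#' The transform is the default preprocessing step before every Pearson
#' correlation in the pipeline, because heavy-tailed profiles (invaded cell
#' counts, raw intensities) otherwise let single outliers drive correlations.
#'
#' @param x Numeric vector, possibly with `NA`s.
#' @return Numeric vector of the same length with attribute `source_ranks`
#'   (average ranks, `NA` preserved).
#' @examples
#' normal_score_transform(c(5, 1, 3))   # 0.674, -0.674, 0
#' @export
normal_score_transform <- function(x) {
  ok <- !is.na(x)
  m <- sum(ok)
  if (m < 3) stop_ivs("normal_score_transform: need >= 3 non-missing values, got %d", m)
  rk <- rank(x, na.last = "keep", ties.method = "average")
  out <- stats::qnorm(rk / (m + 1))
  attr(out, "source_ranks") <- rk
  out
}

# Row-wise normal scores for a probes x samples matrix. Rows with fewer than
# three non-missing entries are returned as all-NA (dropped downstream).
normal_score_rows <- function(X) {
  out <- t(apply(X, 1L, function(x) {
    m <- sum(!is.na(x))
    if (m < 3) return(rep(NA_real_, length(x)))
    stats::qnorm(rank(x, na.last = "keep", ties.method = "average") / (m + 1))
  }))
  dimnames(out) <- dimnames(X)
  out
}

#' Match probes across two expression platforms
#'
#' Restricts a cross-platform probe map to the pairs whose probes are present
#' in both matrices, and records the shared-sample intersection. Many-to-many
#' map entries are all retained; downstream stages decide how to resolve them
#' (the two-stage screen uses the best sign-consistent partner).
#'
#' @param expr_a,expr_b [expression_matrix()] objects.
#' @param probe_map Data frame with columns `probe_a`, `probe_b`,
#'   `gene_symbol` (see [read_probe_map()]).
#' @return Data frame of retained `(probe_a, probe_b, gene_symbol)` rows with
#'   attribute `shared_samples`.
#' @export
match_probes <- function(expr_a, expr_b, probe_map) {
  stopifnot(all(c("probe_a", "probe_b", "gene_symbol") %in% names(probe_map)))
  shared <- intersect(sample_ids(expr_a), sample_ids(expr_b))
  if (length(shared) < 3) {
    stop_ivs("match_probes: only %d shared samples (need >= 3)", length(shared))
  }
  keep <- probe_map$probe_a %in% probe_ids(expr_a) &
    probe_map$probe_b %in% probe_ids(expr_b)
  out <- probe_map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shared_samples") <- shared
  ivs_log("INFO", "match_probes: %d/%d map rows retained, %d shared samples",
          nrow(out), nrow(probe_map), length(shared))
  out
}
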