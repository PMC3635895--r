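#' Intersect per-drug significant probe sets
#'
#' First signature filter: probes significantly correlated with the
#' sensitivity of every drug in the chosen subset (exact set intersection).
#'
#' @param probe_sets Named list of per-drug probe ID vectors (see
#'   [significant_probe_sets()]).
#' @param drugs Drug IDs to intersect over.
#' @return Character vector of common probes.
#' @export
intersect_drug_correlated <- function(probe_sets, drugs = names(probe_sets)) {
  unknown <- setdiff(drugs, names(probe_sets))
  if (length(unknown)) stop_ivs("intersect_drug_correlated: unknown drug(s): %s",
                                paste(unknown, collapse = ", "))
  Reduce(intersect, probe_sets[drugs])
}

#' Restrict probes to one chip
#'
#' Second filter: keep only probes present on the designated chip (the
#' analogue of dropping U133B-only probes so public U133A data can apply the
#' signature). Order is preserved.
#'
#' @param probes Candidate probe IDs.
#' @param membership Data frame with columns `probe` and `chip`.
#' @param chip Chip label to keep.
#' @return Subset of `probes`.
#' @export
filter_platform <- function(probes, membership, chip) {
  idx <- match(probes, membership$probe)
  if (anyNA(idx)) stop_ivs("filter_platform: unknown membership for probe(s): %s",
                           paste(probes[is.na(idx)], collapse = ", "))
  out <- probes[membership$chip[idx] == chip]
  if (!length(out)) warning("filter_platform: no candidate probe on chip ", chip)
  out
}

#' Keep probes with high expression variance
#'
#' Third filter: per-probe standard deviation across all samples on the raw
#' log2 scale, ranked against the full matrix; candidates at or above the
#' top-`(1 - quantile)` cutoff are retained. The cutoff is the SD of the
#' `ceiling((1 - quantile) * n_probes)`-th largest probe, and comparison is
#' `>=`, so boundary behaviour is deterministic.
#'
#' @param expr An [expression_matrix()] (the full chip).
#' @param probes Candidate probe IDs.
#' @param quantile SD quantile defining the cutoff (default 0.9, i.e.
#'   top 10%).
#' @return Subset of `probes`, with attribute `sd_cutoff`.
#' @export
filter_by_sd <- function(expr, probes, quantile = 0.9) {
  stopifnot(quantile > 0, quantile < 1)
  sds <- apply(expr$values, 1L, stats::sd, na.rm = TRUE)
  n_top <- ceiling((1 - quantile) * length(sds))
  cutoff <- unname(sort(sds, decreasing = TRUE)[n_top])
  idx <- match(probes, names(sds))
  if (anyNA(idx)) stop_ivs("filter_by_sd: probe(s) absent from matrix: %s",
                           paste(probes[is.na(idx)], collapse = ", "))
  out <- probes[sds[idx] >= cutoff]
  attr(out, "sd_cutoff") <- cutoff
  out
}

#' Enforce direction consistency of gene-drug correlations
#'
#' Fourth filter: a probe is retained only if, for every in-scope drug, the
#' sign of its gene-drug correlation matches the sign expected for that
#' drug's mechanism class (default convention: positive for targeted-therapy
#' agents, negative for tubulin-binding agents). A missing correlation cell
#' for an in-scope drug rejects the probe (logged).
#'
#' @param probes Candidate probe IDs.
#' @param gd A [gene_drug_correlations()] result.
#' @param expected Named numeric vector of +1/-1 per mechanism class.
#' @param drugs In-scope drug IDs (default: all drugs whose class appears in
#'   `expected`).
#' @return Subset of `probes`.
#' @export
filter_direction_consistency <- function(probes, gd, expected,
                                         drugs = NULL) {
  info <- gd$drug_info
  if (is.null(drugs)) {
    drugs <- info$drug_id[info$mechanism_class %in% names(expected)]
  }
  cls <- info$mechanism_class[match(drugs, info$drug_id)]
  if (anyNA(cls)) stop_ivs("filter_direction_consistency: unknown drug(s): %s",
                           paste(drugs[is.na(cls)], collapse = ", "))
  missing_cls <- setdiff(unique(cls), names(expected))
  if (length(missing_cls)) stop_ivs(
    "filter_direction_consistency: no expected sign for class(es): %s",
    paste(missing_cls, collapse = ", "))
  want <- expected[cls]
  keep <- vapply(probes, function(p) {
    r <- gd$r[p, drugs]
    if (anyNA(r)) {
      ivs_log("INFO", "filter_direction_consistency: probe %s rejected (missing cell)", p)
      return(FALSE)
    }
    all(sign(r) == want)
  }, logical(1))
  probes[keep]
}

#' Collapse probes to a one-probe-per-gene signature
#'
#' When several surviving probes annotate the same gene, the probe with the
#' largest expression SD wins. The per-gene direction map (expected
#' correlation sign per mechanism class) is read off the gene-drug
#' correlation matrix.
#'
#' @param probes Final probe set.
#' @param annotation Data frame with columns `probe`, `gene_symbol`.
#' @param expr An [expression_matrix()] for the SD tie-break.
#' @param gd Optional [gene_drug_correlations()] result used to record the
#'   realised per-class mean correlation sign.
#' @return Data frame of class `signature_definition` (`gene`, `probe`,
#'   `sd`), plus attribute `direction` (class x gene sign matrix) when `gd`
#'   is supplied.
#' @export
collapse_probes_to_genes <- function(probes, annotation, expr, gd = NULL) {
  if (!length(probes)) {
    warning("collapse_probes_to_genes: empty probe set")
    return(structure(data.frame(gene = character(), probe = character(),
                                sd = numeric(), stringsAsFactors = FALSE),
                     class = c("signature_definition", "data.frame")))
  }
  idx <- match(probes, annotation$probe)
  if (anyNA(idx)) stop_ivs("collapse_probes_to_genes: unannotated probe(s): %s",
                           paste(probes[is.na(idx)], collapse = ", "))
  genes <- annotation$gene_symbol[idx]
  sds <- apply(expr$values[probes, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  df <- data.frame(gene = genes, probe = probes, sd = as.vector(sds),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene, -df$sd, df$probe), , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("signature_definition", "data.frame"))
  if (!is.null(gd)) {
    cls <- unique(gd$drug_info$mechanism_class)
    dir <- sapply(df$probe, function(p) {
      vapply(cls, function(cl) {
        dr <- gd$drug_info$drug_id[gd$drug_info$mechanism_class == cl]
        sign(mean(gd$r[p, dr], na.rm = TRUE))
      }, numeric(1))
    })
    dir <- matrix(dir, nrow = length(cls),
                  dimnames = list(cls, df$gene))
    attr(out, "direction") <- dir
  }
  out
}

#' Unweighted-mean risk score with threshold dichotomisation
#'
#' The risk score of a sample is the arithmetic mean of its signature-gene
#' expression values (optionally per-gene z-scored within the cohort first).
#' Samples are split into high/low groups at the cohort mean (or median) of
#' the scores; the threshold is recorded.
#'
#' @param expr Numeric genes x samples matrix (rownames = signature genes),
#'   or an [expression_matrix()] restricted to the signature genes.
#' @param genes Signature gene names; every gene must be present for every
#'   sample.
#' @param standardize Per-gene z-score before averaging (default `FALSE`).
#' @param threshold_rule `"mean"` (default) or `"median"`.
#' @return Data frame (`sample_id`, `score`, `group`) with attribute
#'   `threshold`.
#' @export
compute_risk_score <- function(expr, genes, standardize = FALSE,
                               threshold_rule = c("mean", "median")) {
  threshold_rule <- match.arg(threshold_rule)
  X <- if (inherits(expr, "expr_matrix")) expr$values else expr
  miss <- setdiff(genes, rownames(X))
  if (length(miss)) stop_ivs("compute_risk_score: missing gene(s): %s",
                             paste(miss, collapse = ", "))
  X <- X[genes, , drop = FALSE]
  if (anyNA(X)) {
    bad <- rownames(X)[apply(X, 1L, anyNA)]
    stop_ivs("compute_risk_score: missing values for gene(s): %s",
             paste(bad, collapse = ", "))
  }
  if (standardize) X <- t(scale(t(X)))
  score <- colMeans(X)
  thr <- if (threshold_rule == "mean") mean(score) else stats::median(score)
  out <- data.frame(sample_id = colnames(X), score = as.vector(score),
                    group = ifelse(score > thr, "high", "low"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- thr
  attr(out, "threshold_rule") <- threshold_rule
  out
}
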