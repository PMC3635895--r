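#' Invasion heterogeneity statistics by tissue group
#'
#' Group means of invaded cell counts (ICC), per-line deviations from the
#' group mean (the ingredients of the deviation histogram), and a one-way
#' ANOVA for equality of group means computed on the raw ICC scale.
#' Groups with a single cell line carry no within-group information and are
#' excluded with a warning.
#'
#' @param profile An [invasion_profile()].
#' @return List with `group_means` (data frame), `deviations` (data frame of
#'   cell line, group, deviation from group mean), `F`, `p`, `df`.
#' @export
invasion_group_stats <- function(profile) {
  sizes <- table(profile$tissue_group)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning(sprintf("excluding %d tissue group(s) of size 1: %s",
                    length(singletons), paste(singletons, collapse = ", ")))
    profile <- profile[!profile$tissue_group %in% singletons, , drop = FALSE]
  }
  groups <- unique(profile$tissue_group)
  if (length(groups) < 2) stop_ivs("invasion_group_stats: need >= 2 groups of size >= 2")

  gm <- tapply(profile$icc, profile$tissue_group, mean)
  grand <- mean(profile$icc)
  n <- nrow(profile)
  k <- length(gm)
  ni <- as.vector(table(profile$tissue_group)[names(gm)])
  ssb <- sum(ni * (gm - grand)^2)
  dev <- profile$icc - gm[profile$tissue_group]
  ssw <- sum(dev^2)
  df1 <- k - 1L
  df2 <- n - k
  msb <- ssb / df1
  msw <- ssw / df2
  Fstat <- if (msw == 0 && msb == 0) 0 else msb / msw
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(group_means = data.frame(tissue_group = names(gm), n = ni,
                                mean_icc = as.vector(gm), row.names = NULL),
       deviations = data.frame(cell_line = profile$cell_line,
                               tissue_group = profile$tissue_group,
                               deviation = as.vector(dev)),
       F = Fstat, p = p, df = c(df1, df2))
}

#' Correlate every probe with a phenotype profile
#'
#' Pearson correlation of each probe row against a phenotype vector over the
#' shared samples, with a two-sided p-value from the t distribution on
#' `n_used - 2` degrees of freedom. By default both the expression rows and
#' the phenotype are normal-scored first ([normal_score_transform()]);
#' correlations use pairwise-complete observations. Probes with fewer than
#' three complete pairs, or zero variance, are dropped (and logged).
#'
#' @param expr An [expression_matrix()].
#' @param phenotype Named numeric vector over samples (names matched against
#'   the matrix's sample IDs), or unnamed of matching length.
#' @param transform Logical: apply the normal score transform to expression
#'   rows and phenotype before correlating (default `TRUE`).
#' @return Data frame (`item_id`, `r`, `p_two_sided`, `n_used`), one row per
#'   retained probe.
#' @export
correlate_profile <- function(expr, phenotype, transform = TRUE) {
  X <- expr$values
  if (!is.null(names(phenotype))) {
    shared <- intersect(colnames(X), names(phenotype))
    if (length(shared) < 3) stop_ivs("correlate_profile: < 3 shared samples")
    X <- X[, shared, drop = FALSE]
    phenotype <- phenotype[shared]
  } else if (length(phenotype) != ncol(X)) {
    stop_ivs("correlate_profile: phenotype length %d != %d samples",
             length(phenotype), ncol(X))
  }
  y <- as.numeric(phenotype)
  if (transform) {
    X <- normal_score_rows(X)
    y <- as.numeric(normal_score_transform(y))
  }
  res <- row_pearson(X, y)
  keep <- !is.na(res$r)
  if (any(!keep)) {
    ivs_log("INFO", "correlate_profile: dropped %d probe(s) (constant or < 3 complete pairs)",
            sum(!keep))
  }
  data.frame(item_id = rownames(X)[keep], r = res$r[keep],
             p_two_sided = res$p[keep], n_used = res$n[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confirmation-stage false discovery rate estimate
#'
#' Closed-form estimate for a two-stage screen: if `m` probes enter the
#' confirmation stage and are tested at one-sided level `alpha` (with the
#' sign-consistency requirement), then `m * alpha` passes are expected under
#' the null, so `FDR = m * alpha / k` for `k` observed passes.
#'
#' @param m_confirm_tested Number of probes tested at confirmation.
#' @param alpha_confirm One-sided confirmation level (sign-consistent).
#' @param k_passed Number of probes passing confirmation.
#' @return List (`m_confirm_tested`, `alpha_confirm`, `k_passed`, `fdr`).
#' @examples
#' estimate_confirmation_fdr(2417, 0.025, 744)$fdr  # ~0.0812
#' @export
estimate_confirmation_fdr <- function(m_confirm_tested, alpha_confirm, k_passed) {
  stopifnot(m_confirm_tested >= 0, alpha_confirm > 0, alpha_confirm < 1)
  fdr <- if (k_passed > 0) m_confirm_tested * alpha_confirm / k_passed else NA_real_
  list(m_confirm_tested = as.integer(m_confirm_tested),
       alpha_confirm = alpha_confirm,
       k_passed = as.integer(k_passed),
       fdr = fdr)
}

#' Two-stage sign-consistent invasion-associated probe selection
#'
#' Stage 1 (discovery) retains probes whose two-sided correlation p-value on
#' the discovery platform is below `p_disc`. Stage 2 (confirmation) retains a
#' discovery probe when its best mapped partner on the confirmation platform
#' -- the partner with the largest `|r_confirm|` among those with
#' `sign(r_confirm) == sign(r_discovery)` -- has a two-sided p-value below
#' `2 * p_conf`. The combination is equivalent to a one-sided test at level
#' `p_conf` in the direction fixed by the discovery stage. The FDR estimate
#' uses `m` = probes entering confirmation (stage-1 survivors with at least
#' one mapped partner), `alpha = p_conf`, `k` = probes passing.
#'
#' @param records_discovery,records_confirm Outputs of [correlate_profile()]
#'   for the discovery and confirmation platforms.
#' @param pairs Matched probe pairs (see [match_probes()]).
#' @param p_disc Two-sided discovery threshold (default 0.05).
#' @param p_conf One-sided confirmation threshold (default 0.025).
#' @return List with `table` (the IA gene table: `probe_discovery`,
#'   `probe_confirm`, `gene_symbol`, `r_discovery`, `p_discovery`,
#'   `r_confirm`, `p_confirm`, `direction`) and `fdr`
#'   (an [estimate_confirmation_fdr()] result, or `NA` fields when stage 1 is
#'   empty).
#' @export
two_stage_ia_selection <- function(records_discovery, records_confirm, pairs,
                                   p_disc = 0.05, p_conf = 0.025) {
  stopifnot(p_disc > 0, p_disc < 1, p_conf > 0, p_conf < 1)
  disc <- records_discovery[records_discovery$p_two_sided < p_disc, , drop = FALSE]
  empty <- data.frame(probe_discovery = character(), probe_confirm = character(),
                      gene_symbol = character(), r_discovery = numeric(),
                      p_discovery = numeric(), r_confirm = numeric(),
                      p_confirm = numeric(), direction = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(disc) == 0) {
    ivs_log("WARN", "two_stage_ia_selection: empty discovery set, FDR undefined")
    return(list(table = empty,
                fdr = list(m_confirm_tested = 0L, alpha_confirm = p_conf,
                           k_passed = 0L, fdr = NA_real_)))
  }
  conf_idx <- match(pairs$probe_b, records_confirm$item_id)
  has_conf <- !is.na(conf_idx)
  pr <- pairs[has_conf, , drop = FALSE]
  conf <- records_confirm[conf_idx[has_conf], , drop = FALSE]

  di <- match(pr$probe_a, disc$item_id)
  inplay <- !is.na(di)
  pr <- pr[inplay, , drop = FALSE]
  conf <- conf[inplay, , drop = FALSE]
  di <- di[inplay]

  m <- length(unique(pr$probe_a))
  if (m == 0) {
    ivs_log("WARN", "two_stage_ia_selection: no stage-1 probe has a mapped partner")
    return(list(table = empty,
                fdr = list(m_confirm_tested = 0L, alpha_confirm = p_conf,
                           k_passed = 0L, fdr = NA_real_)))
  }

  cand <- data.frame(probe_discovery = pr$probe_a, probe_confirm = pr$probe_b,
                     gene_symbol = pr$gene_symbol,
                     r_discovery = disc$r[di], p_discovery = disc$p_two_sided[di],
                     r_confirm = conf$r, p_confirm = conf$p_two_sided,
                     stringsAsFactors = FALSE)
  same_sign <- sign(cand$r_confirm) == sign(cand$r_discovery) & cand$r_confirm != 0
  cand <- cand[same_sign, , drop = FALSE]
  if (nrow(cand)) {
    # best partner per discovery probe: largest |r_confirm| with matching sign
    ord <- order(cand$probe_discovery, -abs(cand$r_confirm), cand$probe_confirm)
    cand <- cand[ord, , drop = FALSE]
    cand <- cand[!duplicated(cand$probe_discovery), , drop = FALSE]
    cand <- cand[cand$p_confirm < 2 * p_conf, , drop = FALSE]
  }
  cand$direction <- as.integer(sign(cand$r_discovery))
  rownames(cand) <- NULL
  k <- nrow(cand)
  fdr <- estimate_confirmation_fdr(m, p_conf, k)
  if (k == 0) fdr$fdr <- NA_real_
  ivs_log("INFO", "two_stage_ia_selection: m=%d entered confirmation, k=%d passed, FDR=%s",
          m, k, format(fdr$fdr, digits = 3))
  list(table = cand, fdr = fdr)
}

#' Partition an IA table by correlation sign
#'
#' Splits invasion-associated probes into the negatively and positively
#' invasion-correlated panels, each ordered by decreasing `|r_discovery|`.
#'
#' @param table IA gene table from [two_stage_ia_selection()].
#' @return List (`negative`, `positive`) of disjoint data frames whose union
#'   is the input.
#' @export
partition_by_sign <- function(table) {
  if (nrow(table) == 0) stop_ivs("partition_by_sign: empty IA table")
  ord <- order(-abs(table$r_discovery))
  tb <- table[ord, , drop = FALSE]
  list(negative = tb[tb$direction < 0, , drop = FALSE],
       positive = tb[tb$direction > 0, , drop = FALSE])
}
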