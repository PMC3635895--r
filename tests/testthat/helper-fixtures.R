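# In-code fixture builders shared across test files.

tiny_expr <- function(values, platform = "A",
                      probes = sprintf("P%d", seq_len(nrow(values))),
                      samples = sprintf("S%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(probes, samples)
  expression_matrix(values, platform)
}

random_expr <- function(n_probes, n_samples, platform = "A", seed = 1) {
  set.seed(seed)
  tiny_expr(matrix(rnorm(n_probes * n_samples), n_probes, n_samples),
            platform = platform)
}

tiny_drug_panel <- function(values, classes,
                            drugs = sprintf("D%d", seq_len(nrow(values))),
                            lines = sprintf("S%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(drugs, lines)
  drug_panel(values, classes)
}

# A gene-drug result built directly from matrices (bypasses correlation).
fake_gd <- function(r, p, classes) {
  n <- matrix(50, nrow(r), ncol(r), dimnames = dimnames(r))
  list(r = r, p = p, n = n,
       drug_info = data.frame(drug_id = colnames(r),
                              mechanism_class = classes,
                              stringsAsFactors = FALSE),
       cell_lines = character())
}

# An IA-style table with the requested direction vector.
fake_ia_table <- function(directions, r_abs = NULL) {
  k <- length(directions)
  if (is.null(r_abs)) r_abs <- seq(0.9, 0.3, length.out = k)
  data.frame(probe_discovery = sprintf("A_%03d", seq_len(k)),
             probe_confirm = sprintf("B_%03d", seq_len(k)),
             gene_symbol = sprintf("G%03d", seq_len(k)),
             r_discovery = r_abs * directions,
             p_discovery = rep(0.001, k),
             r_confirm = r_abs * directions,
             p_confirm = rep(0.001, k),
             direction = as.integer(directions),
             stringsAsFactors = FALSE)
}
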