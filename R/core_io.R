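## Domain containers ---------------------------------------------------------

#' Construct an expression matrix
#'
#' A light container: a numeric probes x samples matrix (log2-intensity
#' scale) plus a platform tag. Probe and sample identifiers must be unique.
#'
#' @param values Numeric matrix with probe row names and sample column names.
#' @param platform_id Single label identifying the array platform.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `platform_id`.
#' @export
expression_matrix <- function(values, platform_id) {
  stopifnot(is.matrix(values), length(platform_id) == 1L)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_ivs("expression_matrix: values must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop_ivs("expression_matrix: duplicate probe ID '%s'", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop_ivs("expression_matrix: duplicate sample ID '%s'", dup)
  }
  structure(list(values = values, platform_id = as.character(platform_id)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d probes x %d samples (%d missing)\n",
              x$platform_id, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Construct a drug sensitivity panel
#'
#' @param sensitivity Numeric drugs x cell-lines matrix of -log10 GI50 (or
#'   -log10 IC50) values; missing entries allowed.
#' @param mechanism_class Character vector, one mechanism label per drug.
#' @return Object of class `drug_panel` with elements `sensitivity` and
#'   `info` (data frame `drug_id`, `mechanism_class`).
#' @export
drug_panel <- function(sensitivity, mechanism_class) {
  stopifnot(is.matrix(sensitivity), nrow(sensitivity) == length(mechanism_class))
  if ((nrow(sensitivity) > 0 && is.null(rownames(sensitivity))) ||
      (ncol(sensitivity) > 0 && is.null(colnames(sensitivity)))) {
    stop_ivs("drug_panel: sensitivity must carry drug rownames and cell-line colnames")
  }
  if (anyDuplicated(rownames(sensitivity))) {
    stop_ivs("drug_panel: duplicate drug_id '%s'",
             rownames(sensitivity)[duplicated(rownames(sensitivity))][1])
  }
  structure(list(sensitivity = sensitivity,
                 info = data.frame(drug_id = rownames(sensitivity) %||% character(),
                                   mechanism_class = as.character(mechanism_class),
                                   stringsAsFactors = FALSE)),
            class = "drug_panel")
}

#' @export
print.drug_panel <- function(x, ...) {
  cat(sprintf("drug_panel: %d drugs x %d cell lines; classes: %s\n",
              nrow(x$sensitivity), ncol(x$sensitivity),
              paste(unique(x$info$mechanism_class), collapse = ", ")))
  invisible(x)
}

#' Construct an invasion profile
#'
#' @param cell_line Unique cell-line labels.
#' @param icc Non-negative invaded cell counts (replicate means).
#' @param tissue_group Tissue-of-origin label per line.
#' @return Data frame of class `invasion_profile`.
#' @export
invasion_profile <- function(cell_line, icc, tissue_group) {
  if (anyDuplicated(cell_line)) {
    stop_ivs("invasion_profile: duplicate cell_line '%s'",
             cell_line[duplicated(cell_line)][1])
  }
  if (any(is.na(icc)) || any(icc < 0)) {
    stop_ivs("invasion_profile: icc must be non-negative and non-missing")
  }
  structure(data.frame(cell_line = as.character(cell_line),
                       icc = as.numeric(icc),
                       tissue_group = as.character(tissue_group),
                       stringsAsFactors = FALSE),
            class = c("invasion_profile", "data.frame"))
}

#' Construct a clinical cohort table
#'
#' @param df Data frame with columns `patient_id`, `time` (months, > 0),
#'   `event` (0/1), plus covariate and signature-gene columns.
#' @param covariate_cols Names of covariate columns.
#' @param gene_cols Names of signature-gene expression columns.
#' @return Data frame of class `cohort_table` with attributes
#'   `covariate_cols` and `gene_cols`.
#' @export
cohort_table <- function(df, covariate_cols = character(), gene_cols = character()) {
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ivs("cohort_table: missing required column(s): %s",
                             paste(miss, collapse = ", "))
  if (any(df$time <= 0, na.rm = TRUE) || any(is.na(df$time))) {
    stop_ivs("cohort_table: time must be positive and non-missing")
  }
  if (!all(df$event %in% c(0, 1))) {
    stop_ivs("cohort_table: event must be 0 or 1")
  }
  extra <- setdiff(c(covariate_cols, gene_cols), names(df))
  if (length(extra)) stop_ivs("cohort_table: declared column(s) absent: %s",
                              paste(extra, collapse = ", "))
  structure(as.data.frame(df), covariate_cols = covariate_cols,
            gene_cols = gene_cols, class = c("cohort_table", "data.frame"))
}

## Readers -------------------------------------------------------------------

#' Read a tab-delimited expression matrix
#'
#' Expects a header row `probe_id<TAB>sample1<TAB>...` and one row per probe.
#' The literal token `NA` marks a missing cell; any other non-numeric cell is
#' a hard error naming its position.
#'
#' @param path Path to the tab-delimited file.
#' @param platform_id Platform tag to attach.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, platform_id) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2) stop_ivs("read_expression_matrix: no sample columns in %s", path)
  probes <- raw[[1]]
  if (anyDuplicated(probes)) {
    stop_ivs("read_expression_matrix: duplicate probe ID '%s' in %s",
             probes[duplicated(probes)][1], path)
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  bad <- cells != "NA" & is.na(suppressWarnings(array(as.numeric(cells), dim(cells))))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_ivs("read_expression_matrix: non-numeric cell '%s' at probe '%s', sample '%s'",
             cells[idx[1], idx[2]], probes[idx[1]], colnames(cells)[idx[2]])
  }
  vals <- array(suppressWarnings(as.numeric(cells)), dim(cells))
  dimnames(vals) <- list(probes, colnames(cells))
  expression_matrix(vals, platform_id)
}

#' Write an expression matrix in the format [read_expression_matrix()] reads
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(probe_id = probe_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cross-platform probe map
#'
#' CSV with columns `probe_a`, `probe_b`, `gene_symbol`. Many-to-many
#' mappings are allowed; exact duplicate `(probe_a, probe_b)` pairs are not.
#'
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_a", "probe_b", "gene_symbol")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ivs("read_probe_map: missing column(s): %s",
                             paste(miss, collapse = ", "))
  key <- paste(df$probe_a, df$probe_b, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop_ivs("read_probe_map: duplicate pair (%s, %s)", d$probe_a, d$probe_b)
  }
  df[need]
}

#' Read an invasion profile CSV (`cell_line, icc, tissue_group`)
#' @param path CSV path.
#' @return An [invasion_profile()].
#' @export
read_invasion_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_line", "icc", "tissue_group"), names(df))
  if (length(miss)) stop_ivs("read_invasion_profile: missing column(s): %s",
                             paste(miss, collapse = ", "))
  invasion_profile(df$cell_line, df$icc, df$tissue_group)
}

#' Read a drug panel CSV (`drug_id, mechanism_class`, then cell-line columns)
#' @param path CSV path.
#' @return A [drug_panel()].
#' @export
read_drug_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("drug_id", "mechanism_class"), names(df))
  if (length(miss)) stop_ivs("read_drug_panel: missing column(s): %s",
                             paste(miss, collapse = ", "))
  lines <- setdiff(names(df), c("drug_id", "mechanism_class"))
  if (!length(lines)) stop_ivs("read_drug_panel: no cell-line columns")
  sens <- as.matrix(df[, lines, drop = FALSE])
  mode(sens) <- "numeric"
  rownames(sens) <- df$drug_id
  drug_panel(sens, df$mechanism_class)
}

#' Write a drug panel in the format [read_drug_panel()] reads
#' @param panel A [drug_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_panel <- function(panel, path) {
  df <- data.frame(drug_id = panel$info$drug_id,
                   mechanism_class = panel$info$mechanism_class,
                   panel$sensitivity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort CSV
#'
#' Columns `patient_id`, `time`, `event` are required; covariate and gene
#' columns are declared by the caller and validated. Undeclared extra columns
#' are preserved as opaque covariates.
#'
#' @param path CSV path.
#' @param covariate_cols,gene_cols Declared column names.
#' @return A [cohort_table()].
#' @export
read_cohort_table <- function(path, covariate_cols = character(),
                              gene_cols = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- c("patient_id", "time", "event", covariate_cols, gene_cols)
  opaque <- setdiff(names(df), known)
  cohort_table(df, covariate_cols = union(covariate_cols, opaque),
               gene_cols = gene_cols)
}
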