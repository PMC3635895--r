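#' @keywords internal
"_PACKAGE"

## Logging ------------------------------------------------------------------

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Set or query the logging threshold
#'
#' Messages below the threshold are suppressed. All log output goes to
#' standard error so that result streams stay clean.
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return The previous level, invisibly.
#' @export
ivs_log_level <- function(level = NULL) {
  old <- getOption("invasig.log_level", "INFO")
  if (!is.null(level)) {
    level <- match.arg(level, names(.log_levels))
    options(invasig.log_level = level)
  }
  invisible(old)
}

ivs_log <- function(level, fmt, ...) {
  thr <- .log_levels[[getOption("invasig.log_level", "INFO")]]
  if (.log_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

## Pearson correlation engine ------------------------------------------------

# Row-wise Pearson correlation of a matrix against one profile, pairwise
# complete, with two-sided p from the t distribution on n - 2 df.  Missing
# values are handled by masking, so a single pass of matrix products covers
# probes with arbitrary missingness patterns.
row_pearson <- function(X, y, min_n = 3L) {
  stopifnot(is.matrix(X), ncol(X) == length(y))
  okX <- !is.na(X)
  oky <- !is.na(y)
  M <- okX & rep(oky, each = nrow(X))
  X0 <- ifelse(M, X, 0)
  y0 <- ifelse(oky, y, 0)
  n  <- rowSums(M)
  sx  <- rowSums(X0)
  sy  <- as.vector(M %*% y0)
  sxy <- as.vector(X0 %*% y0)
  sxx <- rowSums(X0 * X0)
  syy <- as.vector(M %*% (y0 * y0))
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  denom <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(n >= min_n & denom > 0, (n * sxy - sx * sy) / denom, NA_real_)
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(is.na(r), NA_real_, 2 * stats::pt(-abs(tt), df))
  list(r = r, p = p, n = n)
}

# Scalar Pearson with the same conventions; used where vectorisation is moot.
pearson_one <- function(x, y, min_n = 3L) {
  res <- row_pearson(matrix(x, nrow = 1), y, min_n = min_n)
  list(r = res$r[1], p = res$p[1], n = res$n[1])
}

## Misc ----------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ivs <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Seed streams: derive reproducible child seeds from one master seed while
# keeping every derived value inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
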