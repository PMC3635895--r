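# Independent brute-force oracles. These re-derive each statistic from
# explicit sums or enumeration and must stay free of the package code paths
# they check.

pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), n = n)
}

welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

anova_oracle <- function(values, groups) {
  gm <- tapply(values, groups, mean)
  ni <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ni * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- length(gm) - 1
  df2 <- length(values) - length(gm)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Product-limit estimate at each distinct event time, one group.
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, survival = surv)
}

# Two-group log-rank via the O - E / hypergeometric-variance sums.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  tt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    at1 <- sum(time >= t & g == 1)
    at2 <- sum(time >= t & g == 2)
    n <- at1 + at2
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * at1 / n
    if (n > 1) V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE), o_minus_e = O - E)
}

# Grid-search maximiser of the (Breslow; no ties expected) Cox log partial
# likelihood for a single covariate.
cox_grid_oracle <- function(time, event, x, lo = -4, hi = 4, step = 1e-4) {
  loglik <- function(beta) {
    eta <- beta * x
    lp <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      lp <- lp + eta[i] - log(sum(exp(eta[risk])))
    }
    lp
  }
  grid <- seq(lo, hi, by = step)
  grid[which.max(vapply(grid, loglik, numeric(1)))]
}

# Normal-score correlation recomputed from raw ranks (brute-force rank
# oracle): qnorm(rank/(n+1)) on each side then explicit-sum Pearson.
rank_normal_corr_oracle <- function(x, y) {
  n <- length(x)
  qx <- qnorm(rank(x) / (n + 1))
  qy <- qnorm(rank(y) / (n + 1))
  pearson_oracle(qx, qy)$r
}
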