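#' Iterative Grubbs outlier detection
#'
#' Repeatedly applies the two-sided Grubbs test to a vector, removing the
#' single most extreme value whenever its Grubbs statistic exceeds the
#' critical value at the requested significance level, until no outlier
#' remains or fewer than 3 values are left.
#'
#' @param x numeric vector.
#' @param alpha significance level per iteration.
#' @return Integer indices (into `x`) of the values flagged as outliers, in
#'   removal order; `integer(0)` when none.
#' @examples
#' grubbs_outliers(c(rnorm(20), 25))
#' @export
grubbs_outliers <- function(x, alpha = 0.05) {
  stopifnot(is.numeric(x))
  keep <- which(!is.na(x))
  removed <- integer(0)
  while (length(keep) >= 3) {
    v <- x[keep]
    n <- length(v)
    s <- stats::sd(v)
    if (s == 0) break
    g <- abs(v - mean(v)) / s
    i <- which.max(g)
    # two-sided critical value from the t quantile at alpha/(2n)
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (g[i] > gcrit) {
      removed <- c(removed, keep[i])
      keep <- keep[-i]
    } else break
  }
  removed
}

# first run of at least min_len consecutive TRUEs; returns c(start, length)
# of the first such run or NULL
first_long_run <- function(flags, min_len) {
  if (!any(flags)) return(NULL)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_len)
  if (!length(ok)) return(NULL)
  c(starts[ok[1]], r$lengths[ok[1]])
}

# weighted central moments: mean, sd, skewness, excess-free kurtosis
weighted_moments <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  if (v <= 0) return(c(mean = m, sd = 0, skew = 0, kurt = 3))
  s <- sqrt(v)
  c(mean = m, sd = s,
    skew = sum(w * ((x - m) / s)^3),
    kurt = sum(w * ((x - m) / s)^4))
}

# Pearson r and two-sided p via the t transform, vectorised over columns of y
fast_pearson <- function(x, y) {
  y <- as.matrix(y)
  n <- length(x)
  r <- as.vector(stats::cor(x, y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

# Spearman rho with t-approximate p, vectorised over columns of y
fast_spearman <- function(x, y) {
  y <- as.matrix(y)
  fast_pearson(rank(x), apply(y, 2, rank))
}
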