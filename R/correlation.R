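#' Trial-by-trial correlation with automatic method choice
#'
#' Applies the package-wide correlation rule: after iterative Grubbs outlier
#' removal (on each variable separately; a trial flagged in either variable
#' is dropped from the pair), Pearson's r is used when at least 30 pairs
#' remain and both variables pass a Shapiro-Wilk normality test at the same
#' alpha; otherwise Spearman's rho.
#'
#' @param x,y paired per-trial metrics.
#' @param alpha significance level for the Grubbs and normality tests.
#' @param min_pearson_n minimum n for Pearson's r.
#' @return List: `r`, `p`, `method` ("pearson"/"spearman"), `n` (pairs
#'   used), `removed` (indices dropped as outliers), `defined` (`FALSE` for
#'   constant input, in which case `r` is `NA`).
#' @export
trial_correlation <- function(x, y, alpha = 0.05, min_pearson_n = 30) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  removed <- union(grubbs_outliers(x, alpha), grubbs_outliers(y, alpha))
  if (length(removed)) { x <- x[-removed]; y <- y[-removed] }
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, method = NA_character_,
                n = n, removed = removed, defined = FALSE))
  normal <- n >= 3 && n <= 5000 &&
    stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  method <- if (n >= min_pearson_n && normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method, n = n,
       removed = removed, defined = TRUE)
}

#' Trial-by-trial spike-eyelid correlation matrix
#'
#' Divides the trial timespan into `bin_ms` bins, averages the spike rate
#' and the eyelid signal within each bin per trial, and correlates every
#' spike bin with every eyelid bin across trials. With a 2 s window and
#' 20 ms bins this yields a 100 x 100 matrix; entry `[i, j]` is the Pearson
#' correlation between spike bin `i` and eyelid bin `j`.
#'
#' @param spike_rate matrix of single-trial SDFs, 1 ms bins x trials (Hz).
#' @param eyelid_pos matrix of eyelid traces, samples x trials (% closure).
#' @param eyelid_time eyelid sample times, ms.
#' @param bin_ms bin size, ms.
#' @param lead which eyelid signal the matrix was built on ("position" or
#'   "velocity"); metadata only.
#' @return A `corr_matrix`: list with `r` (spike bins x eyelid bins),
#'   `bin_ms`, `centers` (bin centers, ms), `n_trials`, `lead`. Degenerate
#'   (zero-variance) bins give `NA` rows/columns.
#' @export
correlation_matrix <- function(spike_rate, eyelid_pos, eyelid_time,
                               bin_ms = 20, lead = "position") {
  stopifnot(is.matrix(spike_rate), is.matrix(eyelid_pos),
            ncol(spike_rate) == ncol(eyelid_pos))
  n_trials <- ncol(spike_rate)
  n_bins <- nrow(spike_rate) %/% bin_ms
  sb <- bin_means(spike_rate, (seq_len(nrow(spike_rate)) - 1) %/% bin_ms,
                  n_bins)
  eb <- bin_means(eyelid_pos, floor(eyelid_time / bin_ms), n_bins)
  r <- suppressWarnings(stats::cor(t(sb), t(eb)))
  structure(list(r = r, bin_ms = bin_ms,
                 centers = (seq_len(n_bins) - 0.5) * bin_ms,
                 n_trials = n_trials, lead = lead),
            class = "corr_matrix")
}

# per-trial means of rows grouped into bins 0..n_bins-1
bin_means <- function(m, bin_of_row, n_bins) {
  keep <- bin_of_row >= 0 & bin_of_row < n_bins
  g <- factor(bin_of_row[keep], levels = 0:(n_bins - 1))
  apply(m[keep, , drop = FALSE], 2, function(col) tapply(col, g, mean))
}

#' Average correlation matrices with sign nullification
#'
#' Before averaging, entries of the sign opposite to the sign of interest
#' are set to zero in every matrix; `NA` entries are excluded from the mean.
#'
#' @param matrices list of [`corr_matrix`][correlation_matrix] objects with
#'   matching grids.
#' @param sign `"positive"` or `"negative"`.
#' @return A `corr_matrix` with the averaged r-values.
#' @export
average_matrices <- function(matrices, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(length(matrices) >= 1)
  dims <- vapply(matrices, function(m) dim(m$r), integer(2))
  if (any(dims != dims[, 1])) stop("matrices have mismatched grids")
  arr <- vapply(matrices, function(m) {
    r <- m$r
    if (sign == "positive") r[!is.na(r) & r < 0] <- 0
    else r[!is.na(r) & r > 0] <- 0
    r
  }, matrices[[1]]$r)
  out <- matrices[[1]]
  out$r <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  out$r[is.nan(out$r)] <- NA_real_
  out$n_matrices <- length(matrices)
  out
}

#' Temporal cross-correlation between average spike and eyelid traces
#'
#' Correlates the average eyelid trace at time `t` with the average spike
#' trace at `t - lag` across the CS-onset-to-US-onset window, for every lag
#' on a 1 ms grid; the best lag maximizes the Pearson correlation. Positive
#' lags mean spikes lead the eyelid. The eyelid trace is resampled from its
#' 4 ms grid to 1 ms by linear interpolation.
#'
#' @param avg_spike trial-averaged SDF: an [`sdf_trace`][average_sdf] or a
#'   numeric per-ms vector.
#' @param eyelid_time,avg_eyelid average eyelid trace and its time grid, ms.
#' @param timing a [stimulus_timing()].
#' @param lag_range searched lags, ms.
#' @return A `lag_estimate`: `best_lag` (ms), `peak_r`, `lags`, `r`.
#' @export
temporal_cross_correlation <- function(avg_spike, eyelid_time, avg_eyelid,
                                       timing, lag_range = c(-200, 200)) {
  rate <- if (inherits(avg_spike, "sdf_trace")) avg_spike$rate else avg_spike
  tgrid <- seq_len(length(rate)) - 0.5
  ey <- stats::approx(eyelid_time, avg_eyelid, xout = tgrid, rule = 2)$y
  win <- which(tgrid >= timing$cs_onset & tgrid <= timing$us_onset)
  lags <- seq(lag_range[1], lag_range[2])
  if (min(win) - max(lags) < 1 || max(win) - min(lags) > length(rate))
    stop("trace too short for the requested lag range")
  r <- vapply(lags, function(L) stats::cor(ey[win], rate[win - L]), 0)
  best <- which.max(r)
  structure(list(best_lag = lags[best], peak_r = r[best],
                 lags = lags, r = r),
            class = "lag_estimate")
}

#' Bootstrap test for the population count of significant cells
#'
#' Tests how improbable the observed number of cells with a significant,
#' direction-consistent trial-by-trial correlation is under the null of no
#' spike-behavior pairing. Each repetition permutes the behavior vector
#' within every cell (preserving both marginals and per-cell trial counts),
#' recomputes the per-cell correlations, and records the count of
#' significant cells of the requested direction; the empirical p-value is
#' the fraction of repetitions whose count reaches the observed one.
#'
#' The observed count uses [trial_correlation()] in full (Grubbs removal
#' and the Pearson/Spearman rule); repetitions reuse each cell's chosen
#' method and outlier-cleaned trials, with t-approximate p-values, so that
#' 500 repetitions over many cells stay fast.
#'
#' @param cells list of cells, each a list/data frame with `x` (spike
#'   metric) and `y` (behavior metric) per trial.
#' @param alpha per-cell significance level.
#' @param reps number of bootstrap repetitions.
#' @param direction `"positive"`, `"negative"`, or `"either"`.
#' @param seed optional integer seed for the permutations.
#' @return A `bootstrap_result`: `observed` (count), `p` (resolution
#'   `1/reps`), `p_label` (reported as `"< 1/reps"` when no repetition
#'   reaches the observed count), `null_counts`, `reps`, `per_cell`.
#' @export
bootstrap_population_test <- function(cells, alpha = 0.05, reps = 500,
                                      direction = c("positive", "negative",
                                                    "either"),
                                      seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(cells) >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))

  dir_ok <- function(r) switch(direction,
                               positive = r > 0, negative = r < 0,
                               either = TRUE)
  per_cell <- lapply(cells, function(cl) {
    res <- trial_correlation(cl$x, cl$y, alpha = alpha)
    x <- cl$x; y <- cl$y
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(res$removed)) { x <- x[-res$removed]; y <- y[-res$removed] }
    list(res = res, x = x, y = y,
         sig = isTRUE(res$defined && res$p < alpha && dir_ok(res$r)))
  })
  observed <- sum(vapply(per_cell, `[[`, logical(1), "sig"))

  null_counts <- integer(reps)
  sig_mat <- vapply(per_cell, function(pc) {
    n <- length(pc$x)
    if (n < 3 || !pc$res$defined) return(logical(reps))
    perm <- replicate(reps, sample.int(n))
    ymat <- matrix(pc$y[perm], nrow = n)
    fp <- if (identical(pc$res$method, "pearson")) fast_pearson(pc$x, ymat)
          else fast_spearman(pc$x, ymat)
    fp$p < alpha & dir_ok(fp$r)
  }, logical(reps))
  null_counts <- rowSums(sig_mat)

  p <- mean(null_counts >= observed)
  structure(
    list(observed = observed, p = p,
         p_label = if (p == 0) sprintf("< %g", 1 / reps) else format(p),
         null_counts = null_counts, reps = reps,
         per_cell = lapply(per_cell, `[[`, "res")),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %d significant cells observed, p %s (%d reps)\n",
              x$observed, x$p_label, x$reps))
  invisible(x)
}

#' Pooled per-cell slope (two-stage random-slopes estimate)
#'
#' Fits an ordinary least-squares slope per cell, then combines the slopes
#' with an inverse-variance-weighted random-effects meta-analysis
#' (DerSimonian-Laird between-cell variance). This is a two-stage
#' approximation to a linear mixed model with random intercepts and slopes;
#' it agrees with the mixed model when per-cell information is balanced.
#'
#' @param cells list of cells with per-trial `x` and `y`.
#' @return List: `slope` (pooled, y-units per x-unit), `se`, `tau2`
#'   (between-cell variance; `NA` with a single cell), `n_cells`,
#'   `per_cell` (data frame of slopes and SEs), `excluded` (cells with
#'   singular fits).
#' @export
pooled_slope <- function(cells) {
  stopifnot(length(cells) >= 1)
  fits <- lapply(cells, function(cl) {
    ok <- stats::complete.cases(cl$x, cl$y)
    x <- cl$x[ok]; y <- cl$y[ok]
    if (length(x) < 3 || stats::sd(x) == 0) return(NULL)
    fit <- stats::lm(y ~ x)
    s <- summary(fit)$coefficients
    if (nrow(s) < 2) return(NULL)
    c(slope = s["x", "Estimate"], se = s["x", "Std. Error"])
  })
  excluded <- which(vapply(fits, is.null, TRUE))
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("no cell admits a slope fit")
  slopes <- vapply(fits, `[[`, 0, "slope")
  ses <- vapply(fits, `[[`, 0, "se")
  if (length(slopes) == 1)
    return(list(slope = slopes[[1]], se = ses[[1]], tau2 = NA_real_,
                n_cells = 1L,
                per_cell = data.frame(slope = slopes, se = ses),
                excluded = excluded, single_cell = TRUE))
  if (max(ses) < 1e-12)   # exact fits: no within-cell sampling variance
    return(list(slope = mean(slopes), se = stats::sd(slopes) / sqrt(length(slopes)),
                tau2 = stats::var(slopes), n_cells = length(slopes),
                per_cell = data.frame(slope = slopes, se = ses),
                excluded = excluded, single_cell = FALSE))
  rma <- metafor::rma(yi = slopes, vi = ses^2, method = "DL")
  list(slope = as.numeric(rma$beta), se = rma$se, tau2 = rma$tau2,
       n_cells = length(slopes),
       per_cell = data.frame(slope = slopes, se = ses),
       excluded = excluded, single_cell = FALSE)
}

#' Power and required sample size for a correlation test
#'
#' `power_correlation_test` gives the power of the two-sided test of zero
#' Pearson correlation at significance `alpha` for `n` bivariate-normal
#' observations with true correlation `r`, using the exact sampling
#' distribution of the sample correlation coefficient (numerical
#' integration of its density) or the Fisher-z normal approximation.
#' `required_trials_for_power` searches n upward for the smallest sample
#' size reaching the target power, reporting the Fisher-z answer alongside
#' the exact one.
#'
#' @param r true correlation, 0 < |r| < 1.
#' @param n sample size (>= 4).
#' @param power target power.
#' @param alpha two-sided significance level.
#' @param method `"exact"` or `"fisher"`.
#' @param n_max search cap.
#' @return `power_correlation_test`: the power (scalar).
#'   `required_trials_for_power`: list with `n` (by `method`), `n_exact`,
#'   `n_fisher`, and `power` attained at `n`.
#' @examples
#' required_trials_for_power(0.73)$n   # 12
#' required_trials_for_power(0.34)$n   # 65
#' @export
power_correlation_test <- function(r, n, alpha = 0.05, method = "exact") {
  stopifnot(abs(r) > 0, abs(r) < 1, n >= 4)
  if (method == "fisher") {
    z <- atanh(abs(r)) * sqrt(n - 3)
    q <- stats::qnorm(1 - alpha / 2)
    return(stats::pnorm(z - q) + stats::pnorm(-z - q))
  }
  tc <- stats::qt(1 - alpha / 2, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  up <- stats::integrate(dcorr, rc, 1, rho = r, n = n,
                         rel.tol = 1e-10)$value
  lo <- stats::integrate(dcorr, -1, -rc, rho = r, n = n,
                         rel.tol = 1e-10)$value
  up + lo
}

#' @rdname power_correlation_test
#' @export
required_trials_for_power <- function(r, power = 0.80, alpha = 0.05,
                                      method = "exact", n_max = 10000) {
  stopifnot(abs(r) > 0, abs(r) < 1, power > 0, power < 1)
  find_n <- function(meth) {
    for (n in 4:n_max)
      if (power_correlation_test(r, n, alpha, meth) >= power) return(n)
    stop("no n <= n_max reaches the target power")
  }
  n_exact <- find_n("exact")
  n_fisher <- find_n("fisher")
  n <- if (method == "fisher") n_fisher else n_exact
  list(n = n, n_exact = n_exact, n_fisher = n_fisher,
       power = power_correlation_test(r, n, alpha, method))
}

# exact density of the sample correlation coefficient under a bivariate
# normal with correlation rho (Hotelling's form with a 2F1 factor)
dcorr <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) -
    0.5 * log(2 * pi) - lgamma(n - 0.5)
  lf <- lc + ((n - 4) / 2) * log1p(-r^2) - (n - 1.5) * log1p(-rho * r)
  exp(lf) * vapply(r, function(ri)
    hyp2f1_series(0.5, 0.5, n - 0.5, (1 + rho * ri) / 2), 0)
}

# Gauss hypergeometric 2F1 by direct series; converges for 0 <= z < 1
# with the large c used here
hyp2f1_series <- function(a, b, c, z, tol = 1e-12, maxit = 10000) {
  term <- 1; s <- 1
  for (k in 0:maxit) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) break
  }
  s
}
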