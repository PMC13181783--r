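#' Mode series container
#'
#' A `hdo_mode_series` is the per-mode time series the observables and
#' FFCF work on: one row per snapshot with replica label, time stamp,
#' frequency, IR intensity, first-shell coordination count and convergence
#' flag, plus the sampling interval.
#'
#' @param data data.frame with columns `replica`, `time_ps`, `freq_cm1`,
#'   `intensity`; optional `n_first_shell` and `converged` (defaulted to
#'   `NA` / `TRUE`).
#' @param mode mode label (`"bend"`, `"OD"` or `"OH"`).
#' @param dt_fs sampling interval in femtoseconds.
#' @return An object of class `hdo_mode_series` (a data.frame with `mode`
#'   and `dt_fs` attributes).
#' @export
mode_series <- function(data, mode, dt_fs) {
  stopifnot(is.data.frame(data),
            all(c("replica", "time_ps", "freq_cm1", "intensity") %in% names(data)))
  if (any(data$intensity < 0)) stop("intensities must be non-negative")
  if (dt_fs <= 0) stop("`dt_fs` must be positive")
  if (is.null(data$n_first_shell)) data$n_first_shell <- NA_integer_
  if (is.null(data$converged)) data$converged <- TRUE
  data <- data[order(data$replica, data$time_ps), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, mode = mode, dt_fs = as.numeric(dt_fs),
            class = c("hdo_mode_series", "data.frame"))
}

# converged snapshots only; observables never see failed engine runs
converged_rows <- function(series) {
  series[is.na(series$converged) | series$converged, , drop = FALSE]
}

#' Intensity-weighted mean
#'
#' @param values numeric vector (cm^-1).
#' @param weights non-negative weights of the same length; not all zero.
#' @return weighted mean `sum(w * x) / sum(w)`.
#' @export
weighted_mean <- function(values, weights = rep(1, length(values))) {
  check_weights(values, weights)
  sum(weights * values) / sum(weights)
}

#' Intensity-weighted standard deviation (population form)
#'
#' `sqrt(sum(w * (x - m)^2) / sum(w))` with `m` the weighted mean; no
#' Bessel correction, matching the population definition of the frequency
#' fluctuation amplitude.
#'
#' @inheritParams weighted_mean
#' @export
weighted_sd <- function(values, weights = rep(1, length(values))) {
  check_weights(values, weights)
  m <- sum(weights * values) / sum(weights)
  sqrt(sum(weights * (values - m)^2) / sum(weights))
}

#' Intensity-weighted asymmetry coefficient
#'
#' Fisher third standardized moment with weights:
#' `sum(w * (x - m)^3) / sum(w) / sd^3`. Negative values indicate a
#' low-frequency tail.
#'
#' @inheritParams weighted_mean
#' @export
asymmetry_coefficient <- function(values, weights = rep(1, length(values))) {
  check_weights(values, weights)
  m <- sum(weights * values) / sum(weights)
  s <- sqrt(sum(weights * (values - m)^2) / sum(weights))
  if (s == 0) stop("asymmetry coefficient undefined for zero spread")
  sum(weights * (values - m)^3) / sum(weights) / s^3
}

check_weights <- function(values, weights) {
  if (length(values) != length(weights))
    stop("`values` and `weights` must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  invisible(TRUE)
}

#' 95% half-width from a spread and a sample count
#'
#' `1.96 * spread / sqrt(n)`: 1.96 standard errors, the half-width of a
#' 95% normal confidence interval.
#'
#' @param spread standard deviation (or weighted standard deviation).
#' @param n sample count, at least 2.
#' @export
uncertainty_95 <- function(spread, n) {
  if (n < 2) stop("`n` must be at least 2")
  if (spread < 0) stop("`spread` must be non-negative")
  1.96 * spread / sqrt(n)
}

#' Summarize a mode series into central frequency and fluctuation amplitude
#'
#' Pools all converged snapshots across replicas. The central frequency
#' `omega0` is the intensity-weighted mean and `sigma` the
#' intensity-weighted standard deviation. The `omega0` half-width is
#' `1.96 sigma / sqrt(N)`; the `sigma` half-width comes from the dispersion
#' of per-replica sigma estimates (`1.96 sd(sigma_r) / sqrt(R)`), which is
#' honest about the strong serial correlation within a replica. With a
#' single replica the sigma half-width is `NA`.
#'
#' @param series an `hdo_mode_series`.
#' @return list of class `hdo_vib_summary`: `omega0`, `omega0_err`, `sigma`,
#'   `sigma_err` (cm^-1), sample count `n`, replica count, and the count of
#'   non-converged snapshots excluded.
#' @export
summarize_mode <- function(series) {
  stopifnot(inherits(series, "hdo_mode_series"))
  n_excluded <- sum(!(is.na(series$converged) | series$converged))
  s <- converged_rows(series)
  if (nrow(s) < 2L) stop("need at least two converged samples")
  omega0 <- weighted_mean(s$freq_cm1, s$intensity)
  sigma <- weighted_sd(s$freq_cm1, s$intensity)
  reps <- split(s, s$replica)
  sigma_err <- if (length(reps) >= 2L) {
    sig_r <- vapply(reps, function(r) weighted_sd(r$freq_cm1, r$intensity),
                    numeric(1))
    1.96 * stats::sd(sig_r) / sqrt(length(reps))
  } else NA_real_
  structure(
    list(mode = attr(series, "mode"),
         omega0 = omega0,
         omega0_err = uncertainty_95(sigma, nrow(s)),
         sigma = sigma,
         sigma_err = sigma_err,
         n = nrow(s),
         replicas = length(reps),
         n_excluded = n_excluded),
    class = "hdo_vib_summary")
}

#' @export
print.hdo_vib_summary <- function(x, ...) {
  cat(sprintf("<%s> omega0 = %.1f +/- %.1f cm-1, sigma = %.1f%s cm-1 (N = %d)\n",
              x$mode %||% "mode", x$omega0, x$omega0_err, x$sigma,
              if (is.na(x$sigma_err)) "" else sprintf(" +/- %.1f", x$sigma_err),
              x$n))
  invisible(x)
}

#' Intensity-weighted frequency distribution
#'
#' Normalized histogram of the frequencies with intensity weights; the
#' binned density integrates to 1. The range is padded by two bins on each
#' side so the tails are visible.
#'
#' @param series an `hdo_mode_series` (or data.frame with `freq_cm1`,
#'   `intensity`).
#' @param bin_width bin width in cm^-1. Defaults: 2 for the bend, 5 for the
#'   stretches.
#' @param edges optional explicit bin edges (overrides `bin_width` padding);
#'   used to bin several subsets onto a common grid.
#' @return list of class `hdo_freq_dist`: `centers`, `density`,
#'   `bin_width`, weighted `mean`, `sd`, `asymmetry`, sample count `n`.
#' @export
build_distribution <- function(series, bin_width = NULL, edges = NULL) {
  s <- if (inherits(series, "hdo_mode_series")) converged_rows(series) else series
  mode <- attr(series, "mode") %||% "mode"
  if (is.null(bin_width)) {
    bin_width <- if (!is.null(edges)) diff(edges)[1]
    else if (identical(mode, "bend")) 2 else 5
  }
  if (bin_width <= 0) stop("`bin_width` must be positive")
  x <- s$freq_cm1
  w <- s$intensity
  check_weights(x, w)
  if (is.null(edges)) {
    lo <- floor(min(x) / bin_width) * bin_width - 2 * bin_width
    hi <- ceiling(max(x) / bin_width) * bin_width + 2 * bin_width
    edges <- seq(lo, hi, by = bin_width)
  }
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  wsum <- vapply(seq_len(length(edges) - 1L),
                 function(b) sum(w[bin == b]), numeric(1))
  density <- wsum / (sum(w) * bin_width)
  structure(
    list(mode = mode,
         centers = (edges[-1L] + edges[-length(edges)]) / 2,
         density = density, bin_width = bin_width,
         mean = weighted_mean(x, w), sd = weighted_sd(x, w),
         asymmetry = if (weighted_sd(x, w) > 0)
           asymmetry_coefficient(x, w) else NA_real_,
         n = length(x)),
    class = "hdo_freq_dist")
}

#' Fit a sum of Gaussians to a binned frequency distribution
#'
#' Least-squares fit of `k` Gaussian components to the density histogram,
#' with deterministic initialization: for `k = 1` the histogram moments,
#' for `k > 1` means spread over the weighted quantiles. Non-convergence or
#' a poor fit (R^2 < 0.9) is flagged, never silent.
#'
#' @param dist an `hdo_freq_dist` from [build_distribution()].
#' @param k number of components (1, 2 or 3).
#' @return the distribution with a `components` data.frame (`amplitude`,
#'   `mean`, `width`), `r_squared` and `fit_flagged` added.
#' @export
fit_gaussians <- function(dist, k = 1) {
  stopifnot(inherits(dist, "hdo_freq_dist"), k %in% 1:3)
  x <- dist$centers
  y <- dist$density
  probs <- seq(0.5 / k, 1 - 0.5 / k, length.out = k)
  cum <- cumsum(y) / sum(y)
  mu0 <- vapply(probs, function(p) x[which.min(abs(cum - p))], numeric(1))
  s0 <- rep(max(dist$sd / k, dist$bin_width), k)
  a0 <- rep(max(y) / k * sqrt(2 * pi) * s0[1], k)
  gauss_k <- function(par) {
    amp <- par[seq_len(k)]
    mu <- par[k + seq_len(k)]
    sg <- par[2 * k + seq_len(k)]
    rowSums(vapply(seq_len(k), function(j)
      amp[j] / (sqrt(2 * pi) * sg[j]) * exp(-(x - mu[j])^2 / (2 * sg[j]^2)),
      numeric(length(x))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a0, mu0, s0),
      fn = function(par) y - gauss_k(par),
      lower = c(rep(0, k), rep(min(x), k), rep(dist$bin_width / 10, k)),
      upper = c(rep(Inf, k), rep(max(x), k), rep(diff(range(x)), k)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    dist$components <- NULL
    dist$r_squared <- NA_real_
    dist$fit_flagged <- TRUE
    return(dist)
  }
  par <- fit$par
  yhat <- gauss_k(par)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  ord <- order(par[k + seq_len(k)])
  dist$components <- data.frame(
    amplitude = par[seq_len(k)][ord],
    mean = par[k + seq_len(k)][ord],
    width = par[2 * k + seq_len(k)][ord])
  dist$r_squared <- r2
  dist$fit_flagged <- is.na(r2) || r2 < 0.9
  dist
}

#' Coordination-resolved frequency subdistributions
#'
#' Partitions the snapshots by their stored first-shell coordination count
#' and computes, per requested count, the weighted central frequency,
#' fluctuation amplitude, asymmetry coefficient, population fraction and
#' full distribution. All subdistributions share the bin grid of the total
#' distribution, so the intensity-weighted population fractions satisfy
#' `sum(fraction * density) == total density` bin by bin when every
#' observed count is requested. Counts with no snapshots are dropped with a
#' warning.
#'
#' @param series an `hdo_mode_series` with `n_first_shell` populated.
#' @param counts integer set of coordination numbers to resolve (default
#'   `c(3, 4, 5)`).
#' @param bin_width forwarded to [build_distribution()].
#' @return list of class `hdo_subdist_set`: `table` (data.frame with one
#'   row per count: `n_first_shell`, `fraction` intensity-weighted,
#'   `omega0`, `sigma`, `asymmetry`, `n`), `distributions` (named list of
#'   `hdo_freq_dist`) and `total` (the pooled `hdo_freq_dist`).
#' @export
decompose_by_coordination <- function(series, counts = c(3, 4, 5),
                                      bin_width = NULL) {
  stopifnot(inherits(series, "hdo_mode_series"), length(counts) >= 1L)
  s <- converged_rows(series)
  if (all(is.na(s$n_first_shell)))
    stop("series carries no first-shell coordination counts")
  total <- build_distribution(series, bin_width = bin_width)
  edges <- c(total$centers - total$bin_width / 2,
             total$centers[length(total$centers)] + total$bin_width / 2)
  w_total <- sum(s$intensity)
  rows <- list()
  dists <- list()
  for (cc in sort(counts)) {
    sub <- s[!is.na(s$n_first_shell) & s$n_first_shell == cc, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no snapshots with first-shell count ", cc, "; omitted")
      next
    }
    d <- build_distribution(sub, edges = edges)
    d$mode <- attr(series, "mode")
    rows[[length(rows) + 1L]] <- data.frame(
      n_first_shell = cc,
      fraction = sum(sub$intensity) / w_total,
      omega0 = d$mean, sigma = d$sd, asymmetry = d$asymmetry,
      n = nrow(sub))
    dists[[as.character(cc)]] <- d
  }
  if (!length(rows)) stop("no requested coordination count is populated")
  structure(list(table = do.call(rbind, rows), distributions = dists,
                 total = total, mode = attr(series, "mode")),
            class = "hdo_subdist_set")
}
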