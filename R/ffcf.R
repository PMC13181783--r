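#' Frequency-fluctuation correlation function
#'
#' Computes `C(t) = <dw(t) dw(0)>` per replica and averages the replica
#' correlation series pointwise with equal weights. Within each replica the
#' fluctuation `dw` is the frequency minus that replica's unweighted mean;
#' `C(k dt)` averages `dw(t0 + k dt) * dw(t0)` over all valid origins,
#' dividing by the number of contributing pairs at that lag (unbiased
#' denominator). `C(0)` therefore equals the pooled population variance of
#' the fluctuations.
#'
#' @param series an `hdo_mode_series`; every replica needs at least 10
#'   converged samples.
#' @param max_lag_ps largest lag (ps); defaults to half the shortest
#'   replica duration and must not exceed it.
#' @return data.frame of class `hdo_ffcf`: `lag_ps`, `C` (cm^-2),
#'   `n_pairs` (summed over replicas); attribute `dt_fs`.
#' @export
compute_ffcf <- function(series, max_lag_ps = NULL) {
  stopifnot(inherits(series, "hdo_mode_series"))
  s <- converged_rows(series)
  reps <- split(s$freq_cm1, s$replica)
  n_min <- min(lengths(reps))
  if (n_min < 10L) stop("every replica needs at least 10 samples")
  dt_ps <- attr(series, "dt_fs") / 1000
  half_ps <- floor(n_min / 2) * dt_ps
  if (is.null(max_lag_ps)) max_lag_ps <- half_ps
  k_max <- round(max_lag_ps / dt_ps)
  if (k_max > n_min - 1L)
    stop("`max_lag_ps` exceeds the replica duration")
  lags <- 0:k_max
  acc <- matrix(0, nrow = length(lags), ncol = length(reps))
  npairs <- matrix(0, nrow = length(lags), ncol = length(reps))
  for (r in seq_along(reps)) {
    x <- reps[[r]] - mean(reps[[r]])
    n <- length(x)
    for (k in lags) {
      npairs[k + 1L, r] <- n - k
      acc[k + 1L, r] <- sum(x[1:(n - k)] * x[(k + 1L):n]) / (n - k)
    }
  }
  out <- data.frame(lag_ps = lags * dt_ps,
                    C = rowMeans(acc),
                    n_pairs = rowSums(npairs))
  attr(out, "dt_fs") <- attr(series, "dt_fs")
  class(out) <- c("hdo_ffcf", "data.frame")
  out
}

#' Fit a biexponential decay to a correlation series
#'
#' Nonlinear least squares of `A1 exp(-t/tau1) + A2 exp(-t/tauc) + y0`
#' over lags `>= dt` (lag 0 excluded by default: the motionally narrowed
#' ultrafast component contaminates it). All amplitudes and times are
#' bounded positive. Initialization is a deterministic multi-start over
#' time-constant pairs `{0.05, 0.1, 0.5} x {0.5, 1, 2}` ps with the
#' amplitude split evenly from `C(dt)`; the start with the lowest residual
#' sum of squares wins. If one amplitude collapses below 2% of `C(dt)` the
#' fit is flagged effectively monoexponential.
#'
#' @param corr an `hdo_ffcf` with at least 8 usable lag points.
#' @param include_lag0 include the lag-0 point in the fit. Default `FALSE`.
#' @return list of class `hdo_biexp_fit`: `A1`, `tau1`, `A2`, `tau_c`,
#'   `y0` (ordered so `tau_c >= tau1`), standard errors `se` (named),
#'   `r_squared`, `monoexponential` flag, and the fitted curve.
#' @export
fit_biexponential <- function(corr, include_lag0 = FALSE) {
  stopifnot(inherits(corr, "hdo_ffcf"))
  use <- if (include_lag0) seq_len(nrow(corr)) else which(corr$lag_ps > 0)
  t <- corr$lag_ps[use]
  y <- corr$C[use]
  if (length(t) < 8L) stop("need at least 8 lag points to fit")
  c_dt <- y[1L]
  model <- function(par, t)
    par[1] * exp(-t / par[2]) + par[3] * exp(-t / par[4]) + par[5]
  starts <- expand.grid(tau1 = c(0.05, 0.1, 0.5), tau2 = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(A1 = max(c_dt, 1e-6) / 2, tau1 = starts$tau1[i],
            A2 = max(c_dt, 1e-6) / 2, tau2 = starts$tau2[i], y0 = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = function(par) y - model(par, t),
        lower = c(0, 1e-6, 0, 1e-6, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("biexponential fit failed to converge from every start")
  fit <- best$fit
  par <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 5))
  names(se) <- c("A1", "tau1", "A2", "tau_c", "y0")
  # order components so tau_c is the longest time
  if (par[2] > par[4]) {
    par <- par[c(3, 4, 1, 2, 5)]
    se <- se[c("A2", "tau_c", "A1", "tau1", "y0")]
    names(se) <- c("A1", "tau1", "A2", "tau_c", "y0")
  }
  yhat <- model(par, t)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else NA_real_
  structure(
    list(A1 = unname(par[1]), tau1 = unname(par[2]),
         A2 = unname(par[3]), tau_c = unname(par[4]),
         y0 = unname(par[5]), se = se, r_squared = r2,
         monoexponential = min(par[1], par[3]) < 0.02 * max(c_dt, 1e-12),
         fitted = data.frame(lag_ps = t, C = y, C_fit = yhat)),
    class = "hdo_biexp_fit")
}

#' @export
print.hdo_biexp_fit <- function(x, ...) {
  cat(sprintf(paste0("<biexponential fit> A1 = %.3g, tau1 = %.3g ps, ",
                     "A2 = %.3g, tau_c = %.3g ps, y0 = %.3g (R2 = %.4f)%s\n"),
              x$A1, x$tau1, x$A2, x$tau_c, x$y0, x$r_squared,
              if (x$monoexponential) " [effectively monoexponential]" else ""))
  invisible(x)
}

#' Extract the spectral-diffusion time from a biexponential fit
#'
#' The spectral-diffusion time is the longest of the two fitted time
#' constants; its 95% half-width is 1.96 times that parameter's standard
#' error from the fit covariance.
#'
#' @param fit an `hdo_biexp_fit`.
#' @return list with `tau_c` (ps) and `tau_c_err` (ps).
#' @export
extract_tau_c <- function(fit) {
  stopifnot(inherits(fit, "hdo_biexp_fit"))
  # components are stored with tau_c the longest already
  list(tau_c = max(fit$tau1, fit$tau_c),
       tau_c_err = 1.96 * unname(fit$se["tau_c"]))
}
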