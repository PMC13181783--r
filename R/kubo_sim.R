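#' Ornstein-Uhlenbeck frequency trajectory (exact discretization)
#'
#' Simulates the stationary Gaussian stochastic frequency process that
#' underlies the Kubo lineshape picture:
#' `dw[k+1] = dw[k] exp(-dt/tau) + sigma sqrt(1 - exp(-2 dt/tau)) xi[k]`
#' with standard normal `xi` and a stationary start `dw[1] ~ N(0, sigma^2)`.
#' The exact update (not Euler-Maruyama) makes the analytic autocorrelation
#' `sigma^2 exp(-t/tau)` hold at any time step.
#'
#' @param sigma stationary standard deviation (cm^-1).
#' @param tau correlation time (ps).
#' @param dt_fs time step (fs).
#' @param n number of points.
#' @param seed integer seed; same seed, same series.
#' @return numeric vector of n frequency fluctuations (cm^-1).
#' @export
simulate_ou <- function(sigma, tau, dt_fs, n, seed = NULL) {
  stopifnot(sigma >= 0, tau > 0, dt_fs > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-(dt_fs / 1000) / tau)
  b <- sigma * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  if (n > 1) {
    xi <- stats::rnorm(n - 1)
    for (k in 2:n) x[k] <- x[k - 1] * a + b * xi[k - 1]
  }
  x
}

#' Parameters of the two-timescale Kubo frequency process
#'
#' Defaults place the components in the physical regimes of water spectral
#' diffusion: a fast hydrogen-bond making/breaking component (tau1 = 0.1
#' ps, inside the 50-400 fs window) and a slow hydrogen-bond-network
#' reorganization component (tau2 = 1.0 ps, inside 0.7-1.2 ps), sampled
#' every 50 fs for 1,000 points in each of 12 replicas.
#'
#' @param mean_cm1 mean frequency added to the fluctuations.
#' @param sigma1,sigma2 component amplitudes (cm^-1).
#' @param tau1,tau2 component correlation times (ps).
#' @param dt_fs sampling interval (fs).
#' @param n_points points per replica.
#' @param replicas replica count.
#' @param seed integer seed.
#' @return named list of class `hdo_kubo_params`.
#' @export
kubo_params <- function(mean_cm1 = 2500, sigma1 = 60, tau1 = 0.1,
                        sigma2 = 40, tau2 = 1.0, dt_fs = 50,
                        n_points = 1000, replicas = 12, seed = 1) {
  stopifnot(sigma1 >= 0, sigma2 >= 0, tau1 > 0, tau2 > 0, dt_fs > 0,
            n_points >= 1, replicas >= 1)
  structure(list(mean_cm1 = mean_cm1, sigma1 = sigma1, tau1 = tau1,
                 sigma2 = sigma2, tau2 = tau2, dt_fs = dt_fs,
                 n_points = n_points, replicas = replicas, seed = seed),
            class = "hdo_kubo_params")
}

#' Simulate a two-timescale Kubo frequency series
#'
#' Sum of two independent Ornstein-Uhlenbeck components plus the mean; the
#' autocorrelation is `sigma1^2 exp(-t/tau1) + sigma2^2 exp(-t/tau2)` and
#' the stationary variance `sigma1^2 + sigma2^2`. Intensities are set to 1
#' unless `intensity_fn` is supplied (a function of the frequency vector
#' returning non-negative weights). Emits the replica structure expected by
#' the observables and FFCF layers.
#'
#' @param params an `hdo_kubo_params` from [kubo_params()].
#' @param mode mode label for the series. Default `"OD"`.
#' @param intensity_fn optional intensity model.
#' @return an `hdo_mode_series`.
#' @export
simulate_two_timescale <- function(params = kubo_params(), mode = "OD",
                                   intensity_fn = NULL) {
  stopifnot(inherits(params, "hdo_kubo_params"))
  set.seed(params$seed)
  out <- vector("list", params$replicas)
  for (r in seq_len(params$replicas)) {
    x1 <- simulate_ou(params$sigma1, params$tau1, params$dt_fs, params$n_points)
    x2 <- simulate_ou(params$sigma2, params$tau2, params$dt_fs, params$n_points)
    freq <- params$mean_cm1 + x1 + x2
    inten <- if (is.null(intensity_fn)) rep(1, params$n_points) else
      intensity_fn(freq)
    out[[r]] <- data.frame(
      replica = r,
      time_ps = seq_len(params$n_points) * params$dt_fs / 1000,
      freq_cm1 = freq, intensity = inten)
  }
  mode_series(do.call(rbind, out), mode = mode, dt_fs = params$dt_fs)
}

# one rigid water: O at origin, O-H 0.9572 A, H-O-H 104.52 deg, then a
# uniformly random rotation and a translation to `center`
rigid_water <- function(center, rot) {
  oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  local <- rbind(c(0, 0, 0),
                 c(oh * sin(half), oh * cos(half), 0),
                 c(-oh * sin(half), oh * cos(half), 0))
  sweep(local %*% t(rot), 2L, center, "+")
}

# uniform random rotation matrix from a random quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Generate a random periodic water box
#'
#' Random sequential insertion of rigid water geometries (O-H 0.9572 Å,
#' H-O-H 104.52°) with uniformly random orientations into a cubic periodic
#' box, rejecting placements whose O-O minimum-image distance to any
#' accepted water falls below `d_min`. Reproducible given the seed.
#'
#' @param n_waters number of water molecules.
#' @param box_length cubic box side (Å).
#' @param d_min minimum O-O distance (Å). Default 2.6, just inside the
#'   liquid-water contact distance.
#' @param seed integer seed.
#' @param max_attempts insertion attempts per molecule before giving up.
#' @param time_ps time stamp for the returned frame.
#' @return an [hdo_frame] with atoms ordered O, H, H per molecule.
#' @export
generate_water_box <- function(n_waters, box_length, d_min = 2.6, seed = 1,
                               max_attempts = 25000, time_ps = 0) {
  stopifnot(n_waters >= 1, box_length > 0, d_min >= 0)
  if (n_waters * 4 / 3 * pi * (d_min / 2)^3 >= box_length^3)
    stop("infeasible packing: ", n_waters, " waters at d_min = ", d_min,
         " A exceed the box volume")
  set.seed(seed)
  box <- rep(box_length, 3L)
  o_pos <- matrix(NA_real_, n_waters, 3L)
  xyz <- matrix(NA_real_, 3L * n_waters, 3L)
  chunk <- 64L
  for (i in seq_len(n_waters)) {
    placed <- FALSE
    attempts <- 0L
    while (attempts < max_attempts) {
      # batched candidate draws keep the rejection loop vectorized
      cand <- matrix(stats::runif(3L * chunk, 0, box_length), ncol = 3L)
      ok <- if (i == 1L) rep(TRUE, chunk) else {
        prev <- o_pos[seq_len(i - 1L), , drop = FALSE]
        d2 <- matrix(0, chunk, i - 1L)
        for (k in 1:3) {
          dk <- outer(cand[, k], prev[, k], "-")
          dk <- dk - box[k] * round(dk / box[k])
          d2 <- d2 + dk * dk
        }
        apply(d2, 1L, min) >= d_min^2
      }
      hit <- which(ok)
      if (length(hit)) {
        o_pos[i, ] <- cand[hit[1L], ]
        xyz[(3 * i - 2):(3 * i), ] <- rigid_water(o_pos[i, ],
                                                  random_rotation())
        placed <- TRUE
        break
      }
      attempts <- attempts + chunk
    }
    if (!placed)
      stop("failed to place water ", i, " after ", max_attempts,
           " attempts; lower the density or d_min")
  }
  hdo_frame(rep(c("O", "H", "H"), n_waters), xyz, box, time_ps = time_ps)
}
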