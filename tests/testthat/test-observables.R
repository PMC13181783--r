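test_that("weighted moments agree with brute-force summation oracles", {
  expect_equal(weighted_mean(c(2400, 2500), c(1, 3)), 2475)
  expect_equal(weighted_mean(1:10), mean(1:10))
  expect_equal(weighted_sd(c(-1, 1)), 1)
  expect_equal(weighted_sd(rep(5, 8)), 0)
  set.seed(10)
  x <- rnorm(1000, 2500, 60)
  w <- runif(1000)
  m_oracle <- sum(w * x) / sum(w)
  expect_equal(weighted_mean(x, w), m_oracle, tolerance = 1e-10)
  expect_equal(weighted_sd(x, w),
               sqrt(sum(w * (x - m_oracle)^2) / sum(w)), tolerance = 1e-10)
  expect_equal(asymmetry_coefficient(x, w),
               (sum(w * (x - m_oracle)^3) / sum(w)) /
                 (sum(w * (x - m_oracle)^2) / sum(w))^1.5,
               tolerance = 1e-10)
})

test_that("weighted moments validate their inputs", {
  expect_error(weighted_mean(1:3, 1:2), "equal length")
  expect_error(weighted_mean(1:3, c(0, 0, 0)), "not all be zero")
  expect_error(weighted_sd(1:3, c(1, -1, 1)), "non-negative")
  expect_error(asymmetry_coefficient(rep(2, 5)), "zero spread")
})

test_that("asymmetry coefficient reports the sign of the tail", {
  sym <- c(-2, -1, 0, 1, 2)
  expect_lt(abs(asymmetry_coefficient(sym)), 1e-12)
  left <- c(0, 0, 0, -10)
  m <- mean(left)
  s <- sqrt(mean((left - m)^2))
  expect_equal(asymmetry_coefficient(left),
               mean((left - m)^3) / s^3)
  expect_lt(asymmetry_coefficient(left), 0)
})

test_that("the 95% half-width follows the 1.96 SE rule", {
  expect_equal(uncertainty_95(26.0, 12000), 1.96 * 26 / sqrt(12000))
  expect_lt(abs(uncertainty_95(26.0, 12000) - 0.465), 5e-4)
  expect_equal(uncertainty_95(0, 100), 0)
  expect_equal(uncertainty_95(10, 400), 2 * uncertainty_95(10, 1600))
  expect_error(uncertainty_95(5, 1), "at least 2")
})

test_that("summaries pool replicas with intensity weights", {
  const <- mode_series(data.frame(replica = rep(1:2, each = 10),
                                  time_ps = rep((1:10) / 20, 2),
                                  freq_cm1 = 2500, intensity = 1), "OD", 50)
  s <- summarize_mode(const)
  expect_equal(s$omega0, 2500)
  expect_equal(s$sigma, 0)
  set.seed(4)
  df <- data.frame(replica = rep(1:4, each = 50),
                   time_ps = rep((1:50) / 20, 4),
                   freq_cm1 = rnorm(200, 2500, 30), intensity = 1)
  s <- summarize_mode(mode_series(df, "OD", 50))
  expect_equal(s$omega0, mean(df$freq_cm1), tolerance = 1e-10)
  expect_equal(s$sigma, sqrt(mean((df$freq_cm1 - mean(df$freq_cm1))^2)),
               tolerance = 1e-10)
  expect_equal(s$n, 200)
  expect_equal(s$replicas, 4)
})

test_that("summaries are permutation-invariant within replicas", {
  set.seed(5)
  df <- data.frame(replica = rep(1:3, each = 40),
                   time_ps = rep((1:40) / 20, 3),
                   freq_cm1 = rnorm(120, 2500, 30),
                   intensity = runif(120))
  s1 <- summarize_mode(mode_series(df, "OD", 50))
  perm <- df[sample(nrow(df)), ]
  s2 <- summarize_mode(mode_series(perm, "OD", 50))
  expect_equal(s1$omega0, s2$omega0)
  expect_equal(s1$sigma, s2$sigma)
  expect_equal(s1$sigma_err, s2$sigma_err)
})

test_that("sigma estimate recovers the generator amplitude", {
  ser <- simulate_two_timescale(kubo_params(sigma1 = 0, sigma2 = 80, seed = 8),
                                mode = "OD")
  s <- summarize_mode(ser)
  se <- 80 / sqrt(2 * 12000 / (2 * 1.0 / 0.05))  # crude effective-N bound
  expect_lt(abs(s$sigma - 80), 3 * se)
})

test_that("distributions are normalized intensity-weighted histograms", {
  rep_one <- mode_series(data.frame(replica = 1, time_ps = (1:20) / 20,
                                    freq_cm1 = 2500, intensity = 2),
                         "OD", 50)
  d <- build_distribution(rep_one, bin_width = 5)
  expect_equal(sum(d$density * d$bin_width), 1, tolerance = 1e-12)
  expect_equal(sum(d$density > 0), 1)
  expect_equal(max(d$density), 1 / 5)

  set.seed(6)
  x <- rnorm(4000, 2500, 40)
  ser <- mode_series(data.frame(replica = 1, time_ps = (1:4000) / 20,
                                freq_cm1 = x, intensity = 1), "OD", 50)
  d <- build_distribution(ser)
  expect_equal(sum(d$density * d$bin_width), 1, tolerance = 1e-12)
  hist_mean <- sum(d$centers * d$density) * d$bin_width
  expect_lt(abs(hist_mean - mean(x)), 3 * 40 / sqrt(4000) + d$bin_width / 2)

  # doubling half the weights doubles those bins relative to a flat oracle
  w <- rep(c(1, 2), each = 2000)
  dw <- build_distribution(data.frame(freq_cm1 = x, intensity = w))
  manual <- vapply(seq_along(dw$centers), function(b) {
    lo <- dw$centers[b] - dw$bin_width / 2
    hi <- dw$centers[b] + dw$bin_width / 2
    inb <- x > lo & x <= hi
    sum(w[inb]) / (sum(w) * dw$bin_width)
  }, numeric(1))
  expect_equal(dw$density, manual, tolerance = 1e-9)
})

test_that("Gaussian fits recover known components and flag misfits", {
  centers <- seq(2300, 2700, by = 5)
  gauss <- function(x, mu, s) exp(-(x - mu)^2 / (2 * s^2)) / (sqrt(2 * pi) * s)
  d1 <- structure(list(mode = "OD", centers = centers,
                       density = gauss(centers, 2500, 40), bin_width = 5,
                       mean = 2500, sd = 40, asymmetry = 0, n = 1000),
                  class = "hdo_freq_dist")
  f1 <- fit_gaussians(d1, k = 1)
  expect_false(f1$fit_flagged)
  expect_lt(abs(f1$components$mean - 2500) / 2500, 0.01)
  expect_lt(abs(f1$components$width - 40) / 40, 0.01)

  mix <- 0.5 * gauss(centers, 2400, 15) + 0.5 * gauss(centers, 2580, 15)
  d2 <- structure(list(mode = "OD", centers = centers, density = mix,
                       bin_width = 5, mean = 2490, sd = 92, asymmetry = 0,
                       n = 1000),
                  class = "hdo_freq_dist")
  f2 <- fit_gaussians(d2, k = 2)
  expect_false(f2$fit_flagged)
  expect_lt(abs(f2$components$mean[1] - 2400) / 2400, 0.02)
  expect_lt(abs(f2$components$mean[2] - 2580) / 2580, 0.02)

  flat <- structure(list(mode = "OD", centers = centers,
                         density = rep(1 / (5 * length(centers)),
                                       length(centers)),
                         bin_width = 5, mean = 2500,
                         sd = stats::sd(centers), asymmetry = 0, n = 1000),
                    class = "hdo_freq_dist")
  f3 <- fit_gaussians(flat, k = 1)
  expect_true(f3$fit_flagged)
})

test_that("coordination subdistributions partition and reconstruct the total", {
  set.seed(9)
  n <- 3000
  counts <- sample(3:5, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  df <- data.frame(replica = 1, time_ps = (1:n) / 20,
                   freq_cm1 = rnorm(n, 2550 - 20 * counts, 15),
                   intensity = runif(n, 0.5, 2),
                   n_first_shell = counts)
  ser <- mode_series(df, "OD", 50)
  sub <- decompose_by_coordination(ser, counts = 3:5)
  expect_equal(sub$table$n_first_shell, 3:5)
  # population fractions equal the direct intensity partition
  for (cc in 3:5) {
    expect_equal(sub$table$fraction[sub$table$n_first_shell == cc],
                 sum(df$intensity[counts == cc]) / sum(df$intensity),
                 tolerance = 1e-12)
  }
  # fraction-weighted densities rebuild the pooled distribution bin by bin
  recon <- Reduce(`+`, lapply(seq_len(nrow(sub$table)), function(i)
    sub$table$fraction[i] *
      sub$distributions[[as.character(sub$table$n_first_shell[i])]]$density))
  expect_equal(recon, sub$total$density, tolerance = 1e-10)
  # a single populated count reproduces the total distribution
  df4 <- df
  df4$n_first_shell <- 4L
  one <- decompose_by_coordination(mode_series(df4, "OD", 50), counts = 4)
  expect_equal(one$table$fraction, 1)
  expect_equal(one$distributions[["4"]]$density, one$total$density,
               tolerance = 1e-12)
  # an empty requested count is dropped with a warning, not an error
  expect_warning(decompose_by_coordination(ser, counts = c(3, 4, 5, 9)),
                 "omitted")
})

test_that("mock-pipeline subdistributions redshift with coordination", {
  set.seed(21)
  rows <- list()
  for (i in 1:250) {
    fr <- generate_water_box(48, 11.3, seed = 5000 + i)
    w <- perceive_waters(fr)
    cl <- carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = 6), n = 20)
    modes <- assign_probe_modes(mock_frequency_map(cl))
    modes$replica <- 1L
    modes$time_ps <- i * 0.05
    modes$n_first_shell <- cl$n_first_shell
    rows[[i]] <- modes
  }
  freqs <- do.call(rbind, rows)
  for (m in c("OD", "OH")) {
    ser <- mode_series(freqs[freqs$mode == m, ], m, 50)
    sub <- suppressWarnings(decompose_by_coordination(ser, counts = 3:5))
    tb <- sub$table[sub$table$n > 5, ]
    expect_true(all(diff(tb$omega0) < 0))
  }
})
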