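test_that("degenerate persistence limit gives a constant-velocity line", {
  # gamma -> 1, theta = 0, vanishing process noise: equally spaced collinear days
  p <- dcrws_params(theta = c(0, 0), gamma = c(1 - 1e-12, 0.5),
                    sigma = diag(1e-24, 2))
  cfg <- sim_config(n_days = 20, params = p, seed = 3, init_step = c(0.1, 0.04))
  tr <- simulate_true_track(cfg, modes = rep(1L, 20))
  d_lon <- diff(tr$states$lon)
  d_lat <- diff(tr$states$lat)
  expect_equal(d_lon, rep(d_lon[1], 19), tolerance = 1e-6)
  expect_equal(d_lat, rep(d_lat[1], 19), tolerance = 1e-6)
  expect_equal(d_lon[1], 0.1, tolerance = 1e-5)
})

test_that("gamma = 0 reduces to an uncorrelated random walk", {
  p <- dcrws_params(theta = c(0, 0), gamma = c(1e-9, 1e-10),
                    sigma = diag(0.05^2, 2))
  cfg <- sim_config(n_days = 10000, params = p, seed = 11)
  tr <- simulate_true_track(cfg, modes = rep(1L, 10000))
  d <- diff(tr$states$lon)
  r <- cor(d[-1], d[-length(d)])
  expect_lt(abs(r), 3 / sqrt(length(d)))  # within Monte-Carlo error of zero
})

test_that("Markov mode sequence attains its stationary distribution", {
  n <- 50000
  p <- dcrws_params(alpha = c(0.9, 0.2))
  cfg <- sim_config(n_days = n, params = p, seed = 5)
  tr <- simulate_true_track(cfg)
  pi1 <- 0.2 / (1 - 0.9 + 0.2)  # closed-form stationary probability
  frac <- mean(tr$modes == 1L)
  # autocorrelation of the 2-state chain is alpha1 - alpha2; the SE of the
  # mean indicator inflates by sqrt((1 + rho) / (1 - rho))
  rho <- 0.9 - 0.2
  se <- sqrt(pi1 * (1 - pi1) / n * (1 + rho) / (1 - rho))
  expect_lt(abs(frac - pi1), 3 * se)
})

test_that("invalid movement parameters are rejected with a diagnostic", {
  expect_error(dcrws_params(gamma = c(1.2, 0.2)), "gamma")
  expect_error(dcrws_params(gamma = c(0.2, 0.8)), "identifiability")
  expect_error(dcrws_params(alpha = c(0, 0.5)), "alpha")
  expect_error(dcrws_params(sigma = matrix(c(1, 2, 2, 1), 2)), "positive-definite")
})

test_that("noiseless fixes lie exactly on the segment between daily states", {
  em <- argos_error_model()
  em$tau_lon[] <- 1e-300; em$tau_lat[] <- 1e-300
  cfg <- sim_config(n_days = 15, seed = 21, error_model = em)
  tr <- simulate_true_track(cfg)
  fx <- simulate_argos_fixes(tr$states, cfg, seed = 22)
  h <- as.numeric(fx$timestamp - as.POSIXct("2001-03-26", tz = "UTC"),
                  units = "hours")
  k <- floor(h / 24) + 1
  j <- h / 24 - (k - 1)
  expect_equal(fx$lon, (1 - j) * tr$states$lon[k] + j * tr$states$lon[k + 1],
               tolerance = 1e-12)
  expect_equal(fx$lat, (1 - j) * tr$states$lat[k] + j * tr$states$lat[k + 1],
               tolerance = 1e-12)
})

test_that("fix rate matches the configured mean fixes per day", {
  cfg <- sim_config(n_days = 1001, mean_fixes_per_day = 1.7, seed = 31,
                    duty_cycle = list(hours_per_day = 4, window_start_hour = 6,
                                      every_other_after_day = 1001))
  tr <- simulate_true_track(cfg)
  fx <- simulate_argos_fixes(tr$states, cfg, seed = 32)
  n_days <- 1000  # transmitting days carrying a bracketing pair
  rate <- nrow(fx) / n_days
  se <- sqrt(1.7 / n_days)  # Poisson-process mean
  expect_lt(abs(rate - 1.7), 3 * se)
})

test_that("an all-Z class mixture yields nothing after prefiltering", {
  probs <- c("3" = 0, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 1)
  cfg <- sim_config(n_days = 10, lc_probabilities = probs, seed = 41)
  tag <- simulate_tag(cfg)
  expect_true(all(tag$fixes$lc == "Z"))
  expect_equal(nrow(prefilter(tag$fixes)), 0)
})

test_that("identical seed and config reproduce the synthetic tag exactly", {
  cfg <- sim_config(n_days = 30, seed = 51)
  a <- simulate_tag(cfg)
  b <- simulate_tag(cfg)
  expect_identical(a, b)
})

test_that("tortuous mode-2 days travel less far than persistent mode-1 days", {
  cfg <- sim_config(n_days = 12000, seed = 61)
  tr <- simulate_true_track(cfg)
  disp <- sqrt(diff(tr$states$lon)^2 + diff(tr$states$lat)^2)
  m <- tr$modes[-1]
  expect_lt(mean(disp[m == 2]), mean(disp[m == 1]))
})

test_that("synthetic coastline geometry behaves like a gulf with an island", {
  cm <- gulf_landmask()
  expect_false(is_on_land(c(-111, 26), cm))        # channel centreline
  expect_true(is_on_land(c(-111.25, 26.5), cm))    # island centroid
  expect_true(is_on_land(c(-112.5, 27), cm))       # west land block
  expect_error(make_synthetic_coastline(gulf_width = -1), "positive")
  # rectangular block area under the planar shoelace convention
  r <- matrix(c(0, 0, 3, 0, 3, 2, 0, 2, 0, 0), ncol = 2, byrow = TRUE)
  expect_equal(abs(dcrws:::ring_area(r)), 6)
})

test_that("every simulated fix lies within the simulated day span", {
  cfg <- sim_config(n_days = 25, seed = 71)
  tag <- simulate_tag(cfg)
  t0 <- as.POSIXct("2001-03-26", tz = "UTC")
  expect_true(all(tag$fixes$timestamp >= t0))
  expect_true(all(tag$fixes$timestamp <= t0 + 24 * 86400))
  expect_equal(length(tag$true_modes), nrow(tag$true_states))
})
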