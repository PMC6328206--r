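test_that("point-in-land matches the ray-casting oracle", {
  cm <- gulf_landmask()
  expect_false(is_on_land(c(-111, 26), cm))
  expect_true(is_on_land(c(-111.25, 26.5), cm))

  set.seed(47)
  pts <- cbind(runif(1000, -115, -107), runif(1000, 21, 33))
  got <- is_on_land(pts, cm)
  want <- vapply(seq_len(1000), function(i) oracle_on_land(pts[i, 1], pts[i, 2], cm),
                 TRUE)
  expect_equal(got, want)
})

test_that("ocean centroid reduces to the ellipse centre without land", {
  empty <- structure(list(), class = "landmask")
  p <- ocean_centroid(c(-111, 26), a = 0.3, b = 0.2, landmask = empty)
  expect_equal(p, c(-111, 26), tolerance = 1e-9)
  expect_error(ocean_centroid(c(-111, 26), a = -1, b = 0.2, empty), "positive")
})

test_that("half-plane clipping matches the analytic half-ellipse centroid", {
  # land occupies lon > center: remaining half-ellipse centroid sits at
  # -4a/(3*pi) along the longitude axis
  center <- c(-111, 0)  # equator so the planar scaling is the identity
  big <- 50
  land <- structure(list(list(
    outer = matrix(c(center[1], -big, center[1] + big, -big,
                     center[1] + big, big, center[1], big, center[1], -big),
                   ncol = 2, byrow = TRUE),
    holes = list())), class = "landmask")
  for (ab in list(c(0.4, 0.25), c(0.2, 0.2))) {
    p <- ocean_centroid(center, a = ab[1], b = ab[2], landmask = land)
    expect_equal(p[1], center[1] - 4 * ab[1] / (3 * pi), tolerance = 2e-4)
    expect_equal(p[2], center[2], tolerance = 1e-6)
  }
})

test_that("a splitting land strip gives the area-weighted two-lobe centroid", {
  # off-centre strip so the two-lobe area-weighted centroid itself is at sea
  center <- c(-111, 0)
  a <- 0.5; b <- 0.3
  strip <- structure(list(list(
    outer = matrix(c(-110.9, -5, -110.8, -5, -110.8, 5, -110.9, 5,
                     -110.9, -5), ncol = 2, byrow = TRUE),
    holes = list())), class = "landmask")
  got <- ocean_centroid(center, a, b, strip)

  # Monte-Carlo rejection-sampling oracle over the ellipse minus the strip
  set.seed(53)
  n <- 400000
  x <- runif(n, -a, a); y <- runif(n, -b, b)
  in_ell <- (x / a)^2 + (y / b)^2 <= 1
  in_sea <- in_ell & (x < 0.1 | x > 0.2)
  mc <- c(center[1] + mean(x[in_sea]), center[2] + mean(y[in_sea]))
  se <- c(sd(x[in_sea]), sd(y[in_sea])) / sqrt(sum(in_sea))
  expect_lt(abs(got[1] - mc[1]), 4 * se[1] + 1e-4)
  expect_lt(abs(got[2] - mc[2]), 4 * se[2] + 1e-4)
})

test_that("corrected tracks leave ocean positions untouched and fix land ones", {
  cm <- gulf_landmask()
  # fully at sea
  sea <- toy_track(lon = seq(-111.1, -110.9, length.out = 5), lat = rep(25.5, 5))
  out <- correct_track(sea, cm)
  expect_equal(out$lon, sea$lon)
  expect_equal(out$lat, sea$lat)
  expect_false(any(out$corrected))

  # one on-land day (inside the west land block)
  tr <- toy_track(lon = c(-111.0, -112.0, -111.0), lat = c(25.0, 25.5, 26.0),
                  b = c(1.1, 1.9, 1.5))
  out <- correct_track(tr, cm)
  expect_equal(sum(out$corrected), 1)
  expect_equal(out$b_mean, tr$b_mean)            # modes retained
  expect_equal(out$date, tr$date)
  expect_equal(out$lon[-2], tr$lon[-2])
  expect_false(any(is_on_land(cbind(out$lon, out$lat), cm)))
  expect_true(all(is_on_land(cbind(out$lon_pre, out$lat_pre), cm) == out$corrected))

  # idempotence
  again <- correct_track(out, cm)
  expect_equal(again, out)
})

test_that("a wandering synthetic track is fully relocated off land", {
  cm <- gulf_landmask()
  set.seed(59)
  n <- 100
  lon <- -111 + cumsum(rnorm(n, 0.015, 0.05))
  lat <- 24.5 + cumsum(abs(rnorm(n, 0.03, 0.02)))
  tr <- toy_track(lon = lon, lat = lat, b = runif(n, 1, 2))
  n_land <- sum(vapply(seq_len(n), function(i) oracle_on_land(lon[i], lat[i], cm), TRUE))
  expect_gt(n_land, 0)
  out <- correct_track(tr, cm)
  expect_equal(sum(out$corrected), n_land)
  on_land_after <- vapply(seq_len(n), function(i)
    oracle_on_land(out$lon[i], out$lat[i], cm), TRUE)
  expect_equal(sum(on_land_after), 0)
})

test_that("corrected point approaches the centre as land overlap vanishes", {
  center <- c(-111, 0)
  prev <- Inf
  for (edge in c(0.05, 0.15, 0.28)) {
    land <- structure(list(list(
      outer = matrix(c(center[1] + edge, -5, center[1] + 5, -5,
                       center[1] + 5, 5, center[1] + edge, 5,
                       center[1] + edge, -5), ncol = 2, byrow = TRUE),
      holes = list())), class = "landmask")
    p <- ocean_centroid(center, a = 0.3, b = 0.3, landmask = land)
    off <- abs(p[1] - center[1])
    expect_lt(off, prev)
    prev <- off
  }
})
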