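test_that("behavioural classification partitions [1,2] with strict cutoffs", {
  expect_equal(classify_mode(1.80), "ARS")
  expect_equal(classify_mode(1.20), "transiting")
  expect_equal(classify_mode(c(1.50, 1.25, 1.75)), rep("uncertain", 3))
  expect_error(classify_mode(2.3), "\\[1, 2\\]")

  set.seed(61)
  b <- runif(500, 1, 2)
  lab <- classify_mode(b)
  expect_true(all(lab %in% c("ARS", "transiting", "uncertain")))
  expect_equal(lab == "ARS", b > 1.75)
  expect_equal(lab == "transiting", b < 1.25)
})

test_that("great-circle distance matches closed forms and metric axioms", {
  expect_equal(great_circle_km(c(0, 0), c(0, 0)), 0)
  expect_equal(great_circle_km(c(0, 0), c(0, 1)), 2 * pi * 6371 / 360,
               tolerance = 1e-9)
  expect_equal(great_circle_km(c(0, 0), c(180, 0)), pi * 6371, tolerance = 1e-9)

  set.seed(67)
  for (i in 1:50) {
    p <- cbind(runif(3, -180, 180), runif(3, -89, 89))
    d12 <- great_circle_km(p[1, ], p[2, ])
    expect_equal(d12, great_circle_km(p[2, ], p[1, ]))
    expect_equal(d12, oracle_haversine_km(p[1, ], p[2, ]), tolerance = 1e-9)
    d13 <- great_circle_km(p[1, ], p[3, ]); d23 <- great_circle_km(p[2, ], p[3, ])
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("seasons split December-May from June-November", {
  expect_equal(assign_season(as.Date("2001-03-26")), "cool")
  expect_equal(assign_season(as.Date("2001-07-23")), "warm")
  expect_equal(assign_season(as.Date("2001-12-01")), "cool")
  months <- seq(as.Date("2001-01-15"), by = "month", length.out = 12)
  expect_equal(sum(assign_season(months) == "cool"), 6)
})

test_that("daily steps carry distance, speed and end-day labels", {
  tr <- toy_track(lon = c(-111, -111), lat = c(26, 26 + 24 / 111.19493),
                  b = c(1.1, 1.9))
  st <- daily_steps(tr)
  expect_equal(nrow(st), 1)
  expect_equal(st$distance_km, 24, tolerance = 1e-4)
  expect_equal(st$speed_kmh, 1, tolerance = 1e-4)
  expect_equal(st$label, "ARS")          # end-day b = 1.9
  st0 <- daily_steps(tr, label_from = "start")
  expect_equal(st0$label, "transiting")

  const <- toy_track(lon = rep(-111, 10), lat = rep(26, 10))
  st <- daily_steps(const)
  expect_equal(nrow(st), 9)
  expect_equal(st$distance_km, rep(0, 9))

  set.seed(71)
  tr <- toy_track(lon = -111 + cumsum(rnorm(12, 0, 0.1)),
                  lat = 26 + cumsum(rnorm(12, 0, 0.1)), b = runif(12, 1, 2))
  st <- daily_steps(tr)
  for (i in seq_len(11)) {
    expect_equal(st$distance_km[i],
                 oracle_haversine_km(c(tr$lon[i], tr$lat[i]),
                                     c(tr$lon[i + 1], tr$lat[i + 1])),
                 tolerance = 1e-9)
  }
  expect_equal(st$speed_kmh, st$distance_km / 24)

  gap <- tr[-5, ]
  expect_error(daily_steps(gap), "gaps")
})

test_that("per-track summaries aggregate steps by mode", {
  tr <- toy_track(lon = rep(-111, 6), lat = 26 + (0:5) * 24 / 111.19493,
                  b = c(1.9, 1.9, 1.9, 1.5, 1.9, 1.9))
  st <- daily_steps(tr)
  row <- per_track_summary(st, ptt = "x")
  expect_equal(row$dist_mean, 24, tolerance = 1e-4)
  expect_equal(row$dist_sd, 0, tolerance = 1e-6)
  expect_equal(row$dist_total, 5 * 24, tolerance = 1e-3)
  expect_equal(row$speed_mean, 1, tolerance = 1e-4)
  expect_true(is.na(row$speed_transiting))  # no transiting steps -> missing
  expect_equal(row$speed_uncertain, 1, tolerance = 1e-4)

  set.seed(73)
  tr <- toy_track(lon = -111 + cumsum(rnorm(20, 0, 0.1)),
                  lat = 26 + cumsum(rnorm(20, 0, 0.1)), b = runif(20, 1, 2))
  st <- daily_steps(tr)
  row <- per_track_summary(st)
  expect_equal(row$dist_mean, mean(st$distance_km))
  expect_equal(row$speed_max, max(st$speed_kmh))
  for (lab in c("transiting", "ARS", "uncertain")) {
    v <- st$speed_kmh[st$label == lab]
    want <- if (length(v)) mean(v) else NA_real_
    expect_equal(row[[paste0("speed_", sub("ARS", "ars", lab))]], want)
  }
})

test_that("cohort aggregation takes unweighted masked column means", {
  rows <- goc_step_stats()
  m <- aggregate_tracks(rows)
  expect_equal(m$dist_mean, 25.4, tolerance = 5e-3)
  expect_equal(m$dist_total, 7522.46, tolerance = 5e-3)
  expect_equal(m$speed_transiting, 3.38, tolerance = 5e-3)

  one <- rows[3, ]
  m1 <- aggregate_tracks(one)
  expect_equal(m1$dist_mean, one$dist_mean)

  set.seed(79)
  rnd <- rows
  rnd$speed_ars[c(2, 5)] <- NA
  m2 <- aggregate_tracks(rnd)
  expect_equal(m2$speed_ars, mean(rnd$speed_ars[-c(2, 5)]))
})

test_that("seasonal proportions tally to one within each season", {
  sp <- seasonal_mode_proportions(rep("ARS", 8),
                                  rep(c("cool", "warm"), 4))
  expect_equal(sp$fraction[sp$label == "ARS"], c(1, 1))

  labs <- c(rep("ARS", 6), "transiting", rep("uncertain", 3))
  sp <- seasonal_mode_proportions(labs, rep("cool", 10))
  expect_equal(sp$fraction, c(0.6, 0.1, 0.3))
  expect_equal(sum(sp$n), 10)

  set.seed(83)
  labs <- sample(c("ARS", "transiting", "uncertain"), 200, replace = TRUE)
  seas <- sample(c("cool", "warm"), 200, replace = TRUE)
  sp <- seasonal_mode_proportions(labs, seas)
  for (s in c("cool", "warm")) {
    sub <- sp[sp$season == s, ]
    expect_equal(sum(sub$n), sum(seas == s))
    expect_equal(sum(sub$fraction), 1)
    for (l in unique(labs))
      expect_equal(sub$n[sub$label == l], sum(labs == l & seas == s))
  }
})
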