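# Fixture builders shared across test files (everything generated in code).

random_fixes <- function(n, seed, n_ptt = 1, span_days = 10,
                         lc_pool = LC_LEVELS,
                         t0 = as.POSIXct("2001-03-26 00:00:00", tz = "UTC")) {
  set.seed(seed)
  data.frame(
    ptt = sample(sprintf("p%02d", seq_len(n_ptt)), n, replace = TRUE),
    timestamp = t0 + runif(n, 0, span_days * 86400),
    lc = sample(lc_pool, n, replace = TRUE),
    lon = runif(n, -112, -110),
    lat = runif(n, 24, 28),
    stringsAsFactors = FALSE
  )
}

# noiseless fixes on a constant-velocity line, all class 3, k per day
line_fixes <- function(n_days = 12, per_day = 2, step = c(0.1, 0.05),
                       start = c(-111, 26), ptt = "line",
                       t0 = as.POSIXct("2001-03-26 00:00:00", tz = "UTC")) {
  states <- data.frame(day = seq_len(n_days),
                       lon = start[1] + (seq_len(n_days) - 1) * step[1],
                       lat = start[2] + (seq_len(n_days) - 1) * step[2])
  hours <- as.vector(outer(seq(6, 10, length.out = per_day), (seq_len(n_days - 1) - 1) * 24, "+"))
  hours <- sort(hours)
  k <- floor(hours / 24) + 1
  j <- hours / 24 - (k - 1)
  fixes <- data.frame(
    ptt = ptt, timestamp = t0 + hours * 3600, lc = "3",
    lon = (1 - j) * states$lon[k] + j * states$lon[k + 1],
    lat = (1 - j) * states$lat[k] + j * states$lat[k + 1],
    stringsAsFactors = FALSE
  )
  list(states = states, fixes = fixes)
}

gulf_landmask <- function() {
  make_synthetic_coastline(gulf_center_lon = -111, gulf_width = 1.6,
                           lat_range = c(23, 31), land_margin = 2.5,
                           islands = list(list(lon = -111.25, lat = 26.5,
                                               radius = 0.15)))
}

# a small posterior-track-like data frame for summary tests
toy_track <- function(lon, lat, b = NULL,
                      start_date = as.POSIXct("2001-04-01 00:00:00", tz = "UTC")) {
  n <- length(lon)
  data.frame(date = start_date + (seq_len(n) - 1) * 86400,
             lon = lon, lat = lat,
             lon_hw95 = rep(0.2, n), lat_hw95 = rep(0.15, n),
             b_mean = if (is.null(b)) rep(1.9, n) else b)
}
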