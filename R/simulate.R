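#' Simulate the latent daily track of a switching correlated random walk
#'
#' Draws one daily position per day from the two-mode switching
#' first-difference correlated random walk: the behavioural mode follows a
#' two-state Markov chain (entered at its stationary distribution) and the
#' daily displacement satisfies
#' `d_t = gamma_b T(theta_b) d_{t-1} + e_t`, `e_t ~ N2(0, sigma)`,
#' where `T` is the rotation matrix and `b` the mode governing day `t`.
#' Movement is simulated in raw longitude/latitude degrees on a locally
#' planar approximation, matching the coordinate convention of the fitting
#' model.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; overrides `config$seed` when given.
#' @param modes optional integer vector of length `n_days` with values in
#'   {1, 2} forcing the mode sequence (e.g. block designs for power studies);
#'   when `NULL` modes are drawn from the Markov chain.
#' @return list with `states` (data frame: `day`, `lon`, `lat`) and `modes`
#'   (integer vector, the mode governing each day's displacement).
#' @export
simulate_true_track <- function(config, seed = NULL, modes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  n <- config$n_days
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))

  if (is.null(modes)) {
    modes <- integer(n)
    # stationary probability of mode 1 for the 2-state chain
    pi1 <- p$alpha[2] / (1 - p$alpha[1] + p$alpha[2])
    modes[1] <- ifelse(stats::runif(1) < pi1, 1L, 2L)
    for (t in 2:n) {
      p1 <- if (modes[t - 1] == 1L) p$alpha[1] else p$alpha[2]
      modes[t] <- ifelse(stats::runif(1) < p1, 1L, 2L)
    }
  } else {
    modes <- as.integer(modes)
    if (length(modes) != n || !all(modes %in% c(1L, 2L)))
      stop("modes must be length n_days with values in {1, 2}")
  }

  L <- t(chol(p$sigma))
  x <- matrix(0, n, 2)
  x[1, ] <- config$start
  d <- config$init_step + as.numeric(L %*% stats::rnorm(2))
  x[2, ] <- x[1, ] + d
  for (t in 3:n) {
    b <- modes[t]
    d <- p$gamma[b] * as.numeric(rotation_matrix(p$theta[b]) %*% d) +
      as.numeric(L %*% stats::rnorm(2))
    x[t, ] <- x[t - 1, ] + d
  }
  list(states = data.frame(day = seq_len(n), lon = x[, 1], lat = x[, 2]),
       modes = modes)
}

#' Simulate Argos-like fixes from a daily track
#'
#' Fix times are a homogeneous Poisson process restricted to the tag's daily
#' transmission window (duty cycle), at a rate giving the configured expected
#' number of fixes per transmitting day; after `every_other_after_day` days
#' the tag transmits only every other day. Each fix is the linear
#' interpolation of the bracketing daily states plus component-wise scaled-t
#' noise with the location class's scale and degrees of freedom; the class
#' itself is drawn from the configured mixture.
#'
#' @param states data frame with `day`, `lon`, `lat` (one row per day).
#' @param config a [sim_config()] object.
#' @param seed integer seed; overrides `config$seed + 1` when given.
#' @param ptt platform identifier for the output fixes.
#' @param t0 POSIXct UTC timestamp of the first daily state.
#' @return data frame of fixes (`ptt`, `timestamp`, `lc`, `lon`, `lat`),
#'   chronologically ordered; zero rows if no fix time was drawn (flagged
#'   with a message).
#' @export
simulate_argos_fixes <- function(states, config, seed = NULL, ptt = "sim01",
                                 t0 = as.POSIXct("2001-03-26 00:00:00", tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(states)
  if (n < 2) stop("need at least two daily states to interpolate fixes")
  set.seed(if (is.null(seed)) config$seed + 1L else as.integer(seed))

  dc <- config$duty_cycle
  times_h <- numeric(0)
  for (d in seq_len(n - 1)) {  # last (partial) day carries no bracketing pair
    transmitting <- d <= dc$every_other_after_day ||
      (d - dc$every_other_after_day) %% 2 == 1
    if (!transmitting) next
    k <- stats::rpois(1, config$mean_fixes_per_day)
    if (k == 0) next
    w0 <- (d - 1) * 24 + dc$window_start_hour
    times_h <- c(times_h, sort(w0 + stats::runif(k) * dc$hours_per_day))
  }
  if (length(times_h) == 0) {
    message("simulate_argos_fixes: zero fixes drawn (rate or duty cycle too low)")
    return(data.frame(ptt = character(0), timestamp = as.POSIXct(character(0), tz = "UTC"),
                      lc = character(0), lon = numeric(0), lat = numeric(0)))
  }

  k <- pmin(floor(times_h / 24) + 1, n - 1)
  j <- times_h / 24 - (k - 1)
  lon <- (1 - j) * states$lon[k] + j * states$lon[k + 1]
  lat <- (1 - j) * states$lat[k] + j * states$lat[k + 1]

  lc <- sample(LC_LEVELS, length(times_h), replace = TRUE,
               prob = config$lc_probabilities)
  em <- config$error_model
  idx <- match(lc, em$lc)
  lon <- lon + em$tau_lon[idx] * stats::rt(length(lc), em$nu[idx])
  lat <- lat + em$tau_lat[idx] * stats::rt(length(lc), em$nu[idx])

  data.frame(ptt = ptt, timestamp = t0 + times_h * 3600, lc = lc,
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

#' Simulate one complete synthetic tag
#'
#' Convenience wrapper producing a ground-truthed synthetic tag: the latent
#' daily track, its mode sequence and the Argos-like fixes, all from one
#' seed. Identical `config` + `seed` give bit-identical output.
#'
#' @inheritParams simulate_true_track
#' @inheritParams simulate_argos_fixes
#' @return list of class `synthetic_track` with `true_states`, `true_modes`
#'   and `fixes`.
#' @export
simulate_tag <- function(config, seed = NULL, ptt = "sim01", modes = NULL,
                         t0 = as.POSIXct("2001-03-26 00:00:00", tz = "UTC")) {
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  tr <- simulate_true_track(config, seed = seed, modes = modes)
  fx <- simulate_argos_fixes(tr$states, config, seed = seed + 10000L,
                             ptt = ptt, t0 = t0)
  structure(list(true_states = tr$states, true_modes = tr$modes, fixes = fx),
            class = "synthetic_track")
}

ring_area <- function(ring) {
  # signed shoelace area; ring is an (n x 2) matrix, closed or open
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

#' Build a synthetic gulf coastline
#'
#' Generates a landmask emulating an elongated, semi-enclosed gulf: land
#' blocks to the west and east of a water channel, a closing land cap at the
#' northern head (the southern mouth stays open), and one or more island
#' polygons inside the channel. Intended as a stand-in coastline for testing
#' land-aware post-processing; it is synthetic and not a cartographic
#' product.
#'
#' @param gulf_center_lon centre longitude of the water channel (degrees).
#' @param gulf_width channel width (degrees longitude).
#' @param lat_range numeric length 2, southern and northern latitude of the
#'   channel (degrees).
#' @param land_margin width of the flanking land blocks (degrees).
#' @param cap_height height of the northern land cap (degrees latitude).
#' @param islands list of islands, each a list with `lon`, `lat`, `radius`
#'   (degrees) and optionally `n_vertices`.
#' @return object of class `landmask`: a list of polygons, each with an
#'   `outer` ring matrix (lon, lat) and a (possibly empty) list of `holes`.
#' @export
make_synthetic_coastline <- function(gulf_center_lon = -111, gulf_width = 1.6,
                                     lat_range = c(23, 31), land_margin = 2.5,
                                     cap_height = 1.5,
                                     islands = list(list(lon = -111.25, lat = 26.5,
                                                         radius = 0.15))) {
  if (gulf_width <= 0 || land_margin <= 0 || cap_height <= 0)
    stop("gulf_width, land_margin and cap_height must be positive")
  if (diff(lat_range) <= 0) stop("lat_range must be increasing")
  wl <- gulf_center_lon - gulf_width / 2
  el <- gulf_center_lon + gulf_width / 2
  s <- lat_range[1] - land_margin
  nn <- lat_range[2]
  rect <- function(x0, x1, y0, y1) {
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0), ncol = 2, byrow = TRUE)
  }
  polys <- list(
    list(outer = rect(wl - land_margin, wl, s, nn), holes = list()),          # west land
    list(outer = rect(el, el + land_margin, s, nn), holes = list()),          # east land
    list(outer = rect(wl - land_margin, el + land_margin, nn, nn + cap_height),
         holes = list())                                                      # northern cap
  )
  for (isl in islands) {
    nv <- if (is.null(isl$n_vertices)) 24L else as.integer(isl$n_vertices)
    ang <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    ring <- cbind(isl$lon + isl$radius * cos(ang), isl$lat + isl$radius * sin(ang))
    ring <- rbind(ring, ring[1, ])
    polys <- c(polys, list(list(outer = ring, holes = list())))
  }
  for (p in polys) {
    if (abs(ring_area(p$outer)) <= 0) stop("degenerate (zero-area) land polygon")
  }
  structure(polys, class = "landmask",
            gulf = list(center_lon = gulf_center_lon, width = gulf_width,
                        lat_range = lat_range))
}
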