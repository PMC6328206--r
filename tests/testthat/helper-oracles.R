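# Independent brute-force oracles used to cross-check the package's
# implementations. Kept deliberately naive (loops, direct formulas).

oracle_drop_z <- function(fixes) {
  keep <- logical(nrow(fixes))
  for (i in seq_len(nrow(fixes))) keep[i] <- fixes$lc[i] != "Z"
  fixes[keep, , drop = FALSE]
}

oracle_20min <- function(fixes, window_min = 20) {
  n <- nrow(fixes)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!fixes$lc[i] %in% c("0", "A", "B")) next
    for (k in seq_len(n)) {
      if (k == i) next
      if (fixes$ptt[k] != fixes$ptt[i]) next
      if (!fixes$lc[k] %in% c("1", "2", "3")) next
      if (abs(as.numeric(fixes$timestamp[i]) - as.numeric(fixes$timestamp[k])) <=
            window_min * 60) {
        keep[i] <- FALSE
        break
      }
    }
  }
  fixes[keep, , drop = FALSE]
}

oracle_dupes <- function(fixes) {
  quality <- c("3" = 7, "2" = 6, "1" = 5, "0" = 4, A = 3, B = 2, Z = 1)
  n <- nrow(fixes)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == i) next
      same <- fixes$ptt[k] == fixes$ptt[i] &&
        as.numeric(fixes$timestamp[k]) == as.numeric(fixes$timestamp[i]) &&
        fixes$lon[k] == fixes$lon[i] && fixes$lat[k] == fixes$lat[i]
      if (!same) next
      qi <- quality[[fixes$lc[i]]]; qk <- quality[[fixes$lc[k]]]
      if (qk > qi || (qk == qi && k < i)) { keep[i] <- FALSE; break }
    }
  }
  fixes[keep, , drop = FALSE]
}

oracle_grid <- function(times_h, step = 24) {
  # (floor node, fraction) per fix time in hours since the first fix
  t0 <- min(times_h)
  n_nodes <- floor((max(times_h) - t0) / step) + 1
  node <- integer(length(times_h)); frac <- numeric(length(times_h))
  for (i in seq_along(times_h)) {
    h <- times_h[i] - t0
    node[i] <- floor(h / step) + 1
    frac[i] <- h / step - (node[i] - 1)
    if (node[i] == n_nodes) { node[i] <- n_nodes - 1; frac[i] <- 1 }
  }
  list(node = node, frac = frac, n_nodes = n_nodes)
}

# scaled-t log density written out from the gamma-function formula
oracle_t_logdens <- function(x, mu, tau, nu) {
  z <- (x - mu) / tau
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) - log(tau) -
    (nu + 1) / 2 * log(1 + z^2 / nu)
}

oracle_bvn_logdens <- function(r, sigma) {
  -log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * as.numeric(t(r) %*% solve(sigma) %*% r)
}

oracle_loglik <- function(states, modes, params, error_model, grid, fixes,
                          kappa = 100) {
  ll <- oracle_bvn_logdens(states[2, ] - states[1, ], kappa * params$sigma)
  n <- nrow(states)
  for (t in 3:n) {
    b <- modes[t]
    Tm <- matrix(c(cos(params$theta[b]), sin(params$theta[b]),
                   -sin(params$theta[b]), cos(params$theta[b])), 2, 2)
    mu <- params$gamma[b] * Tm %*% (states[t - 1, ] - states[t - 2, ])
    ll <- ll + oracle_bvn_logdens(states[t, ] - states[t - 1, ] - as.numeric(mu),
                                  params$sigma)
  }
  for (ii in seq_along(grid$fix_index)) {
    i <- grid$fix_index[ii]
    k <- grid$fix_node[ii]; j <- grid$fix_frac[ii]
    row <- error_model[error_model$lc == as.character(fixes$lc[i]), ]
    mu_lon <- (1 - j) * states[k, 1] + j * states[k + 1, 1]
    mu_lat <- (1 - j) * states[k, 2] + j * states[k + 1, 2]
    ll <- ll + oracle_t_logdens(fixes$lon[i], mu_lon, row$tau_lon, row$nu) +
      oracle_t_logdens(fixes$lat[i], mu_lat, row$tau_lat, row$nu)
  }
  ll
}

# classic crossing-number ray caster (strict interior)
ray_cast <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] == x[n] && y[1] == y[n]) n <- n - 1
  inside <- FALSE
  k <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[k] > py)) {
      xint <- x[i] + (py - y[i]) * (x[k] - x[i]) / (y[k] - y[i])
      if (px < xint) inside <- !inside
    }
    k <- i
  }
  inside
}

oracle_on_land <- function(px, py, landmask) {
  for (poly in landmask) {
    inside <- ray_cast(px, py, poly$outer)
    for (h in poly$holes) if (ray_cast(px, py, h)) inside <- FALSE
    if (inside) return(TRUE)
  }
  FALSE
}

oracle_haversine_km <- function(p1, p2, R = 6371) {
  to_rad <- pi / 180
  dlat <- (p2[2] - p1[2]) * to_rad
  dlon <- (p2[1] - p1[1]) * to_rad
  a <- sin(dlat / 2)^2 + cos(p1[2] * to_rad) * cos(p2[2] * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

oracle_ols <- function(x, y) {
  # normal equations by hand
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  pred <- intercept + slope * x
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  list(slope = slope, intercept = intercept, r_squared = r2,
       f_statistic = r2 / (1 - r2) * (n - 2))
}
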