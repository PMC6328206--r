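bvn_logdens <- function(r1, r2, sigma) {
  # bivariate normal log-density at residual (r1, r2), zero mean
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  q11 <- sigma[2, 2] / det
  q22 <- sigma[1, 1] / det
  q12 <- -sigma[1, 2] / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * (q11 * r1^2 + 2 * q12 * r1 * r2 + q22 * r2^2)
}

#' Joint log-density of the switching state-space model
#'
#' Evaluates the model's log-density for a given configuration of daily
#' states and modes: the process part is the switching first-difference
#' correlated random walk
#' `x_t - x_{t-1} ~ N2(gamma_b T(theta_b) (x_{t-1} - x_{t-2}), sigma)`
#' (the first displacement gets a diffuse zero-mean Gaussian with covariance
#' `kappa * sigma`), and the observation part places each Argos fix around
#' the linear interpolation of its bracketing daily states with
#' component-wise scaled-t errors given by the fix's location class.
#'
#' @param states numeric matrix (`n_days` x 2) of lon/lat, one row per grid
#'   day.
#' @param modes integer vector of modes in {1, 2}, one per grid day.
#' @param params a [dcrws_params()] object.
#' @param error_model an [argos_error_model()] table.
#' @param grid a [build_regular_grid()] object.
#' @param fixes the fixes the grid was built from.
#' @param parts which terms to include: `"both"`, `"process"` or
#'   `"observation"`.
#' @param kappa variance inflation of the diffuse first-displacement prior.
#' @return scalar log-density (finite for valid inputs).
#' @export
dcrws_loglik <- function(states, modes, params, error_model, grid, fixes,
                         parts = c("both", "process", "observation"),
                         kappa = 100) {
  parts <- match.arg(parts)
  states <- as.matrix(states)
  n <- grid$n_days
  if (nrow(states) != n) stop("states must have one row per grid day")
  if (length(modes) != n) stop("modes must have one entry per grid day")
  if (length(grid$fix_index) == 0) stop("grid carries no fixes")
  ll <- 0

  if (parts %in% c("both", "process")) {
    d <- diff(states)
    ll <- ll + bvn_logdens(d[1, 1], d[1, 2], kappa * params$sigma)
    if (n >= 3) {
      for (t in 3:n) {
        b <- modes[t]
        mu <- params$gamma[b] * rotation_matrix(params$theta[b]) %*% d[t - 2, ]
        ll <- ll + bvn_logdens(d[t - 1, 1] - mu[1], d[t - 1, 2] - mu[2], params$sigma)
      }
    }
  }

  if (parts %in% c("both", "observation")) {
    k <- grid$fix_node
    j <- grid$fix_frac
    fx <- fixes[grid$fix_index, , drop = FALSE]
    mu_lon <- (1 - j) * states[k, 1] + j * states[k + 1, 1]
    mu_lat <- (1 - j) * states[k, 2] + j * states[k + 1, 2]
    idx <- match(as.character(fx$lc), error_model$lc)
    tl <- error_model$tau_lon[idx]; tb <- error_model$tau_lat[idx]
    nu <- error_model$nu[idx]
    ll <- ll + sum(stats::dt((fx$lon - mu_lon) / tl, nu, log = TRUE) - log(tl)) +
      sum(stats::dt((fx$lat - mu_lat) / tb, nu, log = TRUE) - log(tb))
  }
  ll
}
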