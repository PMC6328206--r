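#' @useDynLib dcrws, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

init_chain <- function(grid, fixes, chain) {
  # overdispersed initial values: states interpolate the fixes with
  # chain-scaled jitter; parameters are drawn from the priors
  n <- grid$n_days
  fx <- fixes[grid$fix_index, , drop = FALSE]
  th <- as.numeric(fx$timestamp)
  node_t <- as.numeric(grid$times)
  lon <- stats::approx(th, fx$lon, xout = node_t, rule = 2, ties = mean)$y
  lat <- stats::approx(th, fx$lat, xout = node_t, rule = 2, ties = mean)$y
  jit <- 0.01 * chain
  x0 <- cbind(lon + stats::rnorm(n, 0, jit), lat + stats::rnorm(n, 0, jit))
  x0[1, ] <- c(fx$lon[1], fx$lat[1])
  x0[2, ] <- x0[1, ]
  g <- sort(stats::runif(2, 0.05, 0.95), decreasing = TRUE)
  pars0 <- c(stats::runif(2, -pi, pi), g, stats::runif(2, 0.05, 0.95),
             abs(stats::rnorm(2, 0, 0.1)) + 0.01, stats::runif(1, -0.5, 0.5))
  b0 <- sample(c(1L, 2L), n, replace = TRUE)
  list(x = x0, b = b0, pars = pars0)
}

PAR_NAMES <- c("theta1", "theta2", "gamma1", "gamma2", "alpha1", "alpha2",
               "sigma_lon", "sigma_lat", "rho")

#' Run the MCMC sampler for one track
#'
#' Fits the switching first-difference correlated random walk state-space
#' model to the prefiltered fixes of a single platform. Two (by default)
#' chains are run from overdispersed starting values with a single-site
#' Metropolis-within-Gibbs scheme: bivariate random-walk proposals for each
#' daily state, scalar random-walk proposals for the movement parameters
#' (with the identifiability constraint `gamma1 > gamma2` enforced through
#' the prior support) and direct Gibbs draws for the discrete behavioural
#' modes. Proposal scales adapt during burn-in only. Priors:
#' `theta_k ~ U(-pi, pi)`, `gamma` uniform on the ordered unit square,
#' `alpha_k ~ U(0, 1)`, half-normal on the process SDs and `U(-1, 1)` on the
#' process correlation.
#'
#' @param fixes data frame of prefiltered fixes for one platform.
#' @param error_model an [argos_error_model()] table.
#' @param config an [mcmc_config()] object.
#' @param fix_modes optional integer vector (length = grid days) freezing the
#'   behavioural modes (no Gibbs updates); mainly for validation studies.
#' @param fix_params logical; freeze the movement parameters at their initial
#'   values (validation only).
#' @param params_init optional [dcrws_params()] used as the initial (and, if
#'   `fix_params`, permanent) parameter values for every chain.
#' @return object of class `dcrws_samples`: per-chain retained samples of
#'   parameters, deviance, modes and states, plus the grid, fixes and
#'   configuration used.
#' @export
run_mcmc <- function(fixes, error_model = argos_error_model(),
                     config = mcmc_config(), fix_modes = NULL,
                     fix_params = FALSE, params_init = NULL) {
  validate_fixes(fixes)
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  grid <- build_regular_grid(fixes)
  fx <- fixes[grid$fix_index, , drop = FALSE]
  idx <- match(as.character(fx$lc), error_model$lc)
  if (anyNA(idx)) stop("fix location class missing from error model")

  chains <- vector("list", config$n_chains)
  for (c_i in seq_len(config$n_chains)) {
    set.seed(config$seed + c_i)
    ini <- init_chain(grid, fixes, c_i)
    if (!is.null(params_init)) {
      stopifnot(inherits(params_init, "dcrws_params"))
      s <- params_init$sigma
      ini$pars <- c(params_init$theta, params_init$gamma, params_init$alpha,
                    sqrt(s[1, 1]), sqrt(s[2, 2]), s[1, 2] / sqrt(s[1, 1] * s[2, 2]))
    }
    if (!is.null(fix_modes)) {
      stopifnot(length(fix_modes) == grid$n_days, all(fix_modes %in% 1:2))
      ini$b <- as.integer(fix_modes)
    }
    res <- dcrws_chain_cpp(ini$x, ini$b, ini$pars,
                           fx$lon, fx$lat, grid$fix_node, grid$fix_frac,
                           error_model$tau_lon[idx], error_model$tau_lat[idx],
                           error_model$nu[idx],
                           config$n_iter, config$burn_in, config$thin,
                           config$kappa, config$sd_prior_scale,
                           config$target_accept,
                           !is.null(fix_modes), fix_params)
    colnames(res$params) <- PAR_NAMES
    chains[[c_i]] <- res
  }
  structure(list(chains = chains, grid = grid, fixes = fixes,
                 error_model = error_model, config = config,
                 ptt = as.character(fixes$ptt[1])),
            class = "dcrws_samples")
}

pool_samples <- function(samples, what) {
  do.call(rbind, lapply(samples$chains, function(ch) {
    x <- ch[[what]]
    if (length(dim(x)) == 3) x else as.matrix(x)
  }))
}

#' Summarise posterior samples into a daily track
#'
#' Pools the retained samples of all chains and reduces them to one record
#' per grid day: posterior mean longitude/latitude, the 95% equal-tailed
#' credible half-width of each coordinate, and the posterior mean of the
#' behavioural mode indicator `b_mean` (continuous in [1, 2] because it
#' averages the sampled discrete modes).
#'
#' @param samples a `dcrws_samples` object, or a list with elements
#'   `states` (array: samples x days x 2), `modes` (matrix: samples x days)
#'   and optionally `times`.
#' @return data frame of class `posterior_track` with columns `date`, `lon`,
#'   `lat`, `lon_hw95`, `lat_hw95`, `b_mean`.
#' @export
summarize_posterior <- function(samples) {
  if (inherits(samples, "dcrws_samples")) {
    st <- abind_chains(lapply(samples$chains, `[[`, "states"))
    md <- do.call(rbind, lapply(samples$chains, `[[`, "modes"))
    times <- samples$grid$times
  } else {
    st <- samples$states
    md <- samples$modes
    times <- if (!is.null(samples$times)) samples$times else seq_len(dim(st)[2])
  }
  if (nrow(md) < 100) stop("need at least 100 retained samples")
  n <- dim(st)[2]
  hw <- function(v) unname(diff(stats::quantile(v, c(0.025, 0.975))) / 2)
  out <- data.frame(
    date = times,
    lon = apply(st[, , 1, drop = FALSE], 2, mean),
    lat = apply(st[, , 2, drop = FALSE], 2, mean),
    lon_hw95 = apply(st[, , 1, drop = FALSE], 2, hw),
    lat_hw95 = apply(st[, , 2, drop = FALSE], 2, hw),
    b_mean = colMeans(md)
  )
  class(out) <- c("posterior_track", "data.frame")
  out
}

abind_chains <- function(arrs) {
  S <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  n <- dim(arrs[[1]])[2]
  out <- array(NA_real_, c(S, n, 2))
  at <- 0
  for (a in arrs) {
    s <- dim(a)[1]
    out[at + seq_len(s), , ] <- a
    at <- at + s
  }
  out
}

#' Deviance and DIC of a fitted track
#'
#' The deviance `D` is the posterior mean of -2 x the observation
#' log-likelihood over retained samples; the deviance information criterion
#' is `DIC = D + p_D` with the effective parameter count
#' `p_D = D - D(posterior means)`, the plug-in deviance evaluated at the
#' posterior mean states.
#'
#' @param samples a `dcrws_samples` object, or a numeric vector of per-sample
#'   deviances.
#' @param plug_in_deviance the deviance at the posterior means; required when
#'   `samples` is a bare vector.
#' @return list with `D`, `p_D` and `DIC`.
#' @export
compute_deviance_dic <- function(samples, plug_in_deviance = NULL) {
  if (inherits(samples, "dcrws_samples")) {
    dev <- unlist(lapply(samples$chains, `[[`, "deviance"))
    st <- abind_chains(lapply(samples$chains, `[[`, "states"))
    xbar <- cbind(apply(st[, , 1, drop = FALSE], 2, mean),
                  apply(st[, , 2, drop = FALSE], 2, mean))
    ll <- dcrws_loglik(xbar, rep(1L, samples$grid$n_days),
                       dcrws_params(), samples$error_model, samples$grid,
                       samples$fixes, parts = "observation")
    plug_in_deviance <- -2 * ll
  } else {
    dev <- as.numeric(samples)
    if (is.null(plug_in_deviance))
      stop("plug_in_deviance is required when samples is a deviance vector")
  }
  D <- mean(dev)
  p_D <- D - plug_in_deviance
  list(D = D, p_D = p_D, DIC = D + p_D)
}

#' Fit the switching state-space model to one track
#'
#' High-level wrapper: runs the MCMC sampler, summarises the posterior into
#' a daily track and computes deviance and DIC, together with posterior
#' summaries of the movement parameters.
#'
#' @inheritParams run_mcmc
#' @param keep_samples retain the raw `dcrws_samples` object in the result.
#' @return object of class `dcrws_fit` with elements `track`
#'   (a `posterior_track` data frame), `D`, `DIC`, `p_D`, `params_summary`,
#'   `ptt`, `config`, and optionally `samples`.
#' @export
fit_track <- function(fixes, error_model = argos_error_model(),
                      config = mcmc_config(), keep_samples = FALSE) {
  samples <- run_mcmc(fixes, error_model, config)
  track <- summarize_posterior(samples)
  dic <- compute_deviance_dic(samples)
  pp <- pool_samples(samples, "params")
  ps <- data.frame(
    parameter = colnames(pp),
    mean = colMeans(pp),
    sd = apply(pp, 2, stats::sd),
    q025 = apply(pp, 2, stats::quantile, 0.025),
    q975 = apply(pp, 2, stats::quantile, 0.975),
    row.names = NULL
  )
  out <- list(track = track, D = dic$D, DIC = dic$DIC, p_D = dic$p_D,
              params_summary = ps, ptt = samples$ptt, config = samples$config)
  if (keep_samples) out$samples <- samples
  structure(out, class = "dcrws_fit")
}
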