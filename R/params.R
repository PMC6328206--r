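#' Argos location-class alphabet
#'
#' The seven Argos location classes in descending order of accuracy.
#' Class 3 is the most accurate (< 200 m nominal error) and class Z carries
#' unbounded error.
#'
#' @export
LC_LEVELS <- c("3", "2", "1", "0", "A", "B", "Z")

#' Movement-model parameters for the switching correlated random walk
#'
#' Bundles the parameters of the two-mode switching first-difference
#' correlated random walk (DCRWS): per-mode mean turning angle `theta`
#' (radians), per-mode move persistence `gamma` (autocorrelation in speed and
#' direction, in (0,1)), mode-switching probabilities `alpha`
#' (`alpha[1]` = P(mode 1 at t | mode 1 at t-1), `alpha[2]` = P(mode 1 at t |
#' mode 2 at t-1)), and the 2x2 process covariance `sigma` in squared degrees.
#'
#' Mode 1 is transiting (fast, directed) and mode 2 is area-restricted
#' searching (ARS; slow, tortuous). For identifiability the persistence of
#' mode 1 must exceed that of mode 2 (`gamma[1] > gamma[2]`).
#'
#' @param theta numeric length 2, mean turning angle per mode (radians).
#' @param gamma numeric length 2, persistence per mode, each in (0,1) with
#'   `gamma[1] > gamma[2]`.
#' @param alpha numeric length 2, switching probabilities in (0,1).
#' @param sigma 2x2 symmetric positive-definite process covariance (deg^2).
#' @return an object of class `dcrws_params`.
#' @examples
#' p <- dcrws_params()
#' p$gamma
#' @export
dcrws_params <- function(theta = c(0, pi / 2),
                         gamma = c(0.8, 0.2),
                         alpha = c(0.9, 0.1),
                         sigma = diag(0.08^2, 2)) {
  stopifnot(length(theta) == 2, length(gamma) == 2, length(alpha) == 2)
  if (!all(is.finite(theta))) stop("theta must be finite")
  if (any(gamma <= 0) || any(gamma >= 1))
    stop("gamma must lie in the open interval (0, 1)")
  if (gamma[1] <= gamma[2])
    stop("identifiability requires gamma[1] > gamma[2] (mode 1 = transiting is more persistent)")
  if (any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must lie in the open interval (0, 1)")
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma))) || any(eigen(sigma, only.values = TRUE)$values <= 0))
    stop("sigma must be a symmetric positive-definite 2x2 matrix")
  structure(list(theta = as.numeric(theta), gamma = as.numeric(gamma),
                 alpha = as.numeric(alpha), sigma = sigma),
            class = "dcrws_params")
}

#' 2D rotation matrix
#'
#' @param theta angle in radians.
#' @return 2x2 rotation matrix with determinant 1.
#' @export
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Argos location-class observation-error model
#'
#' Component-wise scaled-t error model for Argos fixes: each location class
#' carries a scale `tau` (degrees, separately for longitude and latitude) and
#' degrees of freedom `nu`. The default table spans roughly 0.15 km (LC 3) to
#' 9 km (LC B) at mid latitudes, with heavier tails for the poorer classes;
#' the scales are configuration entries, not assertions about any particular
#' Argos error study, and should be tuned to the deployment at hand.
#'
#' @param table data frame with columns `lc`, `tau_lon`, `tau_lat`, `nu`
#'   covering all seven location classes.
#' @return an object of class `argos_error_model` (a data frame).
#' @export
argos_error_model <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      lc      = LC_LEVELS,
      tau_lon = c(0.0015, 0.0025, 0.005, 0.015, 0.030, 0.080, 0.30),
      tau_lat = c(0.0012, 0.0020, 0.004, 0.012, 0.025, 0.065, 0.30),
      nu      = c(10, 8, 6, 4, 4, 4, 3),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("lc", "tau_lon", "tau_lat", "nu") %in% names(table)))
  if (!all(LC_LEVELS %in% table$lc))
    stop("error model must cover all location classes: ", paste(LC_LEVELS, collapse = ", "))
  if (any(table$tau_lon <= 0) || any(table$tau_lat <= 0))
    stop("tau scales must be positive")
  if (any(table$nu <= 2))
    stop("degrees of freedom nu must exceed 2 for every class")
  class(table) <- c("argos_error_model", "data.frame")
  table
}

#' MCMC sampler configuration
#'
#' Defaults follow the analysis protocol of two chains of 30,000 iterations,
#' a 10,000-iteration burn-in and thinning by 5, which retains exactly 4,000
#' samples per chain.
#'
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param kappa variance inflation for the diffuse prior on the first
#'   displacement.
#' @param sd_prior_scale scale (degrees) of the half-normal prior on the
#'   process standard deviations.
#' @param target_accept target acceptance rate for the adaptive single-site
#'   random-walk proposals (adaptation runs during burn-in only).
#' @return an object of class `mcmc_config`.
#' @examples
#' mcmc_config()$n_retained  # 4000
#' @export
mcmc_config <- function(n_iter = 30000, burn_in = 10000, thin = 5,
                        n_chains = 2, seed = 1, kappa = 100,
                        sd_prior_scale = 1, target_accept = 0.44) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1, n_chains >= 1)
  if ((n_iter - burn_in) %% thin != 0)
    stop("(n_iter - burn_in) must be divisible by thin")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), kappa = kappa,
                 sd_prior_scale = sd_prior_scale,
                 target_accept = target_accept,
                 n_retained = as.integer((n_iter - burn_in) / thin)),
            class = "mcmc_config")
}

#' Behavioural classification thresholds
#'
#' Daily posterior mode means above `ars_cutoff` are labelled ARS, below
#' `transit_cutoff` transiting, and anything in between (boundaries included)
#' uncertain.
#'
#' @param transit_cutoff upper bound (exclusive) for transiting.
#' @param ars_cutoff lower bound (exclusive) for ARS.
#' @return an object of class `behavior_thresholds`.
#' @export
behavior_thresholds <- function(transit_cutoff = 1.25, ars_cutoff = 1.75) {
  if (!(1 < transit_cutoff && transit_cutoff < ars_cutoff && ars_cutoff < 2))
    stop("need 1 < transit_cutoff < ars_cutoff < 2")
  structure(list(transit_cutoff = transit_cutoff, ars_cutoff = ars_cutoff),
            class = "behavior_thresholds")
}

#' Simulation configuration for synthetic Argos tags
#'
#' Describes one synthetic deployment: track length, movement parameters,
#' target fix rate, the location-class mixture, the observation-error model
#' and the transmitter duty cycle (a fixed daily transmission window,
#' switching to every other day after `every_other_after_day` days, mirroring
#' battery-saving schedules of implantable whale tags).
#'
#' @param n_days track length in days (>= 3).
#' @param params a [dcrws_params()] object.
#' @param mean_fixes_per_day expected number of Argos fixes per transmitting
#'   day (study-scale default 1.7).
#' @param lc_probabilities named categorical weights over the seven location
#'   classes; must sum to 1. The default is weighted toward the poorer
#'   classes 0/A/B, as is typical of marine deployments.
#' @param error_model an [argos_error_model()] table.
#' @param duty_cycle list with `hours_per_day`, `window_start_hour` and
#'   `every_other_after_day`.
#' @param start numeric length 2, starting longitude/latitude (degrees).
#' @param init_step numeric length 2, deterministic component of the first
#'   daily displacement (degrees).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_days = 70,
                       params = dcrws_params(),
                       mean_fixes_per_day = 1.7,
                       lc_probabilities = c("3" = 0.05, "2" = 0.07, "1" = 0.10,
                                            "0" = 0.18, "A" = 0.25, "B" = 0.30,
                                            "Z" = 0.05),
                       error_model = argos_error_model(),
                       duty_cycle = list(hours_per_day = 4,
                                         window_start_hour = 6,
                                         every_other_after_day = 90),
                       start = c(-111.0, 26.0),
                       init_step = c(0.10, 0.05),
                       seed = 1L) {
  stopifnot(inherits(params, "dcrws_params"))
  if (n_days < 3) stop("n_days must be at least 3")
  if (mean_fixes_per_day <= 0) stop("mean_fixes_per_day must be positive")
  if (!setequal(names(lc_probabilities), LC_LEVELS))
    stop("lc_probabilities must be named by the seven location classes")
  lc_probabilities <- lc_probabilities[LC_LEVELS]
  if (abs(sum(lc_probabilities) - 1) > 1e-8)
    stop("lc_probabilities must sum to 1")
  if (any(lc_probabilities < 0)) stop("lc_probabilities must be non-negative")
  stopifnot(length(start) == 2, length(init_step) == 2)
  structure(list(n_days = as.integer(n_days), params = params,
                 mean_fixes_per_day = mean_fixes_per_day,
                 lc_probabilities = lc_probabilities,
                 error_model = argos_error_model(error_model),
                 duty_cycle = duty_cycle, start = as.numeric(start),
                 init_step = as.numeric(init_step), seed = as.integer(seed)),
            class = "sim_config")
}
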