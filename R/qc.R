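#' Running mean and standard deviation of a chain series
#'
#' Element `k` of each output series is the mean (respectively SD) of the
#' first `k` values, the quantity tracked when checking that an MCMC chain
#' has stabilised. The SD at `k = 1` is `NA`.
#'
#' @param x numeric series of length >= 2 (e.g. per-sample deviance, theta or
#'   gamma).
#' @return list with `mean` and `sd` series the same length as `x`.
#' @export
cumulative_stats <- function(x) {
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  k <- seq_len(n)
  m <- cumsum(x) / k
  s2 <- (cumsum(x^2) - k * m^2) / (k - 1)
  s2[s2 < 0] <- 0  # guard tiny negative round-off
  list(mean = m, sd = c(NA_real_, sqrt(s2[-1])))
}

#' Between-chain agreement diagnostic
#'
#' Potential-scale-reduction-style ratio for two chains of equal length:
#' values near 1 indicate the chains explore the same distribution, values
#' well above 1 (conventionally > 1.1) indicate disagreement.
#'
#' @param chains list of two equal-length numeric vectors.
#' @return scalar ratio.
#' @export
chain_agreement <- function(chains) {
  if (length(chains) != 2) stop("expected exactly two chains")
  n <- length(chains[[1]])
  if (length(chains[[2]]) != n) stop("chains must have equal length")
  if (n < 2) stop("chains too short")
  W <- mean(vapply(chains, stats::var, 0))
  B_over_n <- stats::var(vapply(chains, mean, 0))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Largest-gap unimodality screen
#'
#' Quantitative proxy for the visual inspection of a posterior sample's
#' distribution: the largest gap between consecutive order statistics
#' (within the central 98% of the sample) divided by the mean gap. Clearly
#' bimodal samples with separated clusters give large ratios; unimodal
#' samples stay small. Heuristic only; the threshold is the caller's choice.
#'
#' @param x numeric sample.
#' @return ratio of the largest central gap to the mean gap.
#' @export
unimodality_gap <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 10) stop("sample too small for the gap screen")
  lo <- ceiling(0.01 * n); hi <- floor(0.99 * n)
  x <- x[lo:hi]
  g <- diff(x)
  if (all(g == 0)) return(1)
  max(g) / mean(g)
}

#' Per-track quality-control metrics
#'
#' The six per-track metrics derived from the Argos data: a) mean filtered
#' locations per day (over days with at least one location), b) SD of
#' filtered locations per day, c) input:output ratio of Argos to SSM
#' locations, d) total tracking days (first to last fix date, inclusive),
#' e) total filtered Argos locations, f) `e / d`.
#'
#' @param fixes prefiltered fixes for one platform.
#' @param posterior_track the fitted daily track for the same platform.
#' @return list of class `track_qc_metrics` with elements `a`..`f`.
#' @export
derive_track_metrics <- function(fixes, posterior_track) {
  if (nrow(fixes) == 0) stop("no fixes")
  days <- as.Date(fixes$timestamp, tz = "UTC")
  counts <- as.numeric(table(days))
  d <- as.integer(max(days) - min(days)) + 1L
  if (d <= 0) stop("zero tracking days")
  e <- nrow(fixes)
  out <- list(a = mean(counts),
              b = if (length(counts) > 1) stats::sd(counts) else 0,
              c = e / nrow(posterior_track),
              d = d, e = e, f = e / d)
  class(out) <- "track_qc_metrics"
  out
}

#' Regress track deviance on a quality-control metric
#'
#' Ordinary least squares of the per-track deviance on one of the derived
#' track metrics, reporting slope, intercept, R-squared, the F statistic of
#' the regression and its p-value.
#'
#' @param metric numeric vector of metric values (one per track).
#' @param deviance numeric vector of deviances, same length.
#' @return list of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`, `n`.
#' @export
regress_deviance <- function(metric, deviance) {
  n <- length(metric)
  if (length(deviance) != n) stop("metric and deviance lengths differ")
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::var(metric) == 0) stop("predictor has zero variance")
  fit <- stats::lm(deviance ~ metric)
  sm <- summary(fit)
  f <- unname(sm$fstatistic[1])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 f_statistic = f,
                 p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE),
                 n = n),
            class = "regression_result")
}

#' Keep/discard decision per track
#'
#' Tracks whose total number of filtered Argos locations falls below the
#' threshold are discarded (the metric found to drive model deviance); the
#' decision and reason are returned per track.
#'
#' @param metrics named list of `track_qc_metrics`, one per platform.
#' @param min_total_locations discard threshold on metric e.
#' @return data frame with `ptt`, `keep`, `reason`.
#' @export
flag_tracks <- function(metrics, min_total_locations = 10) {
  ptt <- names(metrics)
  keep <- vapply(metrics, function(m) m$e >= min_total_locations, TRUE)
  reason <- ifelse(keep, "",
                   sprintf("total filtered locations below threshold (%d < %d)",
                           vapply(metrics, function(m) as.integer(m$e), 0L),
                           as.integer(min_total_locations)))
  data.frame(ptt = ptt, keep = unname(keep), reason = unname(reason),
             stringsAsFactors = FALSE, row.names = NULL)
}
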