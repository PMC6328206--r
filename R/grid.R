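#' Build the daily regularisation grid for a track
#'
#' Lays down one node per day, anchored at the first fix's timestamp, and
#' maps each fix to its bracketing node interval with an interpolation
#' fraction `j = (t - node_floor) / 24 h`. The last node is the latest whole
#' day covered by the fixes; a trailing partial day (fixes after the last
#' node) is dropped. A fix landing exactly on the final node is assigned to
#' the final interval with `j = 1` so the closing fix is retained.
#'
#' @param fixes data frame of (prefiltered) Argos fixes for one platform.
#' @param step_hours grid step; 24 gives one estimated location per day.
#' @return object of class `regular_grid`: list with node `times` (POSIXct),
#'   `n_days`, and per retained fix `fix_node` (floor node index),
#'   `fix_frac` (j) and `fix_index` (row in `fixes`).
#' @export
build_regular_grid <- function(fixes, step_hours = 24) {
  if (nrow(fixes) < 2) stop("track unmodelable: need at least 2 fixes")
  if (length(unique(fixes$ptt)) > 1)
    stop("build_regular_grid expects fixes from a single platform")
  ts <- as.numeric(fixes$timestamp)
  t0 <- min(ts)
  span_h <- (max(ts) - t0) / 3600
  if (span_h < 2 * step_hours)
    stop("track unmodelable: fixes span less than 2 days")
  n_nodes <- floor(span_h / step_hours) + 1
  h <- (ts - t0) / 3600
  node <- floor(h / step_hours) + 1
  frac <- h / step_hours - (node - 1)
  at_last <- node == n_nodes
  node[at_last] <- n_nodes - 1
  frac[at_last] <- 1
  keep <- node <= n_nodes - 1
  structure(list(
    times = as.POSIXct(t0 + (seq_len(n_nodes) - 1) * step_hours * 3600,
                       origin = "1970-01-01", tz = "UTC"),
    n_days = as.integer(n_nodes),
    step_hours = step_hours,
    fix_node = as.integer(node[keep]),
    fix_frac = frac[keep],
    fix_index = which(keep)
  ), class = "regular_grid")
}
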