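#' Classify behavioural mode from the posterior mode mean
#'
#' Daily posterior mode means above the ARS cutoff (default 1.75) are
#' area-restricted searching, below the transit cutoff (default 1.25)
#' transiting; everything in between, boundaries included, is uncertain.
#'
#' @param b numeric vector of posterior mode means in \[1, 2\].
#' @param thresholds a [behavior_thresholds()] object.
#' @return character vector with values `"ARS"`, `"transiting"`,
#'   `"uncertain"`.
#' @export
classify_mode <- function(b, thresholds = behavior_thresholds()) {
  if (any(!is.finite(b)) || any(b < 1) || any(b > 2))
    stop("posterior mode means must lie in [1, 2]")
  out <- rep("uncertain", length(b))
  out[b > thresholds$ars_cutoff] <- "ARS"
  out[b < thresholds$transit_cutoff] <- "transiting"
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param p1,p2 numeric length-2 vectors (lon, lat) or n x 2 matrices.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371)) # r in km
}

#' Assign the Gulf of California climatic season
#'
#' December through May is the cool season, June through November the warm
#' season.
#'
#' @param date a `Date`/`POSIXct` vector (or anything `as.Date` accepts).
#' @return character vector `"cool"` / `"warm"`.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date, tz = "UTC"), "%m"))
  ifelse(m >= 6 & m <= 11, "warm", "cool")
}

#' Daily movement steps of a fitted track
#'
#' One step per consecutive pair of daily locations: great-circle distance,
#' speed (distance / 24 h), a behavioural label taken from the step's end
#' day (configurable to the start day) and the climatic season of the same
#' day.
#'
#' @param track a (land-corrected) `posterior_track` data frame with `date`,
#'   `lon`, `lat`, `b_mean`.
#' @param thresholds a [behavior_thresholds()] object.
#' @param label_from `"end"` (default) or `"start"`: which day of the pair
#'   provides the label and season.
#' @return data frame of class `daily_steps` with `date`, `lon0`, `lat0`,
#'   `lon1`, `lat1`, `distance_km`, `speed_kmh`, `label`, `season`.
#' @export
daily_steps <- function(track, thresholds = behavior_thresholds(),
                        label_from = c("end", "start")) {
  label_from <- match.arg(label_from)
  n <- nrow(track)
  if (n < 2) stop("need at least 2 daily locations")
  dt <- diff(as.numeric(as.POSIXct(track$date, tz = "UTC")))
  if (any(abs(dt - 86400) > 1))
    stop("daily grid has gaps; steps require contiguous days")
  i0 <- seq_len(n - 1); i1 <- i0 + 1
  ref <- if (label_from == "end") i1 else i0
  d <- great_circle_km(cbind(track$lon[i0], track$lat[i0]),
                       cbind(track$lon[i1], track$lat[i1]))
  out <- data.frame(
    date = track$date[ref],
    lon0 = track$lon[i0], lat0 = track$lat[i0],
    lon1 = track$lon[i1], lat1 = track$lat[i1],
    distance_km = d,
    speed_kmh = d / 24,
    label = classify_mode(track$b_mean[ref], thresholds),
    season = assign_season(track$date[ref]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("daily_steps", "data.frame")
  out
}

#' Per-track movement summary row
#'
#' Mean, SD, min and max of the daily distances, the total track distance,
#' the same statistics for speed, and mean speed by behavioural mode (NA for
#' modes with no steps).
#'
#' @param steps a [daily_steps()] data frame.
#' @param ptt optional platform identifier for the row.
#' @return one-row data frame with the summary columns.
#' @export
per_track_summary <- function(steps, ptt = NA_character_) {
  if (nrow(steps) < 1) stop("need at least one step")
  mode_mean <- function(lab) {
    v <- steps$speed_kmh[steps$label == lab]
    if (length(v)) mean(v) else NA_real_
  }
  data.frame(
    ptt = ptt,
    dist_mean = mean(steps$distance_km),
    dist_sd = if (nrow(steps) > 1) stats::sd(steps$distance_km) else NA_real_,
    dist_min = min(steps$distance_km),
    dist_max = max(steps$distance_km),
    dist_total = sum(steps$distance_km),
    speed_mean = mean(steps$speed_kmh),
    speed_sd = if (nrow(steps) > 1) stats::sd(steps$speed_kmh) else NA_real_,
    speed_min = min(steps$speed_kmh),
    speed_max = max(steps$speed_kmh),
    speed_transiting = mode_mean("transiting"),
    speed_ars = mode_mean("ARS"),
    speed_uncertain = mode_mean("uncertain"),
    stringsAsFactors = FALSE
  )
}

#' Cohort grand-mean row across per-track summaries
#'
#' Unweighted arithmetic mean of each numeric column across tracks, skipping
#' missing entries, so a per-mode column is averaged over the tracks that
#' report that mode. This is the arithmetic behind a cohort "Mean" row of a
#' per-track summary table.
#'
#' @param rows data frame of per-track summary rows ([per_track_summary()]).
#' @return one-row data frame of column means (`ptt` set to `"mean"`).
#' @export
aggregate_tracks <- function(rows) {
  if (nrow(rows) < 1) stop("need at least one track row")
  num <- vapply(rows, is.numeric, TRUE)
  out <- rows[1, , drop = FALSE]
  for (nm in names(rows)) {
    if (num[[nm]]) {
      v <- mean(rows[[nm]], na.rm = TRUE)
      out[[nm]] <- if (is.nan(v)) NA_real_ else v
    } else {
      out[[nm]] <- NA
    }
  }
  out$ptt <- "mean"
  rownames(out) <- NULL
  out
}

#' Seasonal counts and proportions of behavioural labels
#'
#' Tallies classified daily locations by season and label.
#'
#' @param labels character vector of behavioural labels.
#' @param seasons character vector of seasons, same length.
#' @return data frame with `season`, `label`, `n`, `fraction` (fractions sum
#'   to 1 within each season).
#' @export
seasonal_mode_proportions <- function(labels, seasons) {
  stopifnot(length(labels) == length(seasons))
  lab_lv <- c("ARS", "transiting", "uncertain")
  sea_lv <- intersect(c("cool", "warm"), unique(seasons))
  tab <- table(factor(seasons, levels = sea_lv), factor(labels, levels = lab_lv))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("season", "label", "n")
  tot <- stats::ave(out$n, out$season, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$n / tot, NA_real_)
  out
}
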