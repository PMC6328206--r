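#' @keywords internal
lc_quality <- function(lc) {
  # higher is better: 3 > 2 > 1 > 0 > A > B > Z
  match(as.character(lc), rev(LC_LEVELS))
}

validate_fixes <- function(fixes) {
  req <- c("ptt", "timestamp", "lc", "lon", "lat")
  miss <- setdiff(req, names(fixes))
  if (length(miss)) stop("fixes are missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!as.character(fixes$lc) %in% LC_LEVELS)
  if (length(bad))
    stop("unknown location class in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(unique(fixes$lc[bad]), collapse = ", "))
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct (UTC)")
  if (anyNA(fixes$timestamp)) stop("unparseable timestamp in row(s) ",
                                   paste(which(is.na(fixes$timestamp)), collapse = ", "))
  bad <- which(!is.finite(fixes$lon) | fixes$lon < -180 | fixes$lon > 180 |
                 !is.finite(fixes$lat) | fixes$lat < -90 | fixes$lat > 90)
  if (length(bad)) stop("coordinates out of range in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  invisible(fixes)
}

#' Remove Argos fixes of location class Z
#'
#' Class Z locations carry unbounded error and are dropped outright; all
#' other fixes pass through in their original order.
#'
#' @param fixes data frame of Argos fixes (`ptt`, `timestamp`, `lc`, `lon`,
#'   `lat`).
#' @return the fixes with every class-Z row removed.
#' @export
drop_class_z <- function(fixes) {
  fixes[as.character(fixes$lc) != "Z", , drop = FALSE]
}

#' Remove low-quality fixes close in time to high-quality ones
#'
#' A fix of class 0, A or B is removed when any fix of class 1, 2 or 3 of the
#' same platform lies within the time window (default 20 minutes, two-sided
#' and inclusive at the boundary). High-quality fixes are never removed by
#' this rule.
#'
#' @param fixes data frame of Argos fixes.
#' @param window_min window half-width in minutes.
#' @return the fixes minus the suppressed low-quality rows, per-platform
#'   chronological order preserved.
#' @export
apply_20min_rule <- function(fixes, window_min = 20) {
  if (nrow(fixes) == 0) return(fixes)
  keep <- rep(TRUE, nrow(fixes))
  lc <- as.character(fixes$lc)
  low <- lc %in% c("0", "A", "B")
  high <- lc %in% c("1", "2", "3")
  for (id in unique(fixes$ptt)) {
    sel <- fixes$ptt == id
    ht <- as.numeric(fixes$timestamp[sel & high])
    li <- which(sel & low)
    if (length(ht) == 0 || length(li) == 0) next
    for (i in li) {
      if (min(abs(as.numeric(fixes$timestamp[i]) - ht)) <= window_min * 60)
        keep[i] <- FALSE
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Discard duplicate Argos fixes
#'
#' Fixes identical in (ptt, timestamp, lon, lat) are collapsed to a single
#' row; the retained row is the one with the best location class
#' (3 > 2 > 1 > 0 > A > B > Z), ties broken by first occurrence.
#'
#' @param fixes data frame of Argos fixes.
#' @return the deduplicated fixes, original order of retained rows preserved.
#' @export
drop_duplicates <- function(fixes) {
  if (nrow(fixes) == 0) return(fixes)
  key <- paste(fixes$ptt, format(fixes$timestamp, "%Y-%m-%dT%H:%M:%OS6"),
               sprintf("%.12f", fixes$lon), sprintf("%.12f", fixes$lat), sep = "|")
  q <- lc_quality(fixes$lc)
  ord <- order(key, -q, seq_len(nrow(fixes)))
  first <- !duplicated(key[ord])
  keep <- sort(ord[first])
  fixes[keep, , drop = FALSE]
}

#' Prefilter raw Argos fixes by location class
#'
#' Composition of the three filtering rules, applied in order: remove class-Z
#' fixes, suppress low-quality fixes within 20 minutes of high-quality ones,
#' then discard duplicates. Input is sorted by platform and timestamp first;
#' the operation is idempotent and never fabricates fixes.
#'
#' @param fixes data frame of Argos fixes.
#' @param window_min time window for the quality rule, minutes.
#' @param verbose print a per-rule count of removed fixes.
#' @return the filtered fixes, with attribute `removed` giving per-rule
#'   counts.
#' @export
prefilter <- function(fixes, window_min = 20, verbose = FALSE) {
  validate_fixes(fixes)
  fixes <- fixes[order(fixes$ptt, fixes$timestamp), , drop = FALSE]
  n0 <- nrow(fixes)
  a <- drop_class_z(fixes)
  b <- apply_20min_rule(a, window_min = window_min)
  d <- drop_duplicates(b)
  removed <- c(class_z = n0 - nrow(a), quality_window = nrow(a) - nrow(b),
               duplicates = nrow(b) - nrow(d))
  if (verbose)
    message(sprintf("prefilter: %d -> %d fixes (Z: %d, 20-min rule: %d, duplicates: %d)",
                    n0, nrow(d), removed[1], removed[2], removed[3]))
  attr(d, "removed") <- removed
  d
}
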