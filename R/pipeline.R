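#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default, so
#' all constants are visible and overridable in one place. Any element can
#' also be supplied through a YAML file via [load_pipeline_config()].
#'
#' @param fixes_csv path to the raw Argos fix CSV (NULL when fixes are
#'   passed directly to [run_pipeline()]).
#' @param landmask_geojson path to the landmask GeoJSON (NULL to pass a
#'   `landmask` object directly).
#' @param output_dir directory for the output bundle (NULL = don't write).
#' @param mcmc an [mcmc_config()].
#' @param error_model an [argos_error_model()] table.
#' @param thresholds a [behavior_thresholds()].
#' @param min_total_locations track-exclusion threshold on filtered
#'   locations.
#' @param window_min prefilter quality window (minutes).
#' @param seed global seed; per-track chain seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fixes_csv = NULL, landmask_geojson = NULL,
                            output_dir = NULL, mcmc = mcmc_config(),
                            error_model = argos_error_model(),
                            thresholds = behavior_thresholds(),
                            min_total_locations = 10, window_min = 20,
                            seed = 1L) {
  structure(list(fixes_csv = fixes_csv, landmask_geojson = landmask_geojson,
                 output_dir = output_dir, mcmc = mcmc,
                 error_model = error_model, thresholds = thresholds,
                 min_total_locations = min_total_locations,
                 window_min = window_min, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()]; `mcmc`,
#' `thresholds` and `error_model` may be given as nested mappings.
#'
#' @param path YAML file.
#' @return a `pipeline_config` object.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("fixes_csv", "landmask_geojson", "output_dir",
               "min_total_locations", "window_min", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$mcmc)) args$mcmc <- do.call(mcmc_config, y$mcmc)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(behavior_thresholds, y$thresholds)
  if (!is.null(y$error_model))
    args$error_model <- argos_error_model(as.data.frame(y$error_model))
  do.call(pipeline_config, args)
}

# stable fingerprint of the scientific configuration for output sidecars;
# input/output paths are excluded so runs on the same data and settings in
# different locations fingerprint identically
config_fingerprint <- function(config) {
  cfg <- config[setdiff(names(config),
                        c("fixes_csv", "landmask_geojson", "output_dir"))]
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full telemetry analysis pipeline
#'
#' Orchestrates prefilter -> exclusion -> state-space fit -> convergence QC
#' -> land correction -> movement summaries for every platform in the input,
#' then builds the cohort products: the per-track summary table with its
#' grand-mean row, the deviance-versus-metric regression table, and the
#' seasonal behavioural proportions. Identical seed and configuration give
#' identical outputs.
#'
#' @param config a [pipeline_config()] object.
#' @param fixes optional data frame of raw fixes (otherwise read from
#'   `config$fixes_csv`).
#' @param landmask optional `landmask` object (otherwise read from
#'   `config$landmask_geojson`; NULL skips land correction).
#' @return list of class `pipeline_result` with `tracks` (per-ptt results),
#'   `excluded` (ptt + reason), `summary_table`, `regressions`,
#'   `seasonal_proportions`, `qc`, `seed` and `config_fingerprint`.
#' @export
run_pipeline <- function(config = pipeline_config(), fixes = NULL,
                         landmask = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fixes)) {
    if (is.null(config$fixes_csv)) stop("no fixes given and no fixes_csv configured")
    fixes <- read_argos_csv(config$fixes_csv)
  }
  if (is.null(landmask) && !is.null(config$landmask_geojson))
    landmask <- read_landmask(config$landmask_geojson)

  filtered <- prefilter(fixes, window_min = config$window_min)
  ptts <- sort(unique(filtered$ptt))
  tracks <- list()
  excluded <- data.frame(ptt = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  exclude <- function(id, why) {
    excluded <<- rbind(excluded, data.frame(ptt = id, reason = why,
                                            stringsAsFactors = FALSE))
  }

  for (i in seq_along(ptts)) {
    id <- ptts[i]
    fx <- filtered[filtered$ptt == id, , drop = FALSE]
    if (nrow(fx) < config$min_total_locations) {
      exclude(id, sprintf("only %d filtered locations (threshold %d)",
                          nrow(fx), config$min_total_locations))
      next
    }
    span_ok <- tryCatch({ build_regular_grid(fx); TRUE },
                        error = function(e) FALSE)
    if (!span_ok) {
      exclude(id, "fixes span less than 2 days")
      next
    }
    mc <- config$mcmc
    mc$seed <- config$seed + i
    fit <- tryCatch(fit_track(fx, config$error_model, mc, keep_samples = TRUE),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      exclude(id, paste("model fit failed:", conditionMessage(fit)))
      next
    }
    metrics <- derive_track_metrics(fx, fit$track)
    dev_chains <- lapply(fit$samples$chains, `[[`, "deviance")
    agreement <- chain_agreement(dev_chains)
    corrected <- if (!is.null(landmask)) correct_track(fit$track, landmask)
                 else fit$track
    steps <- daily_steps(corrected, config$thresholds)
    summary_row <- per_track_summary(steps, ptt = id)
    fit$samples <- NULL
    tracks[[id]] <- list(ptt = id, fit = fit, metrics = metrics,
                         chain_agreement = agreement,
                         corrected = corrected, steps = steps,
                         summary = summary_row,
                         n_corrected = sum(corrected$corrected))
  }

  if (length(tracks) == 0) stop("no track survived filtering and fitting")

  summary_table <- do.call(rbind, lapply(tracks, `[[`, "summary"))
  rownames(summary_table) <- NULL
  cohort_mean <- aggregate_tracks(summary_table)
  summary_table <- rbind(summary_table, cohort_mean)

  regressions <- NULL
  if (length(tracks) >= 3) {
    devs <- vapply(tracks, function(t) t$fit$D, 0)
    regressions <- do.call(rbind, lapply(c("a", "b", "c", "d", "e", "f"), function(m) {
      vals <- vapply(tracks, function(t) as.numeric(t$metrics[[m]]), 0)
      r <- tryCatch(regress_deviance(vals, devs), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(metric = m, slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, f_statistic = r$f_statistic,
                 p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
    }))
    rownames(regressions) <- NULL
  }

  all_steps <- do.call(rbind, lapply(tracks, `[[`, "steps"))
  seasonal <- seasonal_mode_proportions(all_steps$label, all_steps$season)

  qc <- data.frame(
    ptt = names(tracks),
    D = vapply(tracks, function(t) t$fit$D, 0),
    DIC = vapply(tracks, function(t) t$fit$DIC, 0),
    chain_agreement = vapply(tracks, function(t) t$chain_agreement, 0),
    locs_per_day = vapply(tracks, function(t) t$metrics$a, 0),
    total_locs = vapply(tracks, function(t) as.numeric(t$metrics$e), 0),
    tracking_days = vapply(tracks, function(t) as.numeric(t$metrics$d), 0),
    n_land_corrected = vapply(tracks, function(t) as.numeric(t$n_corrected), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )

  result <- structure(list(tracks = tracks, excluded = excluded,
                           summary_table = summary_table,
                           regressions = regressions,
                           seasonal_proportions = seasonal, qc = qc,
                           seed = config$seed,
                           config_fingerprint = config_fingerprint(config)),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_outputs(result, config$output_dir)
  result
}

#' Write the pipeline output bundle
#'
#' Per-track posterior and corrected-track CSVs, daily-step CSVs, the cohort
#' summary table, the regression table, the seasonal proportions, classified
#' locations as GeoJSON, a QC report and a JSON sidecar carrying the seed
#' and configuration fingerprint.
#'
#' @param result a `pipeline_result`.
#' @param output_dir directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fmt_track <- function(tr) {
    tr$date <- strftime(tr$date, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    num <- vapply(tr, is.numeric, TRUE)
    tr[num] <- lapply(tr[num], function(v) sprintf("%.17g", v))
    tr
  }
  for (t in result$tracks) {
    utils::write.csv(fmt_track(t$fit$track),
                     file.path(output_dir, paste0("track_", t$ptt, "_posterior.csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(fmt_track(t$corrected),
                     file.path(output_dir, paste0("track_", t$ptt, "_corrected.csv")),
                     row.names = FALSE, quote = FALSE)
    st <- t$steps
    st$date <- strftime(st$date, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(st, file.path(output_dir, paste0("track_", t$ptt, "_steps.csv")),
                     row.names = FALSE, quote = FALSE)
    write_locations_geojson(t$steps,
                            file.path(output_dir, paste0("track_", t$ptt, "_locations.geojson")))
  }
  utils::write.csv(result$summary_table, file.path(output_dir, "summary_table.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(result$regressions))
    utils::write.csv(result$regressions, file.path(output_dir, "deviance_regressions.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(result$seasonal_proportions,
                   file.path(output_dir, "seasonal_proportions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$qc, file.path(output_dir, "qc_report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$excluded, file.path(output_dir, "excluded_tracks.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = result$seed,
                            config_fingerprint = result$config_fingerprint,
                            n_tracks = length(result$tracks),
                            excluded = result$excluded),
                       file.path(output_dir, "run_sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
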