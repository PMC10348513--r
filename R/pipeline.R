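# ISO-8601 UTC parser with explicit seconds ("2019-08-01T10:00:05Z" or with
# a space); base as.POSIXct guesses a minutes-only format for the T variant
.parse_iso8601 <- function(x) {
  as.POSIXct(sub("Z$", "", sub("T", " ", x)),
             format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
}

#' Read GPS fixes from CSV
#'
#' Expected columns: `bird_id`, `timestamp` (ISO-8601 UTC), `lon`, `lat`,
#' optionally `trip_id`. Timestamps must be strictly increasing per bird.
#'
#' @param path CSV file path.
#' @return validated data.frame with POSIXct timestamps.
#' @export
read_fixes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("fixes file missing column(s): ", paste(miss, collapse = ", "))
  x$timestamp <- .parse_iso8601(x$timestamp)
  if (any(is.na(x$timestamp))) {
    bad <- which(is.na(x$timestamp))[1]
    stop("unparseable timestamp at data row ", bad, " of ", path)
  }
  for (b in unique(x$bird_id)) {
    tt <- x$timestamp[x$bird_id == b]
    if (any(diff(as.numeric(tt)) <= 0))
      stop("out-of-order timestamps for bird_id ", b, " in ", path)
  }
  x
}

#' Read 1-Hz depth traces from CSV
#'
#' Expected columns: `bird_id`, `timestamp` (ISO-8601 UTC), `depth_m`
#' (non-negative). Timestamps must be strictly increasing per bird.
#'
#' @param path CSV file path.
#' @return validated data.frame with POSIXct timestamps.
#' @export
read_traces <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "depth_m")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("traces file missing column(s): ", paste(miss, collapse = ", "))
  x$timestamp <- .parse_iso8601(x$timestamp)
  if (any(is.na(x$timestamp)))
    stop("unparseable timestamp in ", path)
  if (any(x$depth_m < 0))
    stop("negative depth at data row ", which(x$depth_m < 0)[1], " of ", path)
  for (b in unique(x$bird_id)) {
    tt <- x$timestamp[x$bird_id == b]
    if (any(diff(as.numeric(tt)) <= 0))
      stop("out-of-order timestamps for bird_id ", b, " in ", path)
  }
  x
}

#' Write fixes / traces / dive events as CSV with ISO-8601 timestamps
#'
#' @param x data.frame with a `timestamp` (or `start`/`end`) POSIXct column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(x, path) {
  for (cl in intersect(c("timestamp", "start", "end", "time"), names(x)))
    if (inherits(x[[cl]], "POSIXct"))
      x[[cl]] <- format(x[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read an environmental stack from a directory of ASCII grids
#'
#' Expects `bathy.asc`, `slope.asc` (optional; derived from bathymetry when
#' absent), `sea.asc` (optional; derived as `bathy > 0`), and one
#' `sst_YYYY-MM-DD.asc` per day. A sidecar `colony.json` supplies the
#' colony coordinates.
#'
#' @param dir directory path.
#' @return an `env_stack`.
#' @export
read_rasters <- function(dir) {
  bp <- file.path(dir, "bathy.asc")
  if (!file.exists(bp)) stop("missing bathy.asc in ", dir)
  bathy <- read_ascii_grid(bp)
  sp <- file.path(dir, "slope.asc")
  slope <- if (file.exists(sp)) read_ascii_grid(sp) else gr_slope(bathy)
  mp <- file.path(dir, "sea.asc")
  sea <- if (file.exists(mp)) read_ascii_grid(mp)
         else grid_raster(ifelse(is.na(bathy$values), 0, 1),
                          bathy$xmin, bathy$ymin, bathy$cell)
  sf <- sort(list.files(dir, pattern = "^sst_\\d{4}-\\d{2}-\\d{2}\\.asc$",
                        full.names = TRUE))
  if (length(sf) == 0L) stop("no sst_YYYY-MM-DD.asc layers in ", dir)
  dates <- as.Date(sub("^sst_(.*)\\.asc$", "\\1", basename(sf)))
  sst <- lapply(sf, read_ascii_grid)
  names(sst) <- as.character(dates)
  cj <- file.path(dir, "colony.json")
  colony <- if (file.exists(cj)) {
    cc <- jsonlite::read_json(cj, simplifyVector = TRUE)
    c(lon = cc$lon, lat = cc$lat)
  } else c(lon = NA_real_, lat = NA_real_)
  structure(list(bathy = bathy, slope = slope, sea = sea, sst = sst,
                 dates = dates, colony = colony),
            class = "env_stack")
}

#' Write an environmental stack as ASCII grids plus a colony sidecar
#'
#' @param env an `env_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(env$bathy, file.path(dir, "bathy.asc"))
  write_ascii_grid(env$slope, file.path(dir, "slope.asc"))
  write_ascii_grid(env$sea, file.path(dir, "sea.asc"))
  for (i in seq_along(env$dates))
    write_ascii_grid(env$sst[[i]],
                     file.path(dir, sprintf("sst_%s.asc", env$dates[i])))
  jsonlite::write_json(list(lon = env$colony[["lon"]],
                            lat = env$colony[["lat"]]),
                       file.path(dir, "colony.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration file (JSON)
#'
#' The file holds either a `synthetic` block (arguments to [sim_config()],
#' one per year) or an `inputs` block (paths to fixes/traces CSVs and a
#' raster directory), plus optional stage parameters and a master `seed`.
#'
#' @param path JSON file path.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$synthetic) == is.null(cfg$inputs))
    stop("config must contain exactly one of 'synthetic' or 'inputs'")
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) synthetic data generation, dive processing, the
#' year-by-shape contingency test (when at least two years are present),
#' kernel utilization distributions per dive class, and per-dive-type
#' habitat suitability models with daily prediction and mean/SD maps.
#' Stage failures halt with a stage-tagged error. All randomness derives
#' from the master seed, so a fixed seed gives identical results.
#'
#' @param sims a `sim_data` object or list of them (one per year), or NULL
#'   when `fixes` / `traces` / `env` are supplied directly.
#' @param fixes,traces,env real inputs (ignored when `sims` given).
#' @param dive_types dive classes to model (default U, V-early, V-late).
#' @param cutoff a [cutoff_rule()]; default auto-detects the U-drop date.
#' @param ratio pseudo-absence to presence ratio.
#' @param select run all-subsets AICc selection per dive type (default
#'   FALSE: fit the global model; selection is expensive).
#' @param terms global smooth terms for the habitat models.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional output directory; when given, artifacts and a
#'   `manifest.json` (parameters, seeds, per-stage record counts) are
#'   written.
#' @return list of class `divehab_pipeline`: `events`, `contingency` (or
#'   NULL), `uds`, `hsm` (per dive type: fit/selection, `hsi` mean + sd),
#'   `domain`, `manifest`.
#' @export
run_pipeline <- function(sims = NULL, fixes = NULL, traces = NULL,
                         env = NULL,
                         dive_types = c("U", "V-early", "V-late"),
                         cutoff = cutoff_rule("auto"), ratio = 3,
                         select = FALSE,
                         terms = c("bathy", "slope", "sst", "lonlat"),
                         seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(sims)) {
    if (inherits(sims, "sim_data")) sims <- list(sims)
    fixes <- do.call(rbind, lapply(sims, `[[`, "fixes"))
    traces <- do.call(rbind, lapply(sims, `[[`, "traces"))
    env <- stage("synthetic_data", {
      envs <- lapply(sims, function(s) gen_environment(s$config))
      if (length(envs) == 1L) envs[[1]] else {
        # merge seasons: identical static layers, pooled SST stacks
        e <- envs[[1]]
        for (k in seq(2, length(envs))) {
          e$sst <- c(e$sst, envs[[k]]$sst)
          e$dates <- c(e$dates, envs[[k]]$dates)
        }
        o <- order(e$dates)
        e$sst <- e$sst[o]; e$dates <- e$dates[o]
        e
      }
    })
  }
  if (is.null(fixes) || is.null(traces) || is.null(env))
    stop("either sims or all of fixes/traces/env must be supplied")
  colony <- env$colony
  events <- stage("dive_processing", {
    ev <- process_dives(traces, fixes, cutoff = cutoff)
    if (nrow(ev) == 0L) stop("no dives survive detection and filtering")
    ev
  })
  contingency <- NULL
  if (length(unique(events$year)) >= 2L)
    contingency <- stage("dive_stats",
                         chi_square_independence(build_table(events)))
  cls <- ifelse(events$shape == "U", "U", paste0("V-", events$phase))
  located <- !is.na(events$lon)
  mean_range <- stage("space_use", foraging_range(fixes, colony))
  h <- smoothing_scale(mean_range)
  uds <- stage("space_use", {
    out <- list()
    for (ty in dive_types) {
      sel <- located & cls == ty
      if (sum(sel) >= 5L)
        out[[ty]] <- kde_ud(events$lon[sel], events$lat[sel], colony, h = h)
    }
    out
  })
  domain <- stage("habitat_model",
                  build_domain(colony, events$lon[located],
                               events$lat[located], env))
  hsm_out <- list()
  for (ti in seq_along(dive_types)) {
    ty <- dive_types[ti]
    sel <- located & cls == ty
    if (sum(sel) < 50L) next
    hsm_out[[ty]] <- stage("habitat_model", {
      pres <- data.frame(lon = events$lon[sel], lat = events$lat[sel],
                         date = events$date[sel], year = events$year[sel])
      recs <- sample_pseudo_absences(pres, domain, ratio = ratio,
                                     seed = seed + 1000L * ti)
      recs <- extract_covariates(recs, env)
      fit <- if (select) select_model(recs, global_terms = terms)
             else hsm_fit(recs, terms = terms)
      dts <- if (startsWith(ty, "V-"))
        sort(unique(events$date[sel])) else env$dates
      dts <- dts[dts >= min(env$dates) & dts <= max(env$dates)]
      hsi <- summarize_hsi(predict_daily(fit, env, domain, dates = dts))
      list(fit = fit, records = recs, hsi = hsi)
    })
  }
  manifest <- list(
    seed = seed,
    parameters = list(ratio = ratio, terms = terms, h_km = h,
                      mean_range_km = mean_range,
                      domain_radius_km = domain$radius_km,
                      cutoff_mode = cutoff$mode, select = select),
    counts = list(
      fixes = nrow(fixes), trace_samples = nrow(traces),
      dives = nrow(events),
      dives_by_class = as.list(table(cls)),
      located_dives = sum(located),
      presences = vapply(hsm_out, function(x) sum(x$records$label == 1), 0L),
      pseudo_absences = vapply(hsm_out, function(x) sum(x$records$label == 0), 0L),
      domain_cells = sum(domain$mask$values == 1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tracking_csv(events, file.path(out_dir, "dive_events.csv"))
    if (!is.null(contingency)) {
      utils::write.csv(contingency$observed,
                       file.path(out_dir, "table_observed.csv"))
      utils::write.csv(round(contingency$expected, 2),
                       file.path(out_dir, "table_expected.csv"))
    }
    for (ty in names(hsm_out)) {
      slug <- gsub("[^A-Za-z0-9]", "_", ty)
      write_ascii_grid(hsm_out[[ty]]$hsi$mean,
                       file.path(out_dir, sprintf("hsi_mean_%s.asc", slug)))
      write_ascii_grid(hsm_out[[ty]]$hsi$sd,
                       file.path(out_dir, sprintf("hsi_sd_%s.asc", slug)))
    }
    for (ty in names(uds)) {
      slug <- gsub("[^A-Za-z0-9]", "_", ty)
      for (p in c(0.5, 0.95))
        write_isopleth_geojson(uds[[ty]], isopleth(uds[[ty]], p),
                               file.path(out_dir, sprintf("ud%d_%s.geojson",
                                                          round(100 * p), slug)),
                               level = p)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(events = events, contingency = contingency, uds = uds,
                 hsm = hsm_out, domain = domain, h = h,
                 manifest = manifest),
            class = "divehab_pipeline")
}

#' @export
print.divehab_pipeline <- function(x, ...) {
  cat("divehab pipeline result\n")
  cat(sprintf("  %d dive events (%s)\n", nrow(x$events),
              paste(sprintf("%s: %d", names(x$manifest$counts$dives_by_class),
                            unlist(x$manifest$counts$dives_by_class)),
                    collapse = ", ")))
  if (!is.null(x$contingency))
    cat(sprintf("  chi-square = %.2f (df %d)\n",
                x$contingency$statistic, x$contingency$df))
  cat(sprintf("  h = %.2f km; domain %.0f km radius, %d cells\n",
              x$h, x$domain$radius_km, x$manifest$counts$domain_cells))
  cat(sprintf("  habitat models: %s\n",
              paste(names(x$hsm), collapse = ", ")))
  invisible(x)
}
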