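#' Configuration for the central-place foraging simulator
#'
#' Bundles every knob of the synthetic data generator: colony position,
#' tracking effort, the seasonal decline in U-dive frequency, the habitat
#' preference weights that define where each dive shape occurs, and the
#' environmental field parameters. Defaults emulate a gannet-like system: a
#' coastal colony, 15-min GPS fixes, 1-Hz depth sampling during submersion,
#' U-shaped dives clustered over shallow, flat, cool-water cells and V-shaped
#' dives spread over a broader, warmer, steeper-sloped habitat, with the
#' daily U-dive proportion dropping sharply partway through chick-rearing.
#'
#' @param colony named numeric `c(lon, lat)` of the colony, decimal degrees.
#' @param n_birds number of tracked birds.
#' @param date_range character or Date vector of length 2, first and last
#'   tracking day (one breeding season).
#' @param fix_interval GPS fix interval in seconds (default 900 = 15 min).
#' @param dive_rate mean number of dives per foraging trip (Poisson).
#' @param trips_per_day foraging trips per bird per day.
#' @param u_fraction_by_day function mapping day-of-study (1-based integer)
#'   to the probability that a dive is U-shaped, values in `[0, 1]`. The
#'   default is a step: 0.7 before `u_drop_day`, 0.05 from it on.
#' @param u_drop_day day-of-study at which the default U-dive proportion
#'   drops; ignored when `u_fraction_by_day` is supplied. Defaults to 45
#'   percent of the season.
#' @param habitat_truth list with elements `U` and `V`, each a named numeric
#'   vector of weights on the standardized covariates `bathy`, `slope`,
#'   `sst`. Dive sites for a shape are drawn with probability proportional
#'   to `exp(weights %*% z(covariates))` over sea cells.
#' @param sst_field list: `mean_start` (deg C on day 1), `warming_per_day`
#'   (deg C/day), `lat_gradient` (deg C per degree latitude), `noise_sd`
#'   (sd of smooth daily spatial noise, deg C).
#' @param grid list: `xmin`, `xmax`, `ymin`, `ymax` (degrees), `cell`
#'   (degrees, > 0).
#' @param depth_noise_sd Gaussian sensor noise sd on depth samples, m.
#' @param seed integer seed; all outputs are reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(colony = c(lon = -54.18, lat = 46.81),
                       n_birds = 8,
                       date_range = c("2019-07-15", "2019-09-10"),
                       fix_interval = 900,
                       dive_rate = 8,
                       trips_per_day = 1,
                       u_fraction_by_day = NULL,
                       u_drop_day = NULL,
                       habitat_truth = list(
                         U = c(bathy = -1.3, slope = -0.9, sst = -0.9),
                         V = c(bathy = -0.3, slope = 0.5, sst = 0.7)),
                       sst_field = list(mean_start = 11, warming_per_day = 0.1,
                                        lat_gradient = -1.5, noise_sd = 0.3),
                       grid = list(xmin = -57, xmax = -52,
                                   ymin = 45.3, ymax = 47.2, cell = 0.05),
                       depth_noise_sd = 0.1,
                       seed = 1L) {
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || any(is.na(date_range)) ||
      date_range[2] < date_range[1])
    stop("date_range must be two valid dates, start <= end")
  if (!is.numeric(grid$cell) || grid$cell <= 0)
    stop("grid cell size must be > 0")
  n_days <- as.integer(date_range[2] - date_range[1]) + 1L
  if (is.null(u_drop_day)) u_drop_day <- max(2L, floor(0.45 * n_days))
  if (is.null(u_fraction_by_day)) {
    force(u_drop_day)
    u_fraction_by_day <- function(day) ifelse(day < u_drop_day, 0.7, 0.05)
  }
  uf <- u_fraction_by_day(seq_len(n_days))
  if (any(uf < 0 | uf > 1)) stop("u_fraction_by_day values must lie in [0, 1]")
  for (s in names(habitat_truth))
    if (!all(names(habitat_truth[[s]]) %in% c("bathy", "slope", "sst")))
      stop("habitat_truth weights must be named bathy/slope/sst")
  structure(list(colony = colony, n_birds = n_birds, date_range = date_range,
                 n_days = n_days, fix_interval = fix_interval,
                 dive_rate = dive_rate, trips_per_day = trips_per_day,
                 u_fraction_by_day = u_fraction_by_day,
                 habitat_truth = habitat_truth, sst_field = sst_field,
                 grid = grid, depth_noise_sd = depth_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# smooth low-frequency random field on cell-centre coords (sum of sinusoids)
.smooth_field <- function(lonc, latc, amplitude, n_waves = 4L) {
  f <- matrix(0, length(latc), length(lonc))
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.4, 1.6); fy <- stats::runif(1, 0.4, 1.6)
    px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1, 0, amplitude / sqrt(n_waves))
    f <- f + a * outer(sin(fy * latc * 2 * pi / diff(range(latc)) + py),
                       sin(fx * lonc * 2 * pi / diff(range(lonc)) + px))
  }
  f
}

#' Generate the synthetic environment (bathymetry, slope, sea mask, daily SST)
#'
#' Builds a coastal shelf south of the colony: land north of the coastline,
#' depth increasing offshore with a cross-shelf ridge and smooth noise (so
#' slope varies), and a daily SST stack that is spatially smooth (latitudinal
#' gradient plus low-frequency noise) and warms linearly over the season.
#'
#' @param config a [sim_config()].
#' @return a list of class `env_stack`: `bathy` (m, positive down, NA on
#'   land), `slope` (degrees), `sea` (1 = sea, 0 = land), `sst` (named list
#'   of `grid_raster`, one per day), `dates` (Date vector), `colony`.
#' @export
gen_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  nx <- round((g$xmax - g$xmin) / g$cell)
  ny <- round((g$ymax - g$ymin) / g$cell)
  if (nx < 2L || ny < 2L) stop("degenerate grid: need at least 2 x 2 cells")
  lon0 <- config$colony[["lon"]]; lat0 <- config$colony[["lat"]]
  if (lon0 < g$xmin || lon0 > g$xmax || lat0 < g$ymin || lat0 > g$ymax)
    stop("grid extent must contain the colony")
  set.seed(config$seed)
  lonc <- g$xmin + (seq_len(nx) - 0.5) * g$cell
  latc <- g$ymin + (seq_len(ny) - 0.5) * g$cell
  coast_lat <- lat0 + 0.02
  # depth grows southward off the coast; a lon-wise ridge adds slope contrast
  dist_off <- outer(pmax(coast_lat - latc, 0), rep(1, nx))
  ridge <- outer(rep(1, ny), 120 * sin((lonc - g$xmin) * 2 * pi / 2.3)^2)
  depth <- 15 + 520 * dist_off + ridge * sqrt(dist_off) +
    .smooth_field(lonc, latc, 25)
  land <- matrix(rep(latc > coast_lat, nx), ny, nx)
  depth[land] <- NA_real_
  depth[!land] <- pmax(depth[!land], 2)
  bathy <- grid_raster(depth, g$xmin, g$ymin, g$cell)
  slope <- gr_slope(bathy)
  slope$values[!land & is.na(slope$values)] <- 0
  sea <- grid_raster(ifelse(land, 0, 1), g$xmin, g$ymin, g$cell)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  sf <- config$sst_field
  sst <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    f <- sf$mean_start + sf$warming_per_day * (i - 1) +
      sf$lat_gradient * outer(latc - lat0, rep(1, nx)) +
      .smooth_field(lonc, latc, sf$noise_sd)
    f[land] <- NA_real_
    sst[[i]] <- grid_raster(f, g$xmin, g$ymin, g$cell)
  }
  names(sst) <- as.character(dates)
  structure(list(bathy = bathy, slope = slope, sea = sea, sst = sst,
                 dates = dates, colony = config$colony),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d x %d cells, %d sea, %d SST days (%s .. %s)\n",
              nrow(x$bathy$values), ncol(x$bathy$values),
              sum(x$sea$values == 1), length(x$dates),
              min(x$dates), max(x$dates)))
  invisible(x)
}

# linear predictor of a truth weight vector over sea cells, given covariate
# z-scores; returns matrix of cell selection weights (0 on land)
.truth_weights <- function(env, w, sst_values) {
  sea <- env$sea$values == 1
  zs <- function(m) { v <- m[sea]; (m - mean(v)) / stats::sd(v) }
  lp <- matrix(0, nrow(env$bathy$values), ncol(env$bathy$values))
  if (!is.null(w[["bathy"]]) && !is.na(w["bathy"]))
    lp <- lp + w[["bathy"]] * zs(env$bathy$values)
  if (!is.null(w[["slope"]]) && !is.na(w["slope"]))
    lp <- lp + w[["slope"]] * zs(env$slope$values)
  if (!is.null(w[["sst"]]) && !is.na(w["sst"]))
    lp <- lp + w[["sst"]] * zs(sst_values)
  p <- exp(lp)
  p[!sea] <- 0
  p
}

#' True habitat suitability surface for a dive shape
#'
#' The season-average cell selection probability implied by the generator's
#' habitat weights, rescaled to `[0, 1]` over sea cells. This is the ground
#' truth that fitted habitat models are benchmarked against.
#'
#' @param config a [sim_config()].
#' @param env the matching [gen_environment()] output.
#' @param shape `"U"` or `"V"`.
#' @return a `grid_raster` of suitability in `[0, 1]` (NA on land).
#' @export
true_suitability <- function(config, env, shape = c("U", "V")) {
  shape <- match.arg(shape)
  w <- config$habitat_truth[[shape]]
  acc <- 0
  for (i in seq_along(env$dates))
    acc <- acc + .truth_weights(env, w, env$sst[[i]]$values)
  acc <- acc / length(env$dates)
  sea <- env$sea$values == 1
  out <- acc
  out[sea] <- (acc[sea] - min(acc[sea])) / (max(acc[sea]) - min(acc[sea]))
  out[!sea] <- NA_real_
  grid_raster(out, env$bathy$xmin, env$bathy$ymin, env$bathy$cell)
}

# one simulated dive's 1-Hz depth profile (no noise); U has a bottom phase
# comfortably over the classifier margins, V is a brief shallow spike
.dive_profile <- function(shape) {
  if (shape == "U") {
    d <- stats::runif(1, 10, 22)
    nb <- sample(5:12, 1)
    down <- seq(2, d, length.out = max(3L, ceiling(d / 2)))
    c(down, rep(d, nb), rev(down))
  } else {
    d <- stats::runif(1, 1.3, 7.5)
    k <- sample(2:3, 1)                      # half-width; duration 5-7 s
    up <- pmax(seq(d / (k + 1), d, length.out = k), 0.75)
    c(up, rev(up)[-1])
  }
}

#' Simulate central-place foraging trips, GPS fixes and depth traces
#'
#' Each bird performs round trips from the colony. Per trip, dive sites are
#' drawn over sea cells with probability proportional to
#' `exp(habitat weights . standardized covariates)` for that day's SST, so
#' the marginal spatial density of dives follows the configured habitat
#' truth. The bird travels colony to site to ... to colony at constant speed;
#' GPS fixes are emitted every `fix_interval` seconds along the path, plus
#' one fix at arrival at each dive site (so every dive has a fix within the
#' 30-min association window). Each dive emits a 1-Hz depth trace — U-shaped
#' (descent, bottom phase of at least 5 s deeper than 10 m, ascent) or
#' V-shaped (spike of at most 7 s, maximum depth under 8 m) — with Gaussian
#' sensor noise and flanking surface samples.
#'
#' @param config a [sim_config()].
#' @param env the matching [gen_environment()] output.
#' @return list of class `sim_data`: `fixes` (bird_id, trip_id, timestamp
#'   POSIXct UTC, lon, lat), `traces` (bird_id, timestamp, depth_m), `truth`
#'   (list: `dives` data.frame with dive_id, bird_id, trip_id, date, time,
#'   lon, lat, shape; `suitability` list of U/V `grid_raster`), and `config`.
#' @export
gen_tracks_and_dives <- function(config, env) {
  stopifnot(inherits(config, "sim_config"), inherits(env, "env_stack"))
  for (s in names(config$habitat_truth)) {
    w <- config$habitat_truth[[s]]
    bad <- setdiff(names(w), c("bathy", "slope", "sst"))
    if (length(bad)) stop("habitat_truth references missing layer: ", bad[1])
  }
  set.seed(config$seed + 1L)
  sea_idx <- which(env$sea$values == 1)
  lonc <- gr_xcoords(env$bathy); latc <- gr_ycoords(env$bathy)
  cellw <- env$bathy$cell
  day_weights <- lapply(c(U = "U", V = "V"), function(s)
    lapply(seq_along(env$dates), function(i)
      .truth_weights(env, config$habitat_truth[[s]], env$sst[[i]]$values)[sea_idx]))
  speed <- 15                                  # m/s cruise speed
  fixes <- list(); traces <- list(); dives <- list()
  dive_id <- 0L
  for (b in seq_len(config$n_birds)) {
    bird <- sprintf("bird%02d", b)
    clock <- as.POSIXct(paste(config$date_range[1] - 1, "00:00:00"), tz = "UTC")
    for (di in seq_len(config$n_days)) {
      date <- config$date_range[1] + (di - 1L)
      for (tr in seq_len(config$trips_per_day)) {
        trip <- sprintf("%s_%s_t%d", bird, format(date), tr)
        n_dv <- max(1L, stats::rpois(1, config$dive_rate))
        is_u <- stats::runif(n_dv) < config$u_fraction_by_day(di)
        shp <- ifelse(is_u, "U", "V")
        cells <- integer(n_dv)
        for (j in seq_len(n_dv))
          cells[j] <- sea_idx[sample.int(length(sea_idx), 1L,
                                         prob = day_weights[[shp[j]]][[di]])]
        rc <- arrayInd(cells, dim(env$sea$values))
        dlon <- lonc[rc[, 2]] + stats::runif(n_dv, -0.5, 0.5) * cellw
        dlat <- latc[rc[, 1]] + stats::runif(n_dv, -0.5, 0.5) * cellw
        # visit sites in greedy nearest-neighbour order to keep trips short
        ord <- integer(n_dv); left <- seq_len(n_dv)
        cur <- c(env$colony[["lon"]], env$colony[["lat"]])
        for (j in seq_len(n_dv)) {
          dd <- geosphere::distHaversine(cur, cbind(dlon[left], dlat[left]))
          pick <- left[which.min(dd)]
          ord[j] <- pick; left <- setdiff(left, pick)
          cur <- c(dlon[pick], dlat[pick])
        }
        dlon <- dlon[ord]; dlat <- dlat[ord]; shp <- shp[ord]
        cells <- cells[ord]
        # waypoints: colony -> sites -> colony
        wlon <- c(env$colony[["lon"]], dlon, env$colony[["lon"]])
        wlat <- c(env$colony[["lat"]], dlat, env$colony[["lat"]])
        seg <- geosphere::distHaversine(cbind(wlon[-length(wlon)], wlat[-length(wlat)]),
                                        cbind(wlon[-1], wlat[-1]))
        t0 <- as.POSIXct(paste(date, "06:00:00"), tz = "UTC") +
          (b - 1) * 120 + (tr - 1) * 6 * 3600
        t0 <- max(t0, clock + 300)             # never overlap the previous trip
        arr <- t0 + cumsum(c(0, seg / speed))  # arrival at each waypoint
        # scheduled fixes along the path + one at each dive-site arrival
        tt <- seq(0, as.numeric(arr[length(arr)] - t0, units = "secs"),
                  by = config$fix_interval)
        pos_at <- function(tsec) {
          cum <- as.numeric(arr - t0, units = "secs")
          i <- findInterval(tsec, cum, rightmost.closed = TRUE)
          i <- pmin(pmax(i, 1L), length(cum) - 1L)
          f <- (tsec - cum[i]) / pmax(cum[i + 1L] - cum[i], 1e-9)
          cbind(wlon[i] + f * (wlon[i + 1L] - wlon[i]),
                wlat[i] + f * (wlat[i + 1L] - wlat[i]))
        }
        ft <- sort(unique(round(c(tt, as.numeric(arr[2:(1 + n_dv)] - t0,
                                                 units = "secs")))))
        fp <- pos_at(ft)
        fixes[[length(fixes) + 1L]] <- data.frame(
          bird_id = bird, trip_id = trip, timestamp = t0 + ft,
          lon = fp[, 1], lat = fp[, 2])
        # dives: 2 min after arrival at each site; never overlapping
        prev_end <- t0
        for (j in seq_len(n_dv)) {
          dive_id <- dive_id + 1L
          dt <- round(max(arr[1L + j] + 120, prev_end + 10))
          prof <- .dive_profile(shp[j])
          prof <- pmax(prof + stats::rnorm(length(prof), 0, config$depth_noise_sd), 0.05)
          samp <- c(0, 0, prof, 0, 0)          # flanking surface samples
          traces[[length(traces) + 1L]] <- data.frame(
            bird_id = bird, timestamp = dt + seq_along(samp) - 1L,
            depth_m = samp)
          dives[[length(dives) + 1L]] <- data.frame(
            dive_id = dive_id, bird_id = bird, trip_id = trip, date = date,
            time = dt + 2, lon = dlon[j], lat = dlat[j], shape = shp[j])
          prev_end <- dt + length(samp)
        }
        clock <- round(max(arr[length(arr)], prev_end + 60))
      }
    }
  }
  truth <- list(
    dives = do.call(rbind, dives),
    suitability = list(U = true_suitability(config, env, "U"),
                       V = true_suitability(config, env, "V")))
  structure(list(fixes = do.call(rbind, fixes),
                 traces = do.call(rbind, traces),
                 truth = truth, config = config),
            class = "sim_data")
}

#' Match detected dive events to simulator ground truth
#'
#' Pairs each detected dive with the generating dive of the same bird whose
#' true start time is nearest (within `tol` seconds); detection can shift a
#' dive start by a sample when noise puts the first sample under the
#' surface threshold.
#'
#' @param events dive-event data.frame from [process_dives()].
#' @param truth the `truth$dives` data.frame of a `sim_data` object.
#' @return integer vector: for each event, the row index into `truth` (NA
#'   when no truth dive lies within `tol`).
#' @param tol matching tolerance in seconds (default 5).
#' @export
match_truth <- function(events, truth, tol = 5) {
  out <- rep(NA_integer_, nrow(events))
  for (b in unique(events$bird_id)) {
    ei <- which(events$bird_id == b)
    ti <- which(truth$bird_id == b)
    if (!length(ti)) next
    tt <- as.numeric(truth$time[ti])
    for (i in ei) {
      dd <- abs(tt - as.numeric(events$start[i]))
      j <- which.min(dd)
      if (dd[j] <= tol) out[i] <- ti[j]
    }
  }
  out
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data: %d birds, %d fixes, %d depth samples, %d true dives (%d U / %d V)\n",
              length(unique(x$fixes$bird_id)), nrow(x$fixes), nrow(x$traces),
              nrow(x$truth$dives), sum(x$truth$dives$shape == "U"),
              sum(x$truth$dives$shape == "V")))
  invisible(x)
}
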