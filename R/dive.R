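#' Detect dives in a 1-Hz depth trace
#'
#' A dive segment is a maximal run of consecutive samples with depth above
#' `surface_threshold`; runs separated by at least one surface sample are
#' distinct segments.
#'
#' @param timestamp numeric or POSIXct sample times, strictly increasing.
#' @param depth_m non-negative depth samples (m, positive down).
#' @param surface_threshold depth above which a sample counts as submerged
#'   (m, default 0.5 — a guard against sensor noise at the surface).
#' @return list of segments, each a list with `start`, `end` (indices into
#'   the trace), `timestamp`, `depth_m` (the sample slices).
#' @export
detect_dives <- function(timestamp, depth_m, surface_threshold = 0.5) {
  if (length(timestamp) != length(depth_m))
    stop("timestamp and depth_m lengths differ")
  if (length(timestamp) == 0L) return(list())
  if (any(diff(as.numeric(timestamp)) <= 0))
    stop("timestamps must be strictly increasing")
  sub <- depth_m > surface_threshold
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    list(start = starts[i], end = ends[i],
         timestamp = timestamp[idx], depth_m = depth_m[idx])
  })
}

#' Dive metrics: maximum depth, duration, bottom time
#'
#' Duration counts the terminal sample interval (a single-sample dive at
#' 1 Hz lasts 1 s, not 0 s). Bottom time is the total time spent at depth
#' greater than or equal to `bottom_frac` of the dive's maximum depth — the
#' package's operational definition of the bottom phase.
#'
#' @param segment a segment as returned by [detect_dives()].
#' @param bottom_frac fraction of maximum depth defining the bottom phase
#'   (default 0.8).
#' @param interval nominal sampling interval in seconds (default 1).
#' @return named numeric: `max_depth` (m), `duration` (s), `bottom_time` (s).
#' @export
compute_metrics <- function(segment, bottom_frac = 0.8, interval = 1) {
  d <- segment$depth_m
  if (length(d) == 0L) stop("empty dive segment")
  t <- as.numeric(segment$timestamp)
  max_depth <- max(d)
  duration <- t[length(t)] - t[1] + interval
  bottom_time <- sum(d >= bottom_frac * max_depth) * interval
  c(max_depth = max_depth, duration = duration, bottom_time = bottom_time)
}

#' Classify a dive as U- or V-shaped
#'
#' Default rule: U if and only if `bottom_time >= bottom_thr`, or
#' (`duration > duration_thr` and `max_depth > depth_thr`); otherwise V.
#' This makes V the exact complement of U. The published clause pairs for U
#' and V are not logical complements (a dive can satisfy neither printed
#' description), so the precedence is an explicit package choice; a
#' `"strict_and"` variant (U requires all three conditions) is provided.
#'
#' @param max_depth,duration,bottom_time dive metrics (m, s, s); vectorized.
#' @param bottom_thr bottom-time threshold, s (default 3).
#' @param duration_thr duration threshold, s (default 10).
#' @param depth_thr depth threshold, m (default 8).
#' @param rule `"or"` (default) or `"strict_and"`.
#' @return character vector of `"U"` / `"V"`.
#' @export
classify_dive <- function(max_depth, duration, bottom_time,
                          bottom_thr = 3, duration_thr = 10, depth_thr = 8,
                          rule = c("or", "strict_and")) {
  rule <- match.arg(rule)
  u <- if (rule == "or")
    bottom_time >= bottom_thr | (duration > duration_thr & max_depth > depth_thr)
  else
    bottom_time >= bottom_thr & duration > duration_thr & max_depth > depth_thr
  ifelse(u, "U", "V")
}

#' Remove dives shallower than a minimum depth
#'
#' Drops dives with maximum depth below `min_depth` (default 1 m); such
#' excursions are likely bathing, not prey pursuit. Dives exactly at the
#' threshold are retained. Idempotent.
#'
#' @param events dive-event data.frame with a `max_depth` column.
#' @param min_depth minimum maximum-depth to retain, m.
#' @return the filtered data.frame.
#' @export
filter_dives <- function(events, min_depth = 1) {
  events[events$max_depth >= min_depth, , drop = FALSE]
}

#' Associate each dive with its foraging GPS location
#'
#' A dive's location is the fix of the same bird recorded within `window`
#' seconds before (or at) the dive start; when several qualify, the latest
#' (closest in time to the dive) is used. Dives with no qualifying fix keep
#' NA coordinates.
#'
#' @param events dive-event data.frame (`bird_id`, `start`).
#' @param fixes GPS fix data.frame (`bird_id`, `timestamp`, `lon`, `lat`,
#'   optionally `trip_id`).
#' @param window association window in seconds (default 1800 = 30 min).
#' @return `events` with `lon`, `lat` (and `trip_id` if present in `fixes`)
#'   columns added.
#' @export
assign_foraging_locations <- function(events, fixes, window = 1800) {
  n <- nrow(events)
  events$lon <- rep(NA_real_, n); events$lat <- rep(NA_real_, n)
  has_trip <- "trip_id" %in% names(fixes)
  if (has_trip) events$trip_id <- rep(NA_character_, n)
  if (n == 0L || nrow(fixes) == 0L) return(events)
  for (b in unique(events$bird_id)) {
    fi <- fixes[fixes$bird_id == b, , drop = FALSE]
    if (nrow(fi) == 0L) next
    fi <- fi[order(fi$timestamp), , drop = FALSE]
    ft <- as.numeric(fi$timestamp)
    ei <- which(events$bird_id == b)
    st <- as.numeric(events$start[ei])
    pos <- findInterval(st, ft)                     # latest fix at/before start
    ok <- pos >= 1L & (st - ft[pmax(pos, 1L)]) <= window
    sel <- ei[ok]
    events$lon[sel] <- fi$lon[pos[ok]]
    events$lat[sel] <- fi$lat[pos[ok]]
    if (has_trip) events$trip_id[sel] <- fi$trip_id[pos[ok]]
  }
  events
}

#' Rule describing how the early/late chick-rearing cut-off date is found
#'
#' @param mode `"fixed_date"` (use supplied per-year calendar dates) or
#'   `"auto"` (detect the day with the sharpest drop in the daily
#'   proportion of U-shaped dives).
#' @param fixed_dates named vector/list of dates, names = years (as
#'   character), required in `fixed_date` mode.
#' @return a list of class `cutoff_rule`.
#' @export
cutoff_rule <- function(mode = c("fixed_date", "auto"), fixed_dates = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_date") {
    if (is.null(fixed_dates)) stop("fixed_date mode requires fixed_dates")
    fixed_dates <- vapply(fixed_dates, function(d) as.character(as.Date(d)), "")
  }
  structure(list(mode = mode, fixed_dates = fixed_dates), class = "cutoff_rule")
}

#' Detect the per-year early/late cut-off date
#'
#' In `auto` mode the cut-off for a year is the day `d` (among observed dive
#' days) maximizing the contrast mean(daily U-proportion before `d`) minus
#' mean(from `d` on), scanned exhaustively; ties break to the earliest day.
#' If the daily proportions are constant the contrast is flat: a warning is
#' issued and the midpoint split is returned. `fixed_date` mode echoes the
#' configured date for each year present in the events.
#'
#' @param events dive-event data.frame with `date` (Date) and `shape`.
#' @param rule a [cutoff_rule()].
#' @return named list of Dates, one per year (names = year as character).
#' @export
detect_cutoff <- function(events, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  years <- sort(unique(format(events$date, "%Y")))
  out <- list()
  for (y in years) {
    if (rule$mode == "fixed_date") {
      if (is.null(rule$fixed_dates[[y]]))
        stop("no fixed cutoff date configured for year ", y)
      out[[y]] <- as.Date(rule$fixed_dates[[y]])
      next
    }
    ev <- events[format(events$date, "%Y") == y, , drop = FALSE]
    days <- sort(unique(ev$date))
    if (length(days) < 7L)
      stop("auto cutoff needs at least 7 days of data in year ", y)
    prop <- vapply(days, function(d) mean(ev$shape[ev$date == d] == "U"), 0)
    contrasts <- vapply(2:length(days), function(k)
      mean(prop[1:(k - 1)]) - mean(prop[k:length(prop)]), 0)
    if (max(contrasts) - min(contrasts) < 1e-12) {
      warning("constant daily U-proportions in year ", y,
              "; returning midpoint split")
      out[[y]] <- days[ceiling(length(days) / 2)]
    } else {
      out[[y]] <- days[1L + which.max(contrasts)]
    }
  }
  out
}

#' Label dives early or late chick-rearing
#'
#' Dives dated before the year's cut-off are `early`; dives on or after it
#' are `late`. All dives receive a label (the U/V tabulation ignores phase
#' for U dives; carrying it costs nothing and keeps bookkeeping uniform).
#'
#' @param events dive-event data.frame with `date`.
#' @param cutoffs named list of per-year cut-off Dates (from
#'   [detect_cutoff()]).
#' @return `events` with a `phase` column (`"early"` / `"late"`).
#' @export
phase_labels <- function(events, cutoffs) {
  yr <- format(events$date, "%Y")
  cut <- as.Date(vapply(yr, function(y) {
    if (is.null(cutoffs[[y]])) stop("no cutoff for year ", y)
    as.character(cutoffs[[y]])
  }, ""))
  events$phase <- ifelse(events$date < cut, "early", "late")
  events
}

#' Daily dive counts and shape proportions
#'
#' @param events dive-event data.frame with `date` and `shape`.
#' @return data.frame (one row per day with at least one dive): `date`,
#'   `n_dives`, `prop_U`, `prop_V`; proportions sum to 1 on every row.
#' @export
daily_summary <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(date = as.Date(character()), n_dives = integer(),
                      prop_U = numeric(), prop_V = numeric()))
  days <- sort(unique(events$date))
  n <- vapply(days, function(d) sum(events$date == d), 0L)
  pu <- vapply(days, function(d) mean(events$shape[events$date == d] == "U"), 0)
  data.frame(date = days, n_dives = n, prop_U = pu, prop_V = 1 - pu)
}

#' Full dive-processing chain: detect, measure, classify, locate, phase
#'
#' Applies [detect_dives()], [compute_metrics()], the minimum-depth filter,
#' [classify_dive()], [assign_foraging_locations()] and (when a cut-off rule
#' is given) [phase_labels()] per bird, returning one row per retained dive.
#' Processing is per-bird and order-independent: shuffling input rows does
#' not change the result.
#'
#' @param traces depth-trace data.frame: `bird_id`, `timestamp`, `depth_m`.
#' @param fixes optional GPS fix data.frame for location association.
#' @param surface_threshold,bottom_frac,min_depth,window,rule,
#'   bottom_thr,duration_thr,depth_thr parameters passed to the stages.
#' @param cutoff optional [cutoff_rule()]; when supplied, `phase` labels are
#'   added.
#' @return data.frame of dive events: `bird_id`, `start`, `end`, `date`,
#'   `year`, `max_depth`, `duration`, `bottom_time`, `shape`, and `lon`,
#'   `lat` (+ `trip_id`, `phase`) when available.
#' @export
process_dives <- function(traces, fixes = NULL, surface_threshold = 0.5,
                          bottom_frac = 0.8, min_depth = 1, window = 1800,
                          bottom_thr = 3, duration_thr = 10, depth_thr = 8,
                          rule = c("or", "strict_and"), cutoff = NULL) {
  rule <- match.arg(rule)
  need <- c("bird_id", "timestamp", "depth_m")
  miss <- setdiff(need, names(traces))
  if (length(miss)) stop("traces missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (b in sort(unique(traces$bird_id))) {
    tr <- traces[traces$bird_id == b, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (any(duplicated(tr$timestamp)))
      stop("non-monotone timestamps in trace for bird ", b)
    segs <- detect_dives(tr$timestamp, tr$depth_m, surface_threshold)
    for (s in segs) {
      m <- compute_metrics(s, bottom_frac = bottom_frac)
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = b, start = s$timestamp[1],
        end = s$timestamp[length(s$timestamp)],
        max_depth = m[["max_depth"]], duration = m[["duration"]],
        bottom_time = m[["bottom_time"]])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(bird_id = character(), start = numeric(),
                      end = numeric(), max_depth = numeric(),
                      duration = numeric(), bottom_time = numeric(),
                      shape = character(), date = as.Date(character()),
                      year = character()))
  ev <- do.call(rbind, rows)
  ev <- filter_dives(ev, min_depth)
  ev$shape <- classify_dive(ev$max_depth, ev$duration, ev$bottom_time,
                            bottom_thr, duration_thr, depth_thr, rule)
  ev$date <- as.Date(as.POSIXct(as.numeric(ev$start),
                                origin = "1970-01-01", tz = "UTC"))
  ev$year <- format(ev$date, "%Y")
  if (!is.null(fixes)) ev <- assign_foraging_locations(ev, fixes, window)
  if (!is.null(cutoff)) ev <- phase_labels(ev, detect_cutoff(ev, cutoff))
  rownames(ev) <- NULL
  ev
}
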