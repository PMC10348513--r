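#' Analysis domain: sea cells within a scaled maximum dive distance
#'
#' The domain is the set of sea cells whose centre lies within
#' `scale` times the maximum great-circle distance from the colony to any
#' dive location. With the default scale 1.1 this reproduces the convention
#' of padding the observed foraging extent by 10%.
#'
#' @param colony named numeric `c(lon, lat)`.
#' @param lon,lat dive locations, decimal degrees (NA allowed, ignored).
#' @param env an `env_stack`.
#' @param scale radius multiplier (default 1.1).
#' @return object of class `hsm_domain`: `mask` (`grid_raster`, 1 inside),
#'   `radius_km`, `colony`.
#' @export
build_domain <- function(colony, lon, lat, env, scale = 1.1) {
  ok <- !is.na(lon) & !is.na(lat)
  if (!any(ok)) stop("need at least one dive location")
  dmax <- max(geosphere::distHaversine(c(colony[["lon"]], colony[["lat"]]),
                                       cbind(lon[ok], lat[ok]))) / 1000
  radius <- scale * dmax
  sea <- env$sea
  lonc <- gr_xcoords(sea); latc <- gr_ycoords(sea)
  cc <- expand.grid(lat = latc, lon = lonc)       # row-major over matrix
  dd <- geosphere::distHaversine(c(colony[["lon"]], colony[["lat"]]),
                                 cbind(cc$lon, cc$lat)) / 1000
  inside <- matrix(dd <= radius, nrow(sea$values), ncol(sea$values))
  m <- ifelse(inside & sea$values == 1, 1, 0)
  if (sum(m) == 0) stop("empty domain: no sea cells within the radius")
  structure(list(mask = grid_raster(m, sea$xmin, sea$ymin, sea$cell),
                 radius_km = radius, colony = colony),
            class = "hsm_domain")
}

#' @export
print.hsm_domain <- function(x, ...) {
  cat(sprintf("hsm_domain: %d sea cells within %.1f km of the colony\n",
              sum(x$mask$values == 1), x$radius_km))
  invisible(x)
}

#' Sample pseudo-absence background points
#'
#' For each presence, `ratio` points are placed uniformly over the domain's
#' sea cells (uniform within the cell), with a uniform random date drawn
#' from that presence's year's tracking period (the presence date range of
#' that year). Reproducible from `seed`.
#'
#' @param presences data.frame with `lon`, `lat`, `date` (Date), `year`.
#' @param domain an `hsm_domain`.
#' @param ratio pseudo-absences per presence (default 3).
#' @param seed integer seed.
#' @return data.frame of presences (label 1) stacked over pseudo-absences
#'   (label 0), columns `lon`, `lat`, `date`, `year`, `label`.
#' @export
sample_pseudo_absences <- function(presences, domain, ratio = 3, seed = 1L) {
  stopifnot(inherits(domain, "hsm_domain"))
  set.seed(as.integer(seed))
  mask <- domain$mask
  cells <- which(mask$values == 1)
  if (length(cells) == 0L) stop("empty domain")
  pres <- data.frame(lon = presences$lon, lat = presences$lat,
                     date = as.Date(presences$date),
                     year = as.character(presences$year), label = 1L)
  n_abs <- ratio * nrow(pres)
  if (n_abs == 0L) return(pres)
  lonc <- gr_xcoords(mask); latc <- gr_ycoords(mask)
  pick <- cells[sample.int(length(cells), n_abs, replace = TRUE)]
  rc <- arrayInd(pick, dim(mask$values))
  alon <- lonc[rc[, 2]] + stats::runif(n_abs, -0.5, 0.5) * mask$cell
  alat <- latc[rc[, 1]] + stats::runif(n_abs, -0.5, 0.5) * mask$cell
  yr <- rep(pres$year, each = ratio)
  rng <- lapply(split(as.numeric(pres$date), pres$year), range)
  adate <- as.Date(vapply(yr, function(y) {
    r <- rng[[y]]
    floor(stats::runif(1, r[1], r[2] + 1))
  }, 0), origin = "1970-01-01")
  rbind(pres, data.frame(lon = alon, lat = alat, date = adate, year = yr,
                         label = 0L))
}

#' Attach environmental covariates to presence/pseudo-absence records
#'
#' Static bathymetry and slope come from the cell containing each point;
#' SST comes from the layer of the record's date (nearest available day).
#' Distance to the colony (km) is computed as a candidate covariate.
#' Records falling on land or no-data cells are dropped; the count of
#' dropped records is reported via a message and the `dropped` attribute.
#'
#' @param records data.frame with `lon`, `lat`, `date`.
#' @param env an `env_stack`.
#' @return `records` with `bathy`, `slope`, `sst`, `dist_km` columns added;
#'   attribute `dropped` holds the number of removed records.
#' @export
extract_covariates <- function(records, env) {
  records$bathy <- gr_extract(env$bathy, records$lon, records$lat)
  records$slope <- gr_extract(env$slope, records$lon, records$lat)
  di <- findInterval(as.numeric(as.Date(records$date)),
                     as.numeric(env$dates), all.inside = TRUE)
  # nearest day: findInterval gives the layer at/before; check the next one
  nxt <- pmin(di + 1L, length(env$dates))
  use_next <- abs(as.numeric(env$dates)[nxt] - as.numeric(as.Date(records$date))) <
    abs(as.numeric(env$dates)[di] - as.numeric(as.Date(records$date)))
  di[use_next] <- nxt[use_next]
  records$sst <- vapply(seq_len(nrow(records)), function(i)
    gr_extract(env$sst[[di[i]]], records$lon[i], records$lat[i]), 0)
  records$dist_km <- geosphere::distHaversine(
    c(env$colony[["lon"]], env$colony[["lat"]]),
    cbind(records$lon, records$lat)) / 1000
  keep <- !is.na(records$bathy) & !is.na(records$slope) & !is.na(records$sst)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " record(s) on land/no-data cells dropped")
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# formula for a term set; terms from {dist, bathy, slope, sst, lonlat}
.hsm_formula <- function(terms, year_fixed, k_1d, k_2d) {
  sm <- c(dist = sprintf("s(dist_km, k = %d, bs = 'tp')", k_1d),
          bathy = sprintf("s(bathy, k = %d, bs = 'tp')", k_1d),
          slope = sprintf("s(slope, k = %d, bs = 'tp')", k_1d),
          sst = sprintf("s(sst, k = %d, bs = 'tp')", k_1d),
          lonlat = sprintf("s(lon, lat, k = %d, bs = 'tp')", k_2d))
  bad <- setdiff(terms, names(sm))
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  rhs <- c(sm[terms], if (year_fixed) "year")
  if (length(rhs) == 0L) rhs <- "1"
  stats::as.formula(paste("label ~", paste(rhs, collapse = " + ")))
}

#' Pairwise concurvity screen for candidate smooth terms
#'
#' Fits the additive model containing every candidate smooth and measures
#' pairwise concurvity between smooths (how well one smooth's fitted basis
#' is reproduced from the span of another's). Terms are screened in the
#' given order — distance-to-colony, a derived covariate, is evaluated
#' first by default — and a term is dropped when its worst pairwise
#' concurvity with a surviving term exceeds `threshold`.
#'
#' @param records covariate-extracted presence/pseudo-absence data.frame.
#' @param terms candidate term names, subset of `dist`, `bathy`, `slope`,
#'   `sst`, `lonlat` (default all, `dist` first).
#' @param threshold concurvity threshold (default 0.9).
#' @param k_1d,k_2d basis sizes for 1-D smooths and the lon/lat surface.
#' @return character vector of retained terms; attributes `dropped` (named
#'   numeric of offending concurvities) and `pairwise` (the full matrix).
#' @export
concurvity_screen <- function(records,
                              terms = c("dist", "bathy", "slope", "sst", "lonlat"),
                              threshold = 0.9, k_1d = 10, k_2d = 25) {
  if (length(terms) < 2L) stop("need at least 2 candidate terms")
  f <- .hsm_formula(terms, year_fixed = FALSE, k_1d = k_1d, k_2d = k_2d)
  fit <- mgcv::gam(f, family = stats::binomial(), data = records,
                   method = "GCV.Cp")
  cc <- mgcv::concurvity(fit, full = FALSE)$estimate
  labels <- rownames(cc)
  smooth_of <- c(dist = "s(dist_km)", bathy = "s(bathy)", slope = "s(slope)",
                 sst = "s(sst)", lonlat = "s(lon,lat)")
  keep <- terms
  dropped <- numeric()
  for (tm in terms) {                       # screen in the given order
    if (!(tm %in% keep)) next
    lab <- smooth_of[[tm]]
    others <- smooth_of[setdiff(keep, tm)]
    worst <- max(cc[lab, others], cc[others, lab])
    if (worst > threshold) {
      keep <- setdiff(keep, tm)
      dropped[tm] <- worst
      if (length(keep) < 2L) break
    }
  }
  structure(keep, dropped = dropped, pairwise = cc)
}

#' Fit a presence/pseudo-absence additive habitat model
#'
#' Penalized additive logistic regression of presence (1) versus
#' pseudo-absence (0): thin-plate regression spline smooths for the 1-D
#' covariates, a two-dimensional thin-plate smooth for longitude/latitude,
#' and year as a categorical fixed effect. Smoothing parameters are chosen
#' by the GCV/UBRE criterion (mgcv's `"GCV.Cp"`). Reports the effective
#' degrees of freedom, small-sample AIC (AICc), deviance explained and
#' adjusted R-squared.
#'
#' @param records covariate-extracted data.frame with `label` and `year`.
#' @param terms smooth terms to include, subset of `dist`, `bathy`,
#'   `slope`, `sst`, `lonlat`.
#' @param year_fixed include year as a fixed factor term (default TRUE).
#' @param k_1d basis size per 1-D smooth (default 10).
#' @param k_2d basis size of the lon/lat surface smooth (default 25).
#' @param method mgcv smoothness-selection criterion (default `"GCV.Cp"`).
#' @return object of class `hsm`: the mgcv fit plus `terms`, `edf`
#'   (effective df used by AICc), `aicc`, `deviance_explained`, `adj_r2`,
#'   `train_range` (per-covariate ranges used to clamp predictions),
#'   `years`, `n`.
#' @export
hsm_fit <- function(records, terms = c("bathy", "slope", "sst", "lonlat"),
                    year_fixed = TRUE, k_1d = 10, k_2d = 25,
                    method = "GCV.Cp") {
  if (!all(c(0, 1) %in% records$label))
    stop("need both presence (1) and pseudo-absence (0) labels")
  records$year <- factor(as.character(records$year))
  if (year_fixed && nlevels(records$year) < 2L) year_fixed <- FALSE
  f <- .hsm_formula(terms, year_fixed, k_1d, k_2d)
  n <- nrow(records)
  fit <- mgcv::gam(f, family = stats::binomial(), data = records,
                   method = method)
  ll <- stats::logLik(fit)
  k <- as.numeric(attr(ll, "df"))            # effective df (edf + parametric)
  aicc <- -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  dev_expl <- 1 - fit$deviance / fit$null.deviance
  vars <- intersect(c("dist_km", "bathy", "slope", "sst", "lon", "lat"),
                    all.vars(f))
  tr <- lapply(records[vars], range)
  structure(list(gam = fit, terms = terms, year_fixed = year_fixed,
                 edf = k, aicc = aicc, deviance_explained = dev_expl,
                 adj_r2 = summary(fit)$r.sq, train_range = tr,
                 years = levels(records$year), n = n,
                 formula = f),
            class = "hsm")
}

#' @export
print.hsm <- function(x, ...) {
  cat("Habitat suitability model (binomial additive logistic regression)\n")
  cat("  terms:", paste(x$terms, collapse = ", "),
      if (x$year_fixed) "+ year (fixed)", "\n")
  cat(sprintf("  n = %d, effective df = %.1f, AICc = %.2f\n",
              x$n, x$edf, x$aicc))
  cat(sprintf("  deviance explained = %.1f%%, adjusted R^2 = %.2f\n",
              100 * x$deviance_explained, x$adj_r2))
  invisible(x)
}

#' @export
summary.hsm <- function(object, ...) summary(object$gam, ...)

#' @export
coef.hsm <- function(object, ...) stats::coef(object$gam)

#' @export
plot.hsm <- function(x, ...) {
  graphics::plot(x$gam, pages = 1, ...)
  invisible(x)
}

#' @export
residuals.hsm <- function(object, ...) stats::residuals(object$gam, ...)

#' Predict habitat suitability from a fitted model
#'
#' Evaluates the inverse-logit linear predictor on new data. Covariates are
#' clamped to their training ranges (spline extrapolation guard; the number
#' of clamped values is reported via the `clamped` attribute). The year
#' fixed effect is either a specific level or — for pooled prediction —
#' the mean of the year effects on the link scale.
#'
#' @param object an `hsm` fit.
#' @param newdata data.frame with the model's covariates.
#' @param year `"mean"` (default) or one of the training year levels.
#' @param type `"response"` (probability, default) or `"link"`.
#' @param ... unused.
#' @return numeric vector of predictions; attribute `clamped` counts
#'   covariate values moved to a range endpoint.
#' @export
predict.hsm <- function(object, newdata, year = "mean",
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  clamped <- 0L
  for (v in names(object$train_range)) {
    if (!v %in% names(newdata)) stop("newdata lacks covariate ", v)
    r <- object$train_range[[v]]
    out_of <- newdata[[v]] < r[1] | newdata[[v]] > r[2]
    clamped <- clamped + sum(out_of, na.rm = TRUE)
    newdata[[v]] <- pmin(pmax(newdata[[v]], r[1]), r[2])
  }
  if (object$year_fixed) {
    if (identical(year, "mean")) {
      eta <- 0
      for (y in object$years) {
        newdata$year <- factor(y, levels = object$years)
        eta <- eta + stats::predict(object$gam, newdata, type = "link")
      }
      eta <- eta / length(object$years)
    } else {
      if (!year %in% object$years) stop("unknown year level: ", year)
      newdata$year <- factor(year, levels = object$years)
      eta <- stats::predict(object$gam, newdata, type = "link")
    }
  } else {
    eta <- stats::predict(object$gam, newdata, type = "link")
  }
  out <- if (type == "response") stats::plogis(as.numeric(eta))
         else as.numeric(eta)
  attr(out, "clamped") <- clamped
  out
}

#' All-subsets model selection by AICc
#'
#' Fits every subset of the global smooth terms (the year fixed effect is
#' always retained, including in the intercept-only candidate), ranks the
#' candidates by AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1) with k the
#' effective degrees of freedom, and returns the lowest-AICc fit together
#' with the full selection table (term inclusion flags, effective df, AICc,
#' delta AICc, and Akaike weights `w = exp(-delta/2)` normalized over the
#' candidate set).
#'
#' @param records covariate-extracted data.frame with `label` and `year`.
#' @param global_terms smooth terms of the global model.
#' @param include_null include the smooth-free (intercept + year) candidate
#'   (default TRUE).
#' @param ... passed to [hsm_fit()] (`k_1d`, `k_2d`, `method`, ...).
#' @return object of class `hsm_selection`: `best` (an `hsm`), `table`
#'   (data.frame sorted by AICc), `global_terms`.
#' @export
select_model <- function(records,
                         global_terms = c("bathy", "slope", "sst", "lonlat"),
                         include_null = TRUE, ...) {
  stopifnot(length(global_terms) >= 1L)
  subsets <- list()
  for (sz in seq(length(global_terms), 0)) {
    if (sz == 0 && !include_null) next
    cmb <- utils::combn(global_terms, sz, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  fits <- lapply(subsets, function(tm)
    hsm_fit(records, terms = tm, year_fixed = TRUE, ...))
  aicc <- vapply(fits, `[[`, 0, "aicc")
  flags <- do.call(rbind, lapply(subsets, function(tm)
    as.integer(global_terms %in% tm)))
  colnames(flags) <- global_terms
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- data.frame(flags, year = 1L,
                    df = vapply(fits, `[[`, 0, "edf"),
                    AICc = aicc, delta = delta, weight = w)
  o <- order(aicc)
  tab <- tab[o, , drop = FALSE]; rownames(tab) <- NULL
  structure(list(best = fits[[o[1]]], table = tab,
                 global_terms = global_terms),
            class = "hsm_selection")
}

#' @export
print.hsm_selection <- function(x, digits = 2, n = 10, ...) {
  cat("AICc all-subsets selection (year fixed term always retained)\n\n")
  tb <- utils::head(x$table, n)
  tb$df <- round(tb$df, 1)
  tb$AICc <- round(tb$AICc, digits); tb$delta <- round(tb$delta, digits)
  tb$weight <- round(tb$weight, digits)
  print(tb)
  cat("\nBest model:\n")
  print(x$best)
  invisible(x)
}

#' Daily habitat-suitability prediction over the domain
#'
#' For each requested date, evaluates the fitted model at every domain cell
#' centre (static bathymetry and slope, that day's SST layer, lon/lat), and
#' returns one probability raster per day.
#'
#' @param fit an `hsm` (or `hsm_selection`, whose best fit is used).
#' @param env an `env_stack` covering the dates.
#' @param domain an `hsm_domain`.
#' @param dates Date vector (default: all days in `env`).
#' @param year passed to [predict.hsm()] (default `"mean"`, pooled).
#' @return object of class `hsi_maps`: `daily` (named list of
#'   `grid_raster`, values in `[0, 1]`, NA outside the domain), `dates`.
#' @export
predict_daily <- function(fit, env, domain, dates = env$dates,
                          year = "mean") {
  if (inherits(fit, "hsm_selection")) fit <- fit$best
  stopifnot(inherits(fit, "hsm"), inherits(domain, "hsm_domain"))
  dates <- as.Date(dates)
  if (any(dates < min(env$dates) | dates > max(env$dates)))
    stop("requested dates outside the environmental coverage")
  mask <- domain$mask$values == 1
  idx <- which(mask)
  rc <- arrayInd(idx, dim(mask))
  lonc <- gr_xcoords(env$bathy); latc <- gr_ycoords(env$bathy)
  base <- data.frame(lon = lonc[rc[, 2]], lat = latc[rc[, 1]],
                     bathy = env$bathy$values[idx],
                     slope = env$slope$values[idx])
  base$dist_km <- geosphere::distHaversine(
    c(env$colony[["lon"]], env$colony[["lat"]]),
    cbind(base$lon, base$lat)) / 1000
  daily <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    di <- which.min(abs(as.numeric(env$dates) - as.numeric(dates[i])))
    nd <- base
    nd$sst <- env$sst[[di]]$values[idx]
    p <- predict(fit, nd, year = year, type = "response")
    v <- matrix(NA_real_, nrow(mask), ncol(mask))
    v[idx] <- as.numeric(p)
    daily[[i]] <- grid_raster(v, env$bathy$xmin, env$bathy$ymin,
                              env$bathy$cell)
  }
  names(daily) <- as.character(dates)
  structure(list(daily = daily, dates = dates), class = "hsi_maps")
}

#' Mean and standard deviation of daily habitat-suitability maps
#'
#' Per-cell arithmetic mean and population standard deviation over days.
#'
#' @param maps an `hsi_maps` object (or a list of `grid_raster`).
#' @return list with `mean` and `sd` `grid_raster`s.
#' @export
summarize_hsi <- function(maps) {
  daily <- if (inherits(maps, "hsi_maps")) maps$daily else maps
  stopifnot(length(daily) >= 1L)
  a <- daily[[1]]
  n <- length(daily)
  s1 <- 0
  for (d in daily) s1 <- s1 + d$values
  mu <- s1 / n
  ss <- 0                                  # two-pass population variance
  lo <- daily[[1]]$values; hi <- lo
  for (d in daily) {
    ss <- ss + (d$values - mu)^2
    lo <- pmin(lo, d$values); hi <- pmax(hi, d$values)
  }
  sd <- sqrt(ss / n)
  sd[which(hi == lo)] <- 0                 # exact zero when dailies agree
  list(mean = grid_raster(mu, a$xmin, a$ymin, a$cell),
       sd = grid_raster(sd, a$xmin, a$ymin, a$cell))
}
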