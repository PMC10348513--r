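make_domain <- function(cells, nx = 4, ny = 3, xmin = -55, ymin = 46,
                        cell = 0.1) {
  m <- matrix(0, ny, nx)
  m[cells] <- 1
  structure(list(mask = grid_raster(m, xmin, ymin, cell),
                 radius_km = Inf, colony = c(lon = xmin, lat = ymin)),
            class = "hsm_domain")
}

test_that("domain radius is the scaled maximum colony-to-dive distance", {
  s <- small_sim()
  colony <- s$cfg$colony
  p410 <- geosphere::destPoint(colony, 90, 410000, r = 6378137)
  dom <- build_domain(colony, c(colony[["lon"]], p410[1]),
                      c(colony[["lat"]], p410[2]), s$env, scale = 1.1)
  expect_equal(dom$radius_km, 451, tolerance = 1e-6)

  near <- build_domain(colony, colony[["lon"]], colony[["lat"]] - 0.02, s$env)
  expect_lt(sum(near$mask$values), 30)
  expect_gt(sum(near$mask$values), 0)
  expect_error(build_domain(colony, NA_real_, NA_real_, s$env), "at least one")
})

test_that("pseudo-absence sampling is exact-ratio, in-domain and seeded", {
  s <- small_sim()
  ev <- process_dives(s$sim$traces, s$sim$fixes, cutoff = NULL)
  dom <- build_domain(s$cfg$colony, ev$lon, ev$lat, s$env)
  pres <- data.frame(lon = ev$lon[1:10], lat = ev$lat[1:10],
                     date = ev$date[1:10], year = ev$year[1:10])
  rec <- sample_pseudo_absences(pres, dom, ratio = 3, seed = 5)
  expect_equal(sum(rec$label == 0), 30L)
  expect_equal(sum(rec$label == 1), 10L)
  ab <- rec[rec$label == 0, ]
  expect_true(all(gr_extract(dom$mask, ab$lon, ab$lat) == 1))
  expect_true(all(ab$date >= min(pres$date) & ab$date <= max(pres$date)))
  rec2 <- sample_pseudo_absences(pres, dom, ratio = 3, seed = 5)
  expect_identical(rec, rec2)
  expect_equal(nrow(sample_pseudo_absences(pres, dom, ratio = 0, seed = 1)),
               10L)
})

test_that("uniform sampling over a two-cell domain is binomially balanced", {
  dom <- make_domain(c(2, 7))
  pres <- data.frame(lon = rep(-54.95, 2500), lat = rep(46.05, 2500),
                     date = as.Date("2019-08-01"), year = "2019")
  rec <- sample_pseudo_absences(pres, dom, ratio = 4, seed = 2)
  ab <- rec[rec$label == 0, ]
  expect_equal(nrow(ab), 10000L)
  rc <- gr_cell_of(dom$mask, ab$lon, ab$lat)
  counts <- table((rc[, "col"] - 1) * 3 + rc[, "row"])
  expect_equal(length(counts), 2L)
  expect_true(all(abs(counts - 5000) <= 3 * sqrt(2500)))
})

test_that("covariate extraction looks up the right cell and date, drops no-data", {
  s <- small_sim()
  env <- s$env
  sea_rc <- which(env$sea$values == 1, arr.ind = TRUE)[1, ]
  lon <- gr_xcoords(env$bathy)[sea_rc[2]]
  lat <- gr_ycoords(env$bathy)[sea_rc[1]]
  rec <- data.frame(lon = lon, lat = lat,
                    date = env$dates[c(1, 10)], label = 1L, year = "2019")
  out <- extract_covariates(rec, env)
  expect_equal(out$bathy, rep(env$bathy$values[sea_rc[1], sea_rc[2]], 2))
  expect_equal(out$sst[1], env$sst[[1]]$values[sea_rc[1], sea_rc[2]])
  expect_equal(out$sst[2], env$sst[[10]]$values[sea_rc[1], sea_rc[2]])
  expect_false(out$sst[1] == out$sst[2])
  # a point on land is dropped and counted
  land_lat <- max(gr_ycoords(env$bathy))
  rec2 <- rbind(rec, data.frame(lon = lon, lat = land_lat,
                                date = env$dates[1], label = 1L,
                                year = "2019"))
  expect_message(out2 <- extract_covariates(rec2, env), "dropped")
  expect_equal(nrow(out2), 2L)
  expect_equal(attr(out2, "dropped"), 1L)
})

test_that("concurvity screen flags duplicates and derived covariates only", {
  rec <- random_records(1000, seed = 21)
  keep <- concurvity_screen(rec)
  expect_false("dist" %in% keep)                 # function of lon/lat
  expect_gt(attr(keep, "dropped")[["dist"]], 0.9)
  expect_setequal(keep, c("bathy", "slope", "sst", "lonlat"))
  pw <- attr(keep, "pairwise")
  sm <- c("s(bathy)", "s(slope)", "s(sst)")
  off <- pw[sm, sm]; diag(off) <- 0
  expect_lt(max(off), 0.2)                       # independent uniforms
  # a duplicated covariate is perfectly concurve
  rec$slope <- rec$bathy
  keep2 <- concurvity_screen(rec, terms = c("bathy", "slope", "sst"))
  expect_false("bathy" %in% keep2 && "slope" %in% keep2)
  expect_gt(max(attr(keep2, "dropped")), 0.99)
  expect_error(concurvity_screen(rec, terms = "sst"), "2 candidate")
})

test_that("fit on label-independent covariates explains almost no deviance", {
  rec <- random_records(2000, seed = 31)
  fit <- hsm_fit(rec, terms = c("bathy", "slope", "sst"))
  expect_lt(fit$deviance_explained, 0.05)
  expect_gte(fit$deviance_explained, 0)
})

test_that("single-covariate logistic truth is recovered with matching sign", {
  gen_p <- function(df) plogis(-1.5 * scale(df$sst)[, 1])
  rec <- random_records(2000, seed = 32, p = gen_p)
  fit <- hsm_fit(rec, terms = "sst")
  nd <- data.frame(sst = seq(quantile(rec$sst, 0.05),
                             quantile(rec$sst, 0.95), length.out = 25),
                   bathy = 0, slope = 0, lon = 0, lat = 0, dist_km = 0)
  pr <- predict(fit, nd[, "sst", drop = FALSE], type = "link")
  expect_lt(cor(nd$sst, pr, method = "spearman"), -0.95)  # monotone decreasing
  # deviance explained close to the generating model's
  eta <- -1.5 * scale(rec$sst)[, 1]
  mu <- plogis(eta)
  dev_gen <- -2 * sum(rec$label * log(mu) + (1 - rec$label) * log(1 - mu))
  p0 <- mean(rec$label)
  dev_null <- -2 * sum(rec$label * log(p0) + (1 - rec$label) * log(1 - p0))
  expect_lt(abs(fit$deviance_explained - (1 - dev_gen / dev_null)), 0.1)
})

test_that("degenerate fits are rejected; smooth-free model explains nothing", {
  rec <- random_records(300, seed = 33)
  rec$label <- 1L
  expect_error(hsm_fit(rec, terms = "sst"), "both presence")
  rec2 <- random_records(400, seed = 34)
  fit0 <- hsm_fit(rec2, terms = character(0))
  expect_equal(fit0$deviance_explained, 0, tolerance = 1e-8)
})

test_that("AICc selection table is coherent and the best model beats the global", {
  gen_p <- function(df) plogis(1.2 * scale(df$bathy)[, 1] -
                               1.2 * scale(df$sst)[, 1])
  rec <- random_records(1200, seed = 35, p = gen_p)
  selection <- select_model(rec, global_terms = c("bathy", "slope", "sst"))
  tab <- selection$table
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(tab$AICc))
  expect_equal(tab$delta, tab$AICc - tab$AICc[1])
  global_row <- tab[tab$bathy == 1 & tab$slope == 1 & tab$sst == 1, ]
  expect_lte(selection$best$aicc, global_row$AICc)
  expect_true(all(c("bathy", "sst") %in% selection$best$terms))
  # weight ratio between two candidates follows exp(-delta/2)
  expect_equal(tab$weight[1] / tab$weight[2],
               exp((tab$AICc[2] - tab$AICc[1]) / 2), tolerance = 1e-9)
})

test_that("predictions stay in [0,1], clamp extrapolations, and are deterministic", {
  rec <- random_records(800, seed = 36,
                        p = function(df) plogis(scale(df$bathy)[, 1]))
  fit <- hsm_fit(rec, terms = c("bathy", "sst"))
  nd <- data.frame(bathy = c(-1000, 250, 5000), sst = c(14, 14, 14))
  pr <- predict(fit, nd)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(attr(pr, "clamped"), 2L)
  # clamped endpoints equal predictions at the range limits
  ndr <- data.frame(bathy = range(rec$bathy), sst = c(14, 14))
  prr <- predict(fit, ndr)
  expect_equal(pr[c(1, 3)], prr[c(1, 2)], tolerance = 1e-12)
  expect_identical(as.numeric(predict(fit, nd)), as.numeric(pr))
})

test_that("daily habitat prediction responds to SST and pools years on request", {
  s <- small_sim()
  ev <- process_dives(s$sim$traces, s$sim$fixes, cutoff = NULL)
  dom <- build_domain(s$cfg$colony, ev$lon, ev$lat, s$env)
  pres <- data.frame(lon = ev$lon, lat = ev$lat, date = ev$date,
                     year = ev$year)
  rec <- extract_covariates(sample_pseudo_absences(pres, dom, seed = 8),
                            s$env)
  fit <- hsm_fit(rec, terms = "sst")
  maps <- predict_daily(fit, s$env, dom, dates = s$env$dates[c(1, 5)])
  v1 <- maps$daily[[1]]$values
  inside <- dom$mask$values == 1
  expect_true(all(v1[inside] >= 0 & v1[inside] <= 1))
  expect_true(all(is.na(v1[!inside])))
  # same date twice -> identical maps
  maps2 <- predict_daily(fit, s$env, dom, dates = s$env$dates[c(1, 1)])
  expect_identical(maps2$daily[[1]]$values, maps2$daily[[2]]$values)
  expect_error(predict_daily(fit, s$env, dom,
                             dates = max(s$env$dates) + 5), "coverage")
})

test_that("HSI summaries use the population SD and are bounded by the dailies", {
  r <- function(v) grid_raster(matrix(v, 2, 2), 0, 0, 1)
  out <- summarize_hsi(list(r(0.2), r(0.4)))
  expect_equal(out$mean$values, matrix(0.3, 2, 2))
  expect_equal(out$sd$values, matrix(0.1, 2, 2))
  same <- summarize_hsi(list(r(0.7), r(0.7), r(0.7)))
  expect_true(all(same$sd$values == 0))
  set.seed(2)
  dailies <- lapply(1:4, function(i) r(runif(4)))
  s <- summarize_hsi(dailies)
  lo <- Reduce(pmin, lapply(dailies, `[[`, "values"))
  hi <- Reduce(pmax, lapply(dailies, `[[`, "values"))
  expect_true(all(s$mean$values >= lo & s$mean$values <= hi))
})
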