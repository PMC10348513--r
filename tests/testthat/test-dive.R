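test_that("dive detection finds maximal submerged runs", {
  segs <- detect_dives(0:6, c(0, 0, 5, 10, 10, 5, 0), 0.5)
  expect_length(segs, 1L)
  expect_equal(length(segs[[1]]$depth_m), 4L)
  expect_equal(segs[[1]]$depth_m, c(5, 10, 10, 5))

  expect_length(detect_dives(0:9, rep(0, 10), 0.5), 0L)
  expect_length(detect_dives(numeric(0), numeric(0)), 0L)

  # two excursions separated by surface samples; brute-force run count oracle
  d <- c(0, 3, 4, 0, 0, 0, 2, 5, 2, 0)
  runs <- sum(diff(c(FALSE, d > 0.5)) == 1)
  segs2 <- detect_dives(seq_along(d), d, 0.5)
  expect_length(segs2, runs)
  expect_equal(runs, 2L)
})

test_that("non-monotone timestamps are rejected", {
  expect_error(detect_dives(c(1, 2, 2, 3), c(0, 1, 1, 0)), "increasing")
  expect_error(detect_dives(c(1, 3, 2), c(0, 1, 0)), "increasing")
})

test_that("dive metrics follow the 80%-of-max bottom-phase definition", {
  seg <- function(d) list(timestamp = seq_along(d), depth_m = d)
  m <- compute_metrics(seg(c(2, 10, 10, 10, 2)))
  expect_equal(unname(m), c(10, 5, 3))     # threshold 8 m -> 3 bottom samples

  m2 <- compute_metrics(seg(rep(6, 7)))    # constant depth: all bottom
  expect_equal(m2[["bottom_time"]], m2[["duration"]])
  expect_equal(m2[["duration"]], 7)

  m3 <- compute_metrics(seg(c(1, 7, 1)))   # spike: 0.8*7 = 5.6, one sample
  expect_equal(m3[["max_depth"]], 7)
  expect_equal(m3[["bottom_time"]], 1)
})

test_that("U/V classification rule and its boundary behave as documented", {
  expect_equal(classify_dive(15, 20, 5), "U")     # both clauses hold
  expect_equal(classify_dive(3, 4, 1), "V")       # neither clause holds
  expect_equal(classify_dive(8, 10, 2.99), "V")   # all three strict conditions fail
  expect_equal(classify_dive(5, 4, 3), "U")       # bottom time alone suffices
  expect_equal(classify_dive(9, 11, 1), "U")      # deep + long alone suffices
  expect_equal(classify_dive(9, 11, 1, rule = "strict_and"), "V")
  expect_equal(classify_dive(9, 11, 3, rule = "strict_and"), "U")
})

test_that("minimum-depth filter keeps the 1 m boundary and is idempotent", {
  ev <- data.frame(max_depth = c(0.5, 1.0, 9))
  f1 <- filter_dives(ev)
  expect_equal(f1$max_depth, c(1.0, 9))
  expect_identical(filter_dives(f1), f1)
  expect_equal(nrow(filter_dives(data.frame(max_depth = c(0.2, 0.9)))), 0L)
  all_deep <- data.frame(max_depth = c(2, 3))
  expect_identical(filter_dives(all_deep), all_deep)
})

test_that("foraging-location association uses the latest fix within 30 min before", {
  t0 <- as.POSIXct("2019-08-01 10:00:00", tz = "UTC")
  fixes <- data.frame(bird_id = "b1",
                      timestamp = t0 + c(0, 60, 4000),
                      lon = c(1, 2, 3), lat = c(10, 20, 30))
  ev <- data.frame(bird_id = "b1", start = t0 + 20 * 60)
  out <- assign_foraging_locations(ev, fixes)
  expect_equal(out$lon[1], 2)        # latest of the two qualifying fixes
  # dive 31 min after the last prior fix: outside the window
  ev2 <- data.frame(bird_id = "b1", start = t0 + 60 + 1860)
  expect_true(is.na(assign_foraging_locations(ev2, fixes)$lon))
  # fix 1 s after the dive start does not qualify
  ev3 <- data.frame(bird_id = "b1", start = t0 - 1)
  expect_true(is.na(assign_foraging_locations(ev3, fixes)$lon))
})

test_that("auto cutoff matches an exhaustive split-scan oracle", {
  mk <- function(props, year = "2019") {
    dates <- as.Date(paste0(year, "-07-01")) + seq_along(props) - 1
    do.call(rbind, lapply(seq_along(props), function(i) {
      nU <- round(20 * props[i])
      data.frame(date = dates[i], shape = c(rep("U", nU), rep("V", 20 - nU)))
    }))
  }
  # step drop: 0.4 for days 1-20, 0.02 (approx as 0.05 on 20 dives) after
  ev <- mk(c(rep(0.4, 20), rep(0.05, 20)))
  cut <- detect_cutoff(ev, cutoff_rule("auto"))
  expect_equal(cut[["2019"]], as.Date("2019-07-21"))

  # independent oracle on an arbitrary profile
  set.seed(8)
  props <- round(runif(30), 2)
  ev2 <- mk(props)
  days <- sort(unique(ev2$date))
  prop <- sapply(days, function(d) mean(ev2$shape[ev2$date == d] == "U"))
  contr <- sapply(2:length(days), function(k)
    mean(prop[1:(k - 1)]) - mean(prop[k:length(prop)]))
  expect_equal(detect_cutoff(ev2, cutoff_rule("auto"))[["2019"]],
               days[1 + which.max(contr)])
})

test_that("fixed-date cutoff echoes configuration; degenerate cases handled", {
  ev <- data.frame(date = as.Date("2019-08-01") + 0:9,
                   shape = rep(c("U", "V"), 5))
  rule <- cutoff_rule("fixed_date", fixed_dates = c("2019" = "2019-08-16"))
  expect_equal(detect_cutoff(ev, rule)[["2019"]], as.Date("2019-08-16"))
  # constant proportions: warning + midpoint
  ev2 <- do.call(rbind, lapply(0:13, function(i)
    data.frame(date = as.Date("2019-08-01") + i, shape = c("U", "V"))))
  expect_warning(cut <- detect_cutoff(ev2, cutoff_rule("auto")), "constant")
  expect_equal(cut[["2019"]], as.Date("2019-08-01") + 6)
  expect_error(detect_cutoff(ev[1:4, ], cutoff_rule("auto")), "7 days")
})

test_that("phase labels split at the cutoff with the boundary day late", {
  ev <- data.frame(date = as.Date("2019-08-14") + 0:4)
  out <- phase_labels(ev, list("2019" = as.Date("2019-08-16")))
  expect_equal(out$phase, c("early", "early", "late", "late", "late"))
  # all-before and direct-comparison oracle
  set.seed(2)
  dts <- as.Date("2020-07-01") + sample(0:60, 40, replace = TRUE)
  out2 <- phase_labels(data.frame(date = dts),
                       list("2020" = as.Date("2020-08-10")))
  expect_identical(out2$phase,
                   ifelse(dts < as.Date("2020-08-10"), "early", "late"))
})

test_that("daily summary proportions sum to one and days without dives are absent", {
  ev <- data.frame(date = as.Date(c("2019-08-01", "2019-08-01", "2019-08-01",
                                    "2019-08-01", "2019-08-03")),
                   shape = c("U", "U", "U", "V", "U"))
  s <- daily_summary(ev)
  expect_equal(nrow(s), 2L)
  expect_equal(s$prop_U, c(0.75, 1))
  expect_equal(s$prop_U + s$prop_V, c(1, 1))
  expect_equal(s$n_dives, c(4L, 1L))
  expect_false(as.Date("2019-08-02") %in% s$date)
})

test_that("processing is invariant to input row order and conserves counts", {
  s <- small_sim()
  ev <- process_dives(s$sim$traces, s$sim$fixes, cutoff = NULL)
  set.seed(1)
  shuf_t <- s$sim$traces[sample(nrow(s$sim$traces)), ]
  shuf_f <- s$sim$fixes[sample(nrow(s$sim$fixes)), ]
  ev2 <- process_dives(shuf_t, shuf_f, cutoff = NULL)
  rownames(ev) <- rownames(ev2) <- NULL
  expect_equal(ev, ev2)
  expect_equal(sum(ev$shape == "U") + sum(ev$shape == "V"), nrow(ev))
})
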