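# shared small simulation fixture, built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_birds = 2, date_range = c("2019-07-15", "2019-07-28"),
                        seed = 42)
      env <- gen_environment(cfg)
      cache <<- list(cfg = cfg, env = env,
                     sim = gen_tracks_and_dives(cfg, env))
    }
    cache
  }
})

# synthetic presence/pseudo-absence records with independent covariates
random_records <- function(n, seed = 1, p = function(df) rep(0.25, nrow(df))) {
  set.seed(seed)
  df <- data.frame(lon = runif(n, -56, -53), lat = runif(n, 45.5, 46.8),
                   bathy = runif(n, 10, 500), slope = runif(n, 0, 10),
                   sst = runif(n, 10, 18), year = "2019")
  df$dist_km <- geosphere::distHaversine(c(-54.18, 46.81),
                                         cbind(df$lon, df$lat)) / 1000
  df$label <- rbinom(n, 1, p(df))
  df
}
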