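# Shared test fixtures: packaged protocol runs are expensive enough to be
# worth computing once and reusing across test files.

.cvr_cache <- new.env(parent = emptyenv())

cached_protocol <- function(condition) {
  key <- paste0("proto_", condition)
  if (is.null(.cvr_cache[[key]])) {
    cfg <- load_config(scenario_fixture(condition))
    .cvr_cache[[key]] <- run_protocol(cfg, keep_results = TRUE)
  }
  .cvr_cache[[key]]
}

# a short resting simulation of the heart-failure scenario
cached_rest_run <- function(duration = 60) {
  key <- sprintf("rest_%g", duration)
  if (is.null(.cvr_cache[[key]])) {
    cfg <- scenario_config("hf")
    .cvr_cache[[key]] <- cvr_simulate(cfg, duration = duration)
  }
  .cvr_cache[[key]]
}

# synthetic cvr_result with prescribed constant channels, for summary tests
synthetic_result <- function(n_cycles = 20, hr = 60, dt = 0.01,
                             channels = list()) {
  rr <- 60 / hr
  t <- seq(0, n_cycles * rr, by = dt)
  cols <- c("time", cvr_state_names(), cvr_derived_names())
  m <- matrix(0, nrow = length(t), ncol = length(cols),
              dimnames = list(NULL, cols))
  m[, "time"] <- t
  m[, "cycle"] <- floor(t / rr)
  m[, "HR"] <- hr
  for (nm in names(channels)) {
    v <- channels[[nm]]
    m[, nm] <- if (is.function(v)) v(t) else v
  }
  structure(list(timeseries = m, final_state = m[nrow(m), 2:45],
                 final_time = max(t), params = list(),
                 n_suction = 0, n_o2_clamp = 0),
            class = "cvr_result")
}
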