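# Shared simulated datasets for the heavier validation tests, built lazily
# and cached for the session so several test files can reuse them.

.acc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache))
    assign(key, force(expr), envir = .acc_cache)
  get(key, envir = .acc_cache)
}

# the three-state nsALEX validation dataset (seed 1) and its stream views
acc_3state_dataset <- function() cached("three_state_ds", {
  ds <- make_dataset(scenario_3state_dark_acceptor(n_bursts = 500L, seed = 1L))
  ds$mp <- as_obs_set(ds$series, ds$bursts)
  ds$sp <- as_obs_set(ds$series, ds$bursts, streams = 0:1)
  ds
})

# the 20-seed three-state recovery study (ICL scan per seed)
acc_recovery_study <- function() cached("recovery", {
  seeds <- 1:20
  res <- lapply(seeds, function(s) {
    ds <- if (s == 1L) acc_3state_dataset()
          else make_dataset(scenario_3state_dark_acceptor(n_bursts = 500L,
                                                    seed = s))
    data <- if (s == 1L) ds$mp else as_obs_set(ds$series, ds$bursts)
    scan <- h2mm_scan(data, q_max = 6, max_iter = 300,
                      init_strategy = "warm", seed = 1L)
    out <- list(seed = s, selected_q = scan$selected_q)
    if (scan$selected_q == 3) {
      al <- align_states(scan_fit(scan)$model, ds$truth$model)
      out$E_err <- al$E_err
      out$S_err <- al$S_err
      out$rate_rel_err <- al$rate_rel_err
    }
    out
  })
  res
})

# the usALEX two-state dataset: raw (artifact) and shifted views
acc_usalex_dataset <- function() cached("usalex", {
  sc <- scenario_usalex_2state(n_bursts = 300L, seed = 7L)
  ds <- make_dataset(sc)
  ds$scenario <- sc
  ds$raw_obs <- as_obs_set(ds$series, ds$bursts)
  shifted <- shift_acceptor_photons(ds$series, sc$scheme)
  ds$shifted_series <- shifted
  ds$shifted_bursts <- bursts_from_ticks(shifted,
                                         ds$bursts$start_tick,
                                         ds$bursts$stop_tick)
  ds$shifted_obs <- as_obs_set(shifted, ds$shifted_bursts)
  ds
})
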