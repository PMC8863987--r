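test_that("dwell segmentation splits constant-state runs", {
  path <- c(0L, 0L, 1L, 1L, 1L, 0L)
  d <- one_burst_obs(c(0L, 1L, 1L, 0L, 2L, 0L), c(0, 5, 3, 2, 4, 6), 3)
  dw <- segment_dwells(list(path), d)
  expect_equal(dw$state, c(0L, 1L, 0L))
  expect_equal(dw$n_photons, c(2L, 3L, 1L))
  expect_equal(dw$position, c("initial", "internal", "terminal"))
  # durations are photon-to-photon: ticks 0,5,8,10,14,20
  expect_equal(dw$duration_ticks, c(5, 6, 0))
  expect_equal(dw$n_DD + dw$n_DA + dw$n_AA, dw$n_photons)
  # E/S from each dwell's own counts
  expect_equal(dw$E_raw[1], 1 / 2)

  # constant path -> one whole-burst dwell
  dw2 <- segment_dwells(list(rep(2L, 6)), d)
  expect_equal(nrow(dw2), 1L)
  expect_equal(dw2$position, "whole-burst")

  # strictly alternating path -> T single-photon dwells
  dw3 <- segment_dwells(list(rep(c(0L, 1L), 3)), d)
  expect_equal(nrow(dw3), 6L)
  expect_true(all(dw3$n_photons == 1L))
  expect_true(all(dw3$duration_ticks == 0))
})

test_that("dwell photon counts per state sum to the Viterbi occupancy", {
  ds <- make_dataset(scenario_dynamic_2state(n_bursts = 30L, seed = 22L))
  d <- as_obs_set(ds$series, ds$bursts)
  fit <- h2mm(d, 2, max_iter = 200)
  paths <- predict(fit, d, type = "states")
  dw <- segment_dwells(paths, d)
  occ <- table(factor(unlist(paths), 0:1))
  per_state <- tapply(dw$n_photons, factor(dw$state, 0:1), sum)
  expect_equal(as.integer(per_state), as.integer(occ))
})

test_that("burst classification labels pure and mixed bursts", {
  paths <- list(rep(2L, 5), c(0L, 0L, 1L, 1L), c(1L, 1L, 1L))
  cls <- classify_bursts(paths)
  expect_equal(cls$label,
               c("pure-state-2", "mixed-{0,1}", "pure-state-1"))
  expect_equal(cls$states, c("2", "0+1", "1"))
  # deterministic
  expect_identical(classify_bursts(paths), cls)
})

test_that("weighted dwell statistics follow their definitions", {
  dw <- data.frame(burst_id = 0L, state = 0L,
                   n_photons = c(20, 60), n_DD = c(8, 6), n_DA = c(2, 24),
                   n_AA = c(10, 30),
                   duration_ticks = c(10, 10),
                   E_raw = c(0.2, 0.8), S_raw = c(0.5, 0.5),
                   position = "internal")
  st <- weighted_dwell_stats(dw)
  # E weights are donor-excitation photons: 10 and 30 -> mean 0.65
  expect_equal(st$E_mean, 0.65)
  # equal weights reduce to the unweighted mean
  dw2 <- dw
  dw2$n_DD <- c(5, 5); dw2$n_DA <- c(5, 5); dw2$n_photons <- c(20, 20)
  st2 <- weighted_dwell_stats(dw2)
  expect_equal(st2$E_mean, 0.5)
  expect_equal(st2$E_sd, sqrt(mean((c(0.2, 0.8) - 0.5)^2)))
  # a single dwell has zero spread and zero standard error
  st3 <- weighted_dwell_stats(dw[1, ])
  expect_equal(st3$E_sd, 0)
  expect_equal(st3$E_se, 0)
})

test_that("rate conversion: per-tick probabilities to s^-1", {
  A <- matrix(c(1 - 1e-5, 1e-5, 2e-5, 1 - 2e-5), 2, byrow = TRUE)
  m <- state_model(c(0.5, 0.5), A,
                   matrix(c(0.5, 0.5, 0.3, 0.7), 2, byrow = TRUE))
  k <- rates_per_second(m, 12.5e-9)
  expect_equal(k[1, 2], 800)
  expect_equal(k[2, 1], 1600)
  ident <- state_model(c(0.5, 0.5), diag(2), m$emission)
  expect_true(all(rates_per_second(ident, 1e-8)[upper.tri(diag(2))] == 0))
  fast <- state_model(c(0.5, 0.5),
                      matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE),
                      m$emission)
  expect_warning(rates_per_second(fast, 1e-8), "0.01")
})

test_that("rates survive a simulate-estimate round trip within 20%", {
  sc <- scenario_dynamic_2state(n_bursts = 250L, seed = 23L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  fit <- h2mm(d, 2, max_iter = 300)
  al <- align_states(fit$model, ds$truth$model)
  off <- al$rate_rel_err[!is.na(al$rate_rel_err)]
  expect_true(all(abs(off) < 0.2))
})

test_that("variance of subsets degenerates to zero on duplicated bursts", {
  ds <- make_dataset(scenario_dynamic_2state(n_bursts = 4L, seed = 24L))
  d <- as_obs_set(ds$series, ds$bursts)
  # duplicate one burst into every slot: all subsets carry identical data
  dup <- mph2mm:::obs_subset(d, rep(1L, 8L))
  fit <- h2mm(dup, 2, max_iter = 100)
  vs <- variance_of_subsets(dup, fit, n_subsets = 2, seed = 1,
                            max_iter = 100)
  expect_true(all(vs$E_sd < 1e-6))
  expect_true(all(vs$rate_sd[!is.na(vs$rate_sd)] < 1e-6))
  expect_error(variance_of_subsets(d, fit, n_subsets = 1), "at least 2")
})

test_that("subset variance tracks the spread of independent simulations", {
  # SD across subsets (scaled) should agree with the spread of independent
  # full simulations within a factor of ~2
  fits_E <- sapply(31:34, function(s) {
    ds <- make_dataset(scenario_dynamic_2state(n_bursts = 120L, seed = s))
    d <- as_obs_set(ds$series, ds$bursts)
    f <- h2mm(d, 2, max_iter = 200)
    al <- align_states(f$model, ds$truth$model)
    al$E_err[1]
  })
  ds <- make_dataset(scenario_dynamic_2state(n_bursts = 120L, seed = 30L))
  d <- as_obs_set(ds$series, ds$bursts)
  fit <- h2mm(d, 2, max_iter = 200)
  vs <- variance_of_subsets(d, fit, n_subsets = 4, seed = 1,
                            max_iter = 200)
  # subsets have 1/4 of the data -> scale SD down by 2 for the full size
  sd_subsets <- vs$E_sd[1] / 2
  sd_indep <- sd(fits_E)
  expect_lt(sd_subsets / sd_indep, 5)
  expect_gt(sd_subsets / sd_indep, 1 / 5)
})

test_that("internal dwell durations decay exponentially at the exit rate", {
  sc <- scenario_dynamic_2state(n_bursts = 250L, seed = 25L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  fit <- h2mm(d, 2, max_iter = 300)
  dw <- segment_dwells(predict(fit, d, type = "states"), d)
  internal <- dw[dw$position == "internal" & dw$n_photons >= 3, ]
  expect_gt(nrow(internal), 100)
  for (s in 0:1) {
    dur <- internal$duration_ticks[internal$state == s] * d$clock_period
    k_exit <- -diag(rates_per_second(fit$model, d$clock_period))[s + 1]
    ks <- suppressWarnings(stats::ks.test(dur, "pexp", rate = k_exit))
    expect_gt(ks$p.value, 0.01)
  }
})
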