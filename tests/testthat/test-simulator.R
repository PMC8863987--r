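test_that("zero rates give a single dwell in the initial state", {
  traj <- simulate_trajectory(matrix(0, 2, 2), duration = 5, seed = 1,
                              initial = 2L)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$state, 2L)
  expect_equal(traj$time, 0)
})

test_that("symmetric two-state trajectories match exponential closed forms", {
  k <- 1000
  Q <- matrix(c(0, k, k, 0), 2, byrow = TRUE)
  traj <- simulate_trajectory(Q, duration = 100, seed = 2)
  dwell <- diff(c(traj$time, 100))
  n <- length(dwell)
  # mean dwell 1/k within 3 SE; occupancy 1/2 within 3 SE
  expect_lt(abs(mean(dwell) - 1 / k), 3 * (1 / k) / sqrt(n))
  occ1 <- sum(dwell[traj$state == 1]) / 100
  expect_lt(abs(occ1 - 0.5), 3 * 0.5 / sqrt(n / 2))
})

test_that("a cyclic three-state chain reaches its analytic stationary vector", {
  # detailed-balance-violating cycle
  Q <- matrix(c(0, 800, 100,
                100, 0, 800,
                800, 100, 0), 3, byrow = TRUE)
  G <- Q; diag(G) <- -rowSums(Q)
  pi_true <- stationary_distribution(G)
  traj <- simulate_trajectory(Q, duration = 60, seed = 3)
  dwell <- diff(c(traj$time, 60))
  occ <- tapply(dwell, factor(traj$state, 1:3), sum) / 60
  n_dwells <- nrow(traj)
  for (i in 1:3)
    expect_lt(abs(occ[i] - pi_true[i]), 3 * pi_true[i] / sqrt(n_dwells / 3))
  # eigen-solve cross-check of the stationary solver
  ev <- eigen(t(G))
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  expect_equal(pi_true, v / sum(v), tolerance = 1e-8)
})

test_that("emitted stream fractions are multinomial at the state probabilities", {
  sc <- sim_scenario(data.frame(E = 0.5, S = 0.5, rate = 1e5),
                     matrix(0, 1, 1), clock_period = 50e-9)
  # p = (0.25, 0.25, 0.5)
  traj <- data.frame(time = 0, state = 1L)
  ph <- emit_photons(traj, sc, duration = 1, seed = 4)
  n <- nrow(ph)
  expect_gt(n, 9e4)
  p <- c(0.25, 0.25, 0.5)
  frac <- tabulate(ph$stream + 1L, 3L) / n
  for (k in 1:3)
    expect_lt(abs(frac[k] - p[k]), 3 * sqrt(p[k] * (1 - p[k]) / n))
  # zero rate emits nothing
  sc0 <- sim_scenario(data.frame(E = 0.5, S = 0.5, rate = 0),
                      matrix(0, 1, 1))
  expect_equal(nrow(emit_photons(traj, sc0, 1, seed = 5)), 0L)
})

test_that("usALEX emission is strictly segregated by excitation window", {
  sc <- scenario_usalex_2state(n_bursts = 20L, seed = 26L)
  ds <- make_dataset(sc)
  pos <- ds$series$timestamps %% sc$scheme$alternation_period
  don <- ds$series$stream_index %in% c(0L, 1L)
  expect_true(all(pos[don] >= 0 & pos[don] < 2000))
  expect_true(all(pos[!don] >= 2000 & pos[!don] < 4000))
})

test_that("datasets are bitwise reproducible and extendable by seed design", {
  sc <- scenario_dynamic_2state(n_bursts = 10L, seed = 27L)
  a <- make_dataset(sc)
  b <- make_dataset(sc)
  expect_identical(a$series$timestamps, b$series$timestamps)
  expect_identical(a$series$stream_index, b$series$stream_index)
  expect_identical(a$truth$photon_state, b$truth$photon_state)
})

test_that("ground truth exports per-photon states as CSV", {
  ds <- make_dataset(scenario_dynamic_2state(n_bursts = 5L, seed = 33L))
  path <- tempfile(fileext = ".csv")
  write_ground_truth_csv(ds, path)
  got <- read.csv(path)
  expect_equal(nrow(got), length(ds$series$timestamps))
  expect_identical(names(got), c("tick", "stream", "state", "source"))
  expect_true(all(got$state[got$source == "state"] %in% 1:2))
  unlink(path)
})

test_that("ground-truth photon states agree with the trajectory", {
  sc <- scenario_dynamic_2state(n_bursts = 10L, seed = 28L)
  ds <- make_dataset(sc)
  clock <- sc$clock_period
  st <- ds$truth$photon_state
  src <- ds$truth$photon_source
  for (b in seq_len(nrow(ds$truth$windows))) {
    tr <- ds$truth$trajectories[[b]]
    w <- ds$truth$windows[b, ]
    in_b <- which(ds$series$timestamps >= w$start_tick &
                    ds$series$timestamps < w$stop_tick & src == "state")
    t_sec <- ds$series$timestamps[in_b] * clock
    expected <- tr$state[findInterval(t_sec, tr$time)]
    mismatch <- expected != st[in_b]
    # tick quantization can move a photon across a change point by < 1 tick
    expect_lt(mean(mismatch), 0.001)
  }
})

test_that("burst search recovers true high-contrast burst windows", {
  sc <- scenario_dynamic_2state(n_bursts = 100L, seed = 29L)
  sc$burst_duration_dist <- "fixed"
  sc$background <- c(DD = 700, DA = 500, AA = 600)
  sc$inter_burst_mean <- 80e-3   # quiet gaps long enough to carry photons
  ds <- make_dataset(sc)
  bg <- estimate_background(ds$series, slice_seconds = 30)
  found <- sliding_burst_search(ds$series, bg, m = 10, F = 6)
  # each true window should be matched by a found burst with small
  # photon-boundary error
  matched <- 0L
  for (b in seq_len(nrow(ds$bursts))) {
    ov <- which(found$start_tick < ds$bursts$stop_tick[b] &
                  found$stop_tick > ds$bursts$start_tick[b])
    if (!length(ov)) next
    i_err <- abs(found$i_start[ov[1]] - ds$bursts$i_start[b]) +
      abs(found$i_stop[ov[length(ov)]] - ds$bursts$i_stop[b])
    if (i_err < 10) matched <- matched + 1L
  }
  expect_gte(matched, 95L)
})

test_that("state alignment scores estimated against true models", {
  A <- matrix(0.001, 3, 3); diag(A) <- 0.998
  m <- state_model(c(0.5, 0.3, 0.2), A,
                   matrix(c(0.4, 0.1, 0.5,
                            0.2, 0.3, 0.5,
                            0.9, 0.05, 0.05), 3, byrow = TRUE))
  self <- align_states(m, m)
  expect_identical(self$perm, 1:3)
  expect_equal(self$E_err, rep(0, 3))
  swapped <- permute_states(m, c(2L, 1L, 3L))
  al <- align_states(swapped, m)
  expect_identical(al$perm, c(2L, 1L, 3L))
  expect_equal(al$E_err, rep(0, 3))
  expect_equal(max(abs(al$rate_rel_err), na.rm = TRUE), 0)
  # q mismatch is an explicit error
  m2 <- state_model(c(0.5, 0.5), diag(2),
                    matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE))
  expect_error(align_states(m2, m), "mismatch")
  # hand-computed errors
  m_off <- state_model(m$prior, m$trans,
                       matrix(c(0.45, 0.15, 0.40,
                                0.2, 0.3, 0.5,
                                0.9, 0.05, 0.05), 3, byrow = TRUE))
  al2 <- align_states(m_off, m)
  expect_equal(al2$E_err[1], 0.15 / 0.6 - 0.1 / 0.5, tolerance = 1e-12)
  expect_equal(al2$S_err[1], 0.6 - 0.5, tolerance = 1e-12)
})

test_that("a single-state fit recovers the emission probabilities", {
  sc <- scenario_static(E = 0.3, S = 0.6, n_bursts = 60L, seed = 31L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  fit <- h2mm(d, 1, max_iter = 50)
  p <- c(0.6 * 0.7, 0.6 * 0.3, 0.4)
  se <- sqrt(p * (1 - p) / d$n)
  expect_true(all(abs(as.numeric(fit$model$emission) - p) < 4 * se))
})
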