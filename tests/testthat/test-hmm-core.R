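test_that("transition_power is an exact matrix power", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  expect_equal(transition_power(diag(2), 17), diag(2))
  expect_equal(transition_power(A, 1), A)
  expect_equal(transition_power(A, 0), diag(2))
  expect_true(max(abs(transition_power(A, 3) - A %*% A %*% A)) < 1e-12)
  set.seed(1)
  B <- random_state_model(3, 2)$trans
  expect_true(max(abs(transition_power(B, 13) - matpow_naive(B, 13))) <
                1e-12)
  expect_error(transition_power(A, -1), "non-negative")
})

test_that("forward-backward reduces to closed forms", {
  set.seed(2)
  # q = 1: ln p is the sum of per-photon emission logs
  m1 <- state_model(1, matrix(1), matrix(c(0.3, 0.2, 0.5), 1))
  streams <- sample(0:2, 40, TRUE)
  gaps <- c(0, sample(0:5, 39, TRUE))
  d <- one_burst_obs(streams, gaps, r = 3)
  fb <- forward_backward(m1, d)
  expect_equal(fb$loglik, sum(log(m1$emission[1, streams + 1])),
               tolerance = 1e-12)
  # identical emission rows: ln p independent of prior and transitions
  m2 <- state_model(c(0.2, 0.8),
                    matrix(c(0.99, 0.01, 0.5, 0.5), 2, byrow = TRUE),
                    matrix(rep(c(0.3, 0.2, 0.5), each = 2), 2))
  fb2 <- forward_backward(m2, d)
  expect_equal(fb2$loglik, sum(log(m2$emission[1, streams + 1])),
               tolerance = 1e-10)
})

test_that("forward-backward equals the exhaustive path sum (fuzz)", {
  set.seed(3)
  for (rep in 1:40) {
    q <- sample(1:3, 1)
    r <- sample(2:3, 1)
    T <- sample(2:6, 1)
    m <- random_state_model(q, r)
    streams <- sample(0:(r - 1), T, TRUE)
    gaps <- c(0L, sample(0:4, T - 1, TRUE))
    d <- one_burst_obs(streams, gaps, r)
    fb <- forward_backward(m, d)
    expect_equal(fb$loglik, pathsum_loglik(m, streams, gaps),
                 tolerance = 1e-9)
    # gamma rows are posterior distributions
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-10))
  }
})

test_that("an unobservable stream yields an explicit -Inf flag", {
  m <- state_model(c(0.5, 0.5), diag(2),
                   matrix(c(1, 0, 1, 0), 2, byrow = TRUE))
  d <- one_burst_obs(c(0L, 1L), c(0L, 3L), r = 2)
  fb <- forward_backward(m, d)
  expect_false(fb$finite)
  expect_identical(fb$loglik, -Inf)
  expect_error(h2mm(d, 2, init = m, max_iter = 5), "offending burst")
})

test_that("gap handling equals the silent-tick chain expansion", {
  set.seed(4)
  for (rep in 1:30) {
    q <- sample(2:3, 1)
    r <- 3
    T <- sample(3:6, 1)
    m <- random_state_model(q, r, sticky = TRUE)
    streams <- sample(0:(r - 1), T, TRUE)
    gaps <- c(0L, sample(1:4, T - 1, TRUE))
    d <- one_burst_obs(streams, gaps, r)
    fb <- forward_backward(m, d)
    ex <- silent_tick_estep(m, streams, gaps)
    expect_equal(fb$loglik, ex$loglik, tolerance = 1e-9)
    expect_true(max(abs(fb$trans_counts - ex$trans_counts)) < 1e-9)
    expect_true(max(abs(fb$gamma - ex$gamma_photons)) < 1e-9)
  }
})

test_that("one EM step reproduces closed-form updates", {
  set.seed(5)
  # q = 1: emission update equals observed stream frequencies
  m1 <- state_model(1, matrix(1), matrix(c(0.3, 0.2, 0.5), 1))
  streams <- sample(0:2, 500, TRUE, prob = c(0.5, 0.25, 0.25))
  d <- one_burst_obs(streams, c(0, sample(1:9, 499, TRUE)), r = 3)
  st <- em_step(m1, d)
  expect_equal(as.numeric(st$model$emission),
               as.numeric(table(factor(streams, 0:2)) / 500),
               tolerance = 1e-12)
})

test_that("an EM step at the generating model moves parameters within noise", {
  # simulate from a 2-state model and take one EM step starting at truth:
  # each parameter should move by less than ~5x its sampling error
  sc <- scenario_dynamic_2state(n_bursts = 100L, seed = 6L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  truth <- ds$truth$model
  st <- em_step(truth, d)
  es0 <- state_es(truth)
  es1 <- state_es(st$model)
  # emission: binomial SE with n photons per state
  occ <- truth$prior * d$n
  se_E <- sqrt(es0$E_raw * (1 - es0$E_raw) / (occ / 2))
  expect_true(all(abs(es1$E_raw - es0$E_raw) < 5 * se_E))
  # transition: Poisson SE on the expected number of transition events
  total_time_s <- sum(d$gaps) * d$clock_period
  for (i in 1:2) for (j in 1:2) {
    if (i == j) next
    k <- 300
    n_events <- k * total_time_s * truth$prior[i]
    se_rel <- 1 / sqrt(n_events)
    k_new <- st$model$trans[i, j] / d$clock_period
    expect_lt(abs(k_new / k - 1), 5 * se_rel)
  }
})

test_that("EM never decreases the likelihood (random restarts)", {
  sc <- scenario_dynamic_2state(n_bursts = 20L, seed = 8L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  set.seed(9)
  for (rep in 1:20) {
    m <- random_state_model(sample(1:3, 1), 3, sticky = TRUE)
    fit <- h2mm(d, m$q, init = m, max_iter = 20, tol = 0)
    dll <- diff(fit$trace)
    expect_true(all(dll > -1e-8 * abs(fit$trace[-length(fit$trace)])))
  }
})

test_that("h2mm with max_iter = 0 evaluates the initial model unchanged", {
  sc <- scenario_static(n_bursts = 10L, seed = 10L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  set.seed(11)
  m <- random_state_model(2, 3)
  fit <- h2mm(d, 2, init = m, max_iter = 0)
  expect_equal(fit$model$emission, m$emission, tolerance = 1e-15)
  expect_equal(fit$model$trans, m$trans, tolerance = 1e-15)
  expect_equal(fit$niter, 0L)
  expect_equal(fit$loglik, forward_backward(m, d)$loglik)
})

test_that("optimization attains the ground-truth likelihood", {
  sc <- scenario_dynamic_2state(n_bursts = 60L, seed = 12L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  fit <- h2mm(d, 2, seed = 1, max_iter = 500)
  ll_truth <- forward_backward(ds$truth$model, d)$loglik
  expect_gte(fit$loglik, ll_truth - 1 * d$n / 1e4)
})

test_that("restarts from different initializer seeds agree", {
  sc <- scenario_dynamic_2state(n_bursts = 60L, seed = 12L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  f1 <- h2mm(d, 2, seed = 1, max_iter = 500)
  f2 <- h2mm(d, 2, seed = 2, max_iter = 500)
  expect_lt(abs(f1$loglik - f2$loglik), 1)
})

test_that("viterbi matches exhaustive enumeration and bounds the likelihood", {
  set.seed(13)
  for (rep in 1:10) {
    m <- random_state_model(3, 3)
    streams <- sample(0:2, 7, TRUE)
    gaps <- c(0L, sample(0:3, 6, TRUE))
    d <- one_burst_obs(streams, gaps, 3)
    vt <- viterbi(m, d)
    en <- viterbi_enum(m, streams, gaps)
    expect_equal(vt$logpost, en$logpost, tolerance = 1e-9)
    expect_identical(vt$paths[[1]], as.integer(en$path))
    # joint posterior never exceeds the marginal likelihood
    expect_lte(vt$logpost, forward_backward(m, d)$loglik + 1e-10)
  }
})

test_that("viterbi closed forms: single state and permutation emissions", {
  streams <- c(0L, 1L, 1L, 0L)
  d <- one_burst_obs(streams, c(0L, 2L, 1L, 3L), 2)
  m1 <- state_model(1, matrix(1), matrix(c(0.4, 0.6), 1))
  vt <- viterbi(m1, d)
  expect_identical(vt$paths[[1]], rep(0L, 4))
  expect_equal(vt$logpost, forward_backward(m1, d)$loglik)
  # near-deterministic permutation emissions with sticky transitions:
  # the path reads off the observed streams
  m2 <- state_model(c(0.5, 0.5),
                    matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE),
                    matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE))
  vt2 <- viterbi(m2, d)
  expect_identical(vt2$paths[[1]], streams)
})

test_that("state relabeling permutes outputs and preserves ln p and ICL", {
  sc <- scenario_dynamic_2state(n_bursts = 15L, seed = 14L)
  ds <- make_dataset(sc)
  d <- as_obs_set(ds$series, ds$bursts)
  set.seed(15)
  m <- random_state_model(3, 3, sticky = TRUE)
  perm <- c(3L, 1L, 2L)
  mp <- permute_states(m, perm)
  fb <- forward_backward(m, d)
  fbp <- forward_backward(mp, d)
  expect_equal(fbp$loglik, fb$loglik, tolerance = 1e-10)
  expect_equal(fbp$gamma, fb$gamma[, perm], tolerance = 1e-10)
  v <- viterbi(m, d)
  vp <- viterbi(mp, d)
  expect_equal(vp$logpost, v$logpost, tolerance = 1e-10)
  # ICL depends only on the joint posterior, K and n
  expect_equal(icl(vp$logpost, 14, d$n), icl(v$logpost, 14, d$n))
  expect_identical(lapply(vp$paths, function(p) perm[p + 1L] - 1L),
                   v$paths)
})

test_that("state model CSV serialization carries priors, E/S and rates", {
  m <- state_model(c(0.6, 0.4),
                   matrix(c(1 - 1e-5, 1e-5, 2e-5, 1 - 2e-5), 2,
                          byrow = TRUE),
                   matrix(c(0.4, 0.1, 0.5, 0.2, 0.3, 0.5), 2, byrow = TRUE))
  path <- tempfile(fileext = ".csv")
  write_state_model_csv(m, path, clock_period = 12.5e-9)
  got <- read.csv(path)
  expect_equal(got$prior, c(0.6, 0.4))
  expect_equal(got$E_raw, c(0.2, 0.6))
  expect_equal(got$rate_per_s_to_1[1], 1e-5 / 12.5e-9)
  unlink(path)
})
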