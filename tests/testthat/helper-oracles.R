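# Independent oracles: exhaustive path enumeration and the silent-tick
# chain expansion. Deliberately naive implementations, kept separate from
# the package's recursions.

rdirichlet1 <- function(n) {
  x <- rgamma(n, 1)
  x / sum(x)
}

random_state_model <- function(q, r, sticky = FALSE) {
  prior <- rdirichlet1(q)
  raw <- matrix(rgamma(q * q, 1), q)
  if (sticky) raw <- raw + diag(q) * 10
  trans <- raw / rowSums(raw)
  emission <- matrix(rgamma(q * r, 1), q)
  emission <- emission / rowSums(emission)
  state_model(prior, trans, emission)
}

matpow_naive <- function(A, d) {
  M <- diag(nrow(A))
  for (i in seq_len(d)) M <- M %*% A
  M
}

# log-likelihood by summing over every state path, with A^dt gap factors
pathsum_loglik <- function(model, streams, gaps) {
  q <- model$q
  T <- length(streams)
  pows <- lapply(0:max(gaps), function(d) matpow_naive(model$trans, d))
  paths <- as.matrix(expand.grid(rep(list(seq_len(q)), T)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    pr <- model$prior[s[1]] * model$emission[s[1], streams[1] + 1]
    if (T > 1) for (i in 2:T)
      pr <- pr * pows[[gaps[i] + 1]][s[i - 1], s[i]] *
        model$emission[s[i], streams[i] + 1]
    total <- total + pr
  }
  log(total)
}

# most likely path by enumeration
viterbi_enum <- function(model, streams, gaps) {
  q <- model$q
  T <- length(streams)
  pows <- lapply(0:max(gaps), function(d) matpow_naive(model$trans, d))
  paths <- as.matrix(expand.grid(rep(list(seq_len(q)), T)))
  best <- -Inf
  arg <- NULL
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    lp <- log(model$prior[s[1]]) +
      log(model$emission[s[1], streams[1] + 1])
    if (T > 1) for (i in 2:T)
      lp <- lp + log(pows[[gaps[i] + 1]][s[i - 1], s[i]]) +
        log(model$emission[s[i], streams[i] + 1])
    if (lp > best) { best <- lp; arg <- s }
  }
  list(path = arg - 1L, logpost = best)
}

# E-step via explicit chain expansion: insert gap-1 silent ticks (a null
# symbol emitted with probability 1 by every state) and run a plain scaled
# Baum-Welch forward-backward. Requires all gaps >= 1.
silent_tick_estep <- function(model, streams, gaps) {
  q <- model$q
  obs <- c()
  photon_pos <- c()
  for (i in seq_along(streams)) {
    if (i > 1 && gaps[i] >= 1) obs <- c(obs, rep(NA, gaps[i] - 1))
    photon_pos <- c(photon_pos, length(obs) + 1L)
    obs <- c(obs, streams[i])
  }
  T <- length(obs)
  bmat <- sapply(seq_len(T), function(t)
    if (is.na(obs[t])) rep(1, q) else model$emission[, obs[t] + 1])
  bmat <- matrix(bmat, nrow = q)
  alpha <- matrix(0, T, q)
  cs <- numeric(T)
  a <- model$prior * bmat[, 1]
  cs[1] <- sum(a)
  alpha[1, ] <- a / cs[1]
  if (T > 1) for (t in 2:T) {
    a <- as.numeric(t(model$trans) %*% alpha[t - 1, ]) * bmat[, t]
    cs[t] <- sum(a)
    alpha[t, ] <- a / cs[t]
  }
  beta <- matrix(0, T, q)
  beta[T, ] <- 1
  xi <- matrix(0, q, q)
  if (T > 1) for (t in (T - 1):1) {
    w <- bmat[, t + 1] * beta[t + 1, ] / cs[t + 1]
    xi <- xi + model$trans * (alpha[t, ] %o% w)
    beta[t, ] <- as.numeric(model$trans %*% w)
  }
  gamma <- alpha * beta
  list(loglik = sum(log(cs)), trans_counts = xi,
       gamma_photons = gamma[photon_pos, , drop = FALSE])
}

# brute-force sliding-window burst scan: per photon, test every window
# covering it
brute_burst_photons <- function(ts_ticks, clock, m, F, bg_rate) {
  n <- length(ts_ticks)
  covered <- rep(FALSE, n)
  for (i in seq_len(max(0, n - m + 1))) {
    span <- (ts_ticks[i + m - 1] - ts_ticks[i]) * clock
    rate <- if (span == 0) Inf else m / span
    if (rate >= F * bg_rate) covered[i:(i + m - 1)] <- TRUE
  }
  covered
}

# small obs_set from explicit vectors (single burst)
one_burst_obs <- function(streams, gaps, r, clock = 1) {
  obs_set(list(streams), list(gaps), r = r, clock_period = clock)
}
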