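#' Simulation scenario
#'
#' Describes a synthetic smFRET measurement: hidden states with raw-E/S
#' signatures and total photon rates, a continuous-time Markov rate matrix
#' between them, a burst model (count, duration distribution, quiet gaps),
#' per-stream background rates, the clock, and the excitation mode.
#'
#' Each state's per-photon stream probabilities follow from its (E, S)
#' target as `p_DD = S (1 - E)`, `p_DA = S E`, `p_AA = 1 - S`, so the
#' simulated stream frequencies reproduce the requested raw ratios exactly
#' in expectation. Dark-dye photophysics is modelled as ordinary states:
#' a dark acceptor is a high-S state (donor-excitation photons only), a
#' dark donor a low-S state. Diffusion through the excitation volume is
#' *not* simulated — bursts have constant brightness — which is sufficient
#' for likelihood and recovery testing.
#'
#' In usALEX mode, emitted photons are thinned by the alternation gating:
#' donor-excitation photons (DD/DA) are retained only while the donor laser
#' window is open, AA photons only during the acceptor window. With equal
#' half-period windows each class retains half its photons, so the target
#' S values hold post-thinning unchanged.
#'
#' @param states Data frame with columns `E`, `S` (raw signatures in
#'   \[0, 1\]) and `rate` (total photon counts/s while in the state).
#' @param rate_matrix q x q transition rate matrix in s^-1 (off-diagonal;
#'   diagonal ignored).
#' @param n_bursts Number of bursts.
#' @param burst_duration_mean Mean burst duration in seconds.
#' @param burst_duration_dist `"exponential"` or `"fixed"`.
#' @param inter_burst_mean Mean quiet gap between bursts in seconds.
#' @param background Named per-stream background rates in counts/s,
#'   `c(DD = , DA = , AA = )`.
#' @param clock_period Seconds per clock tick.
#' @param mode `"nsALEX"` or `"usALEX"`.
#' @param scheme Required for usALEX: an [alternation_scheme()].
#' @param seed Default seed for [make_dataset()].
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(states, rate_matrix, n_bursts = 100L,
                         burst_duration_mean = 3e-3,
                         burst_duration_dist = c("exponential", "fixed"),
                         inter_burst_mean = 20e-3,
                         background = c(DD = 0, DA = 0, AA = 0),
                         clock_period = 50e-9,
                         mode = c("nsALEX", "usALEX"), scheme = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  burst_duration_dist <- match.arg(burst_duration_dist)
  states <- as.data.frame(states)
  stopifnot(all(c("E", "S", "rate") %in% names(states)),
            all(states$E >= 0 & states$E <= 1),
            all(states$S >= 0 & states$S <= 1),
            all(states$rate >= 0))
  q <- nrow(states)
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(all(dim(rate_matrix) == q))
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  diag(rate_matrix) <- 0
  diag(rate_matrix) <- -rowSums(rate_matrix)
  if (mode == "usALEX") {
    if (is.null(scheme) || scheme$mode != "usALEX")
      stop("usALEX mode requires a usALEX alternation scheme")
  }
  background <- if (is.null(names(background))) rep_len(background, 3)
                else background[c("DD", "DA", "AA")]
  background[is.na(background)] <- 0
  names(background) <- c("DD", "DA", "AA")
  structure(list(states = states, rate_matrix = rate_matrix,
                 n_bursts = as.integer(n_bursts),
                 burst_duration_mean = burst_duration_mean,
                 burst_duration_dist = burst_duration_dist,
                 inter_burst_mean = inter_burst_mean,
                 background = background, clock_period = clock_period,
                 mode = mode, scheme = scheme, seed = as.integer(seed)),
            class = "sim_scenario")
}

# per-state stream probability rows p = (S(1-E), S E, 1-S)
scenario_emission <- function(scenario) {
  with(scenario$states,
       cbind(S * (1 - E), S * E, 1 - S))
}

#' True state model of a scenario at the simulation clock
#'
#' Prior = stationary distribution of the rate matrix; per-tick transition
#' matrix `I + Q * clock_period` (the rates are small per tick, so the
#' linearization error is of order `(k tau)^2`, well below 1e-8 here);
#' emission rows from the (E, S) mapping.
#'
#' @param scenario A `sim_scenario`.
#' @return A `state_model`.
#' @export
scenario_true_model <- function(scenario) {
  Q <- scenario$rate_matrix
  A <- diag(nrow(Q)) + Q * scenario$clock_period
  state_model(stationary_distribution(Q), A, scenario_emission(scenario))
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a bordered linear system.
#' @param Q q x q generator (rows sum to zero).
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  q <- nrow(Q)
  if (q == 1) return(1)
  M <- rbind(t(Q), rep(1, q))
  b <- c(rep(0, q), 1)
  as.numeric(qr.solve(M, b))
}

# deterministic per-segment substream seed from the global one, so changing
# the burst count does not reshuffle earlier bursts
segment_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * index) %% 2147483647)
}

#' Sample a hidden state trajectory (exact CTMC)
#'
#' Gillespie sampling: dwell times are exponential at the state's total
#' exit rate, successor states follow the off-diagonal rates. All-zero exit
#' rates yield a single dwell spanning the duration.
#'
#' @param rate_matrix q x q rate matrix in s^-1.
#' @param duration Trajectory length in seconds.
#' @param seed RNG seed.
#' @param initial Initial state (1-based); sampled from the stationary
#'   distribution when `NULL`.
#' @return Data frame of change points: `time` (s, starting at 0) and
#'   `state` (1-based); each row opens a dwell lasting until the next row
#'   (or `duration`).
#' @export
simulate_trajectory <- function(rate_matrix, duration, seed = 1L,
                                initial = NULL) {
  Q <- as.matrix(rate_matrix)
  diag(Q) <- 0
  q <- nrow(Q)
  set.seed(seed %% .Machine$integer.max)
  if (is.null(initial)) {
    G <- Q; diag(G) <- -rowSums(Q)
    pi0 <- stationary_distribution(G)
    initial <- sample.int(q, 1, prob = pmax(pi0, 0))
  }
  times <- 0; states <- initial
  t <- 0; s <- initial
  repeat {
    exit <- sum(Q[s, ])
    if (exit <= 0) break
    t <- t + rexp(1, exit)
    if (t >= duration) break
    s <- sample.int(q, 1, prob = Q[s, ])
    times <- c(times, t); states <- c(states, s)
  }
  data.frame(time = times, state = states)
}

#' Emit photons from a state trajectory
#'
#' Photon arrivals form a Poisson process at the current state's total
#' rate; each photon's stream is drawn from the state's
#' `(p_DD, p_DA, p_AA)`. Per-stream background photons are superposed over
#' the whole window. Timestamps are quantized to clock ticks; in usALEX
#' mode the alternation gating then thins the photons (DD/DA retained in
#' donor windows, AA in acceptor windows).
#'
#' @param trajectory A [simulate_trajectory()] data frame covering
#'   `[0, duration)`.
#' @param scenario The `sim_scenario`.
#' @param duration Window length in seconds.
#' @param seed RNG seed.
#' @param t0_sec Absolute start time of the window (seconds), added before
#'   tick quantization (the alternation phase depends on absolute time).
#' @return Data frame `tick`, `stream` (0/1/2), `state` (1-based true
#'   state at the photon time, kept for background photons too), `source`
#'   (`"state"` or `"background"`), sorted by tick.
#' @export
emit_photons <- function(trajectory, scenario, duration, seed = 1L,
                         t0_sec = 0) {
  set.seed(seed %% .Machine$integer.max)
  emis <- scenario_emission(scenario)
  t <- numeric(0); str <- integer(0); st <- integer(0); src <- character(0)
  # state photons, dwell by dwell
  bounds <- c(trajectory$time, duration)
  for (d in seq_len(nrow(trajectory))) {
    len <- bounds[d + 1] - bounds[d]
    if (len <= 0) next
    s <- trajectory$state[d]
    rate <- scenario$states$rate[s]
    n <- rpois(1, rate * len)
    if (n == 0) next
    tt <- sort(runif(n, bounds[d], bounds[d + 1]))
    ss <- sample.int(3L, n, replace = TRUE, prob = emis[s, ]) - 1L
    t <- c(t, tt); str <- c(str, ss)
    st <- c(st, rep(s, n)); src <- c(src, rep("state", n))
  }
  # background per stream
  for (k in 1:3) {
    bg <- scenario$background[k]
    if (bg <= 0) next
    n <- rpois(1, bg * duration)
    if (n == 0) next
    t <- c(t, sort(runif(n, 0, duration)))
    str <- c(str, rep(k - 1L, n))
    # the trajectory state at the photon time, for bookkeeping
    t_new <- t[(length(t) - n + 1L):length(t)]
    st <- c(st, trajectory$state[findInterval(t_new, trajectory$time)])
    src <- c(src, rep("background", n))
  }
  if (!length(t))
    return(data.frame(tick = numeric(0), stream = integer(0),
                      state = integer(0), source = character(0)))
  tick <- floor((t + t0_sec) / scenario$clock_period)
  out <- data.frame(tick = tick, stream = str, state = st, source = src)
  out <- out[order(out$tick, method = "radix"), , drop = FALSE]
  if (scenario$mode == "usALEX") {
    sch <- scenario$scheme
    pos <- out$tick %% sch$alternation_period
    in_don <- pos >= sch$donor_window[1] & pos < sch$donor_window[2]
    in_acc <- pos >= sch$acceptor_window[1] & pos < sch$acceptor_window[2]
    keep <- (out$stream %in% c(0L, 1L) & in_don) |
      (out$stream == 2L & in_acc)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset
#'
#' Concatenates quiet background stretches and burst windows: each burst
#' window carries a fresh hidden-state trajectory (initialized from the
#' stationary distribution) plus background; quiet stretches carry
#' background only. Returns the raw photon series (for burst-search
#' testing), the *true* burst windows as a `burst_set` (for HMM testing
#' without search noise), and the ground truth (per-photon true states,
#' per-burst trajectories, and the true `state_model` at the clock).
#'
#' A single global seed fans out to per-segment substreams, so outputs are
#' bitwise reproducible and early bursts do not change when `n_bursts`
#' grows.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Global seed (defaults to the scenario's).
#' @return List with `series` (a `photon_series`), `bursts` (true-window
#'   `burst_set`), and `truth` (list: `model`, `photon_state`,
#'   `photon_source`, `trajectories`, `windows`).
#' @export
make_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  clock <- scenario$clock_period
  bg_total <- sum(scenario$background)
  pieces <- list()
  trajs <- list()
  win_start <- win_stop <- numeric(scenario$n_bursts)
  t_cursor <- 0
  for (b in seq_len(scenario$n_bursts)) {
    set.seed(segment_seed(seed, 3L * b - 2L))
    quiet <- if (scenario$inter_burst_mean > 0)
      rexp(1, 1 / scenario$inter_burst_mean) else 0
    if (bg_total > 0 && quiet > 0) {
      nq <- rpois(1, bg_total * quiet)
      if (nq > 0) {
        tq <- sort(runif(nq, 0, quiet))
        sq <- sample.int(3L, nq, replace = TRUE,
                         prob = scenario$background / bg_total) - 1L
        qt <- floor((tq + t_cursor) / clock)
        if (scenario$mode == "usALEX") {
          sch <- scenario$scheme
          pos <- qt %% sch$alternation_period
          keepq <- (sq %in% c(0L, 1L) & pos >= sch$donor_window[1] &
                      pos < sch$donor_window[2]) |
            (sq == 2L & pos >= sch$acceptor_window[1] &
               pos < sch$acceptor_window[2])
          qt <- qt[keepq]; sq <- sq[keepq]
        }
        if (length(qt))
          pieces[[length(pieces) + 1L]] <-
            data.frame(tick = qt, stream = sq, state = NA_integer_,
                       source = "background")
      }
    }
    t_cursor <- t_cursor + quiet
    dur <- if (scenario$burst_duration_dist == "fixed")
      scenario$burst_duration_mean
    else rexp(1, 1 / scenario$burst_duration_mean)
    traj <- simulate_trajectory(scenario$rate_matrix, dur,
                                seed = segment_seed(seed, 3L * b - 1L))
    ph <- emit_photons(traj, scenario, dur,
                       seed = segment_seed(seed, 3L * b),
                       t0_sec = t_cursor)
    traj$time <- traj$time + t_cursor
    trajs[[b]] <- traj
    win_start[b] <- floor(t_cursor / clock)
    win_stop[b] <- floor((t_cursor + dur) / clock)
    if (nrow(ph)) pieces[[length(pieces) + 1L]] <- ph
    t_cursor <- t_cursor + dur
  }
  all <- do.call(rbind, pieces)
  all <- all[order(all$tick, method = "radix"), , drop = FALSE]
  series <- photon_series(all$tick, all$stream, clock,
                          acquisition_duration = t_cursor,
                          streams_assigned = TRUE)
  i_start <- findInterval(win_start - 0.5, all$tick)
  i_stop <- findInterval(win_stop - 0.5, all$tick)
  keep <- i_stop > i_start
  bursts <- make_burst_set(series, i_start[keep], i_stop[keep])
  truth <- list(model = scenario_true_model(scenario),
                photon_state = all$state, photon_source = all$source,
                trajectories = trajs,
                windows = data.frame(start_tick = win_start,
                                     stop_tick = win_stop,
                                     retained = keep))
  list(series = series, bursts = bursts, truth = truth)
}

#' Export the simulator's ground truth as CSV
#'
#' One row per photon of the dataset's series: `tick`, `stream`, the true
#' hidden `state` at the photon time (1-based; empty for quiet-stretch
#' background photons) and the photon `source` (`state` or `background`).
#'
#' @param dataset A [make_dataset()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(dataset, path) {
  df <- data.frame(tick = dataset$series$timestamps,
                   stream = dataset$series$stream_index,
                   state = dataset$truth$photon_state,
                   source = dataset$truth$photon_source)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Align an estimated model with the ground truth
#'
#' Finds the state permutation minimizing the total Euclidean distance in
#' (E, S) between estimated and true states, and reports per-state errors.
#'
#' @param estimated,truth `state_model`s with the same q.
#' @param clock_period Seconds per tick, for rate errors (optional).
#' @return List with `perm` (estimated state matched to each true state,
#'   1-based), `E_err`, `S_err` (signed, estimated minus true), and
#'   `rate_rel_err` (q x q off-diagonal relative errors, estimated/true -
#'   1; `NA` where the true rate is 0).
#' @export
align_states <- function(estimated, truth, clock_period = NULL) {
  stopifnot(inherits(estimated, "state_model"),
            inherits(truth, "state_model"))
  if (estimated$q != truth$q)
    stop("state count mismatch: estimated q = ", estimated$q,
         ", truth q = ", truth$q, " (no alignment attempted)")
  q <- truth$q
  es_e <- state_es(estimated)
  es_t <- state_es(truth)
  dist1 <- function(i, j) {
    dS <- es_t$S_raw[i] - es_e$S_raw[j]
    if (is.na(dS)) dS <- 0
    sqrt((es_t$E_raw[i] - es_e$E_raw[j])^2 + dS^2)
  }
  perms <- all_permutations(q)
  tot <- vapply(perms, function(p)
    sum(vapply(seq_len(q), function(i) dist1(i, p[i]), 1)), 1)
  perm <- perms[[which.min(tot)]]
  A_e <- estimated$trans[perm, perm, drop = FALSE]
  A_t <- truth$trans
  rel <- A_e / A_t - 1
  rel[A_t == 0] <- NA
  diag(rel) <- NA
  list(perm = perm,
       E_err = es_e$E_raw[perm] - es_t$E_raw,
       S_err = es_e$S_raw[perm] - es_t$S_raw,
       rate_rel_err = rel)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Canned scenario: three-state nsALEX system with a dark acceptor
#'
#' Two FRET states (E 0.2 and 0.65 at S 0.5, interconverting at
#' 300 s^-1 each way — a millisecond two-state system) plus a
#' dark-acceptor blinking state entered at 100 s^-1 and left at
#' 1000 s^-1. The dark state emits only donor-excitation photons
#' (S 0.95 allowing a little direct acceptor excitation) and its raw E
#' (0.2, from donor leakage) coincides with the low-FRET state, so in the
#' donor-excitation streams alone it is indistinguishable from low FRET —
#' the configuration in which the acceptor-excitation stream is decisive.
#' Burst photon rate 1e5 /s, 500 exponential bursts of mean 4.5 ms,
#' background (700, 500, 600) counts/s, 50 ns clock.
#'
#' @param n_bursts,seed Overridable defaults.
#' @return A `sim_scenario`.
#' @export
scenario_3state_dark_acceptor <- function(n_bursts = 500L, seed = 1L) {
  states <- data.frame(E = c(0.2, 0.65, 0.2), S = c(0.5, 0.5, 0.95),
                       rate = c(1e5, 1e5, 1e5))
  Q <- matrix(c(0,   300, 100,
                300, 0,   100,
                500, 500, 0), 3, 3, byrow = TRUE)
  sim_scenario(states, Q, n_bursts = n_bursts,
               burst_duration_mean = 4.5e-3,
               burst_duration_dist = "exponential",
               inter_burst_mean = 20e-3,
               background = c(DD = 700, DA = 500, AA = 600),
               clock_period = 50e-9, mode = "nsALEX", seed = seed)
}

#' Canned scenario: two-state usALEX system (20 kHz alternation)
#'
#' Two FRET states (E 0.2/0.65, S 0.5) interconverting at 300 s^-1, with
#' 12.5 ns clock and a 4000-tick (50 us, 20 kHz) alternation period split
#' into equal donor/acceptor windows. Used to demonstrate the alternation
#' artifact and its cure by [shift_acceptor_photons()].
#'
#' @param n_bursts,seed Overridable defaults.
#' @return A `sim_scenario`.
#' @export
scenario_usalex_2state <- function(n_bursts = 300L, seed = 1L) {
  states <- data.frame(E = c(0.2, 0.65), S = c(0.5, 0.5),
                       rate = c(1e5, 1e5))
  Q <- matrix(c(0, 300, 300, 0), 2, 2, byrow = TRUE)
  sch <- alternation_scheme("usALEX", alternation_period = 4000,
                            donor_window = c(0, 2000),
                            acceptor_window = c(2000, 4000))
  sim_scenario(states, Q, n_bursts = n_bursts,
               burst_duration_mean = 4.5e-3,
               burst_duration_dist = "exponential",
               inter_burst_mean = 20e-3,
               background = c(DD = 700, DA = 500, AA = 600),
               clock_period = 12.5e-9, mode = "usALEX", scheme = sch,
               seed = seed)
}

#' Canned scenario: static single state
#'
#' One state at the given (E, S), no dynamics — the shot-noise-only
#' reference for BVA calibration.
#'
#' @param E,S State signature.
#' @param n_bursts,seed Overridable defaults.
#' @return A `sim_scenario`.
#' @export
scenario_static <- function(E = 0.5, S = 0.5, n_bursts = 500L, seed = 1L) {
  sim_scenario(data.frame(E = E, S = S, rate = 1e5),
               matrix(0, 1, 1), n_bursts = n_bursts,
               burst_duration_mean = 4.5e-3,
               burst_duration_dist = "exponential",
               inter_burst_mean = 20e-3,
               background = c(DD = 0, DA = 0, AA = 0),
               clock_period = 50e-9, mode = "nsALEX", seed = seed)
}

#' Canned scenario: millisecond two-state nsALEX dynamics
#'
#' E 0.2/0.65 at S 0.5, 300 s^-1 each way — produces the classic BVA
#' signature of within-burst dynamics above the shot-noise semicircle at
#' intermediate E.
#'
#' @param n_bursts,seed Overridable defaults.
#' @return A `sim_scenario`.
#' @export
scenario_dynamic_2state <- function(n_bursts = 500L, seed = 1L) {
  states <- data.frame(E = c(0.2, 0.65), S = c(0.5, 0.5),
                       rate = c(1e5, 1e5))
  Q <- matrix(c(0, 300, 300, 0), 2, 2, byrow = TRUE)
  sim_scenario(states, Q, n_bursts = n_bursts,
               burst_duration_mean = 4.5e-3,
               burst_duration_dist = "exponential",
               inter_burst_mean = 20e-3,
               background = c(DD = 0, DA = 0, AA = 0),
               clock_period = 50e-9, mode = "nsALEX", seed = seed)
}
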