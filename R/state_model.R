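#' State model for the photon-by-photon HMM
#'
#' A `q`-state hidden Markov model over `r` photon streams: initial state
#' probabilities `prior` (length q), the *per-clock-tick* transition matrix
#' `trans` (q x q, row stochastic) and the emission matrix `emission`
#' (q x r, row stochastic; row i gives the probability that a photon emitted
#' while in state i belongs to each stream). Because `trans` acts per tick,
#' the kernel between two photons separated by `dt` ticks is the exact
#' matrix power `trans^dt` (see [transition_power()]).
#'
#' @param prior Length-q probability vector.
#' @param trans q x q row-stochastic matrix of per-tick transition
#'   probabilities.
#' @param emission q x r row-stochastic matrix.
#' @return An object of class `state_model`.
#' @export
state_model <- function(prior, trans, emission) {
  prior <- as.numeric(prior)
  trans <- as.matrix(trans)
  emission <- as.matrix(emission)
  q <- length(prior)
  if (q < 1) stop("q must be at least 1")
  if (!all(dim(trans) == q)) stop("trans must be q x q")
  if (nrow(emission) != q) stop("emission must have q rows")
  if (ncol(emission) < 2) stop("at least r = 2 photon streams are required")
  if (any(prior < 0) || any(trans < 0) || any(emission < 0))
    stop("probabilities must be non-negative")
  chk <- function(x, nm) {
    s <- if (is.matrix(x)) rowSums(x) else sum(x)
    if (any(abs(s - 1) > 1e-12))
      stop(nm, " rows must sum to 1 (within 1e-12); got ",
           paste(format(s), collapse = ", "))
  }
  chk(prior, "prior"); chk(trans, "trans"); chk(emission, "emission")
  structure(list(prior = prior, trans = unname(trans),
                 emission = unname(emission), q = q, r = ncol(emission)),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> q =", x$q, "states, r =", x$r, "streams\n")
  es <- state_es(x)
  df <- data.frame(state = seq_len(x$q) - 1L, prior = round(x$prior, 4),
                   E_raw = round(es$E_raw, 4), S_raw = round(es$S_raw, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-state raw E and S signatures of a model
#'
#' Reads the raw-FRET-efficiency and stoichiometry signature of each state
#' off its emission row: `E_raw = p_DA / (p_DD + p_DA)` and
#' `S_raw = (p_DD + p_DA)` (for r = 3; `S_raw` is `NA` for r = 2, where
#' there is no acceptor-excitation stream).
#'
#' @param model A `state_model`.
#' @return List with numeric vectors `E_raw` and `S_raw` (length q).
#' @export
state_es <- function(model) {
  B <- model$emission
  dex <- B[, 1] + B[, 2]
  E <- ifelse(dex > 0, B[, 2] / dex, NA_real_)
  S <- if (model$r >= 3) dex / rowSums(B[, 1:3, drop = FALSE])
       else rep(NA_real_, model$q)
  list(E_raw = E, S_raw = S)
}

#' Relabel the states of a model
#'
#' @param model A `state_model`.
#' @param perm Permutation of `1:q`; new state k is old state `perm[k]`.
#' @return The permuted `state_model`.
#' @export
permute_states <- function(model, perm) {
  stopifnot(inherits(model, "state_model"),
            sort(perm) == seq_len(model$q))
  state_model(model$prior[perm], model$trans[perm, perm, drop = FALSE],
              model$emission[perm, , drop = FALSE])
}

#' Default model initializer
#'
#' Deterministic given `(q, r, seed, pattern)`: uniform prior; off-diagonal
#' per-tick transition probabilities logarithmically spaced over
#' \[1e-7, 1e-3\] across state pairs; the seed applies a small
#' multiplicative jitter so independent restarts can be compared.
#'
#' Two emission-row patterns are available. `"fret-spread"` (the default)
#' spreads rows evenly over the E axis at S of about 0.5 with, for q >= 3
#' and r = 3, one high-S row and one low-S row, so dark-dye candidate
#' states are represented from the start. `"s-split"` (r = 3 only) places
#' half the rows at high S and half at low S — the complementary pattern
#' for solutions organized along the stoichiometry axis rather than the
#' FRET axis (dark-dye-dominated fits, or the laser-alternation artifact
#' of unshifted usALEX data, whose basin is not reachable from S = 0.5
#' rows). Jitter-seed restarts do not cross between these basins, so
#' structurally diverse multi-starts fit both patterns and keep the higher
#' likelihood.
#'
#' @param q Number of states.
#' @param r Number of streams (2 or 3).
#' @param seed Integer jitter seed.
#' @param pattern `"fret-spread"` or `"s-split"`.
#' @return A `state_model`.
#' @export
default_init_model <- function(q, r, seed = 1L,
                               pattern = c("fret-spread", "s-split")) {
  stopifnot(q >= 1, r >= 2)
  pattern <- match.arg(pattern)
  if (pattern == "s-split" && r != 3)
    stop("the s-split pattern requires r = 3")
  prior <- rep(1 / q, q)
  trans <- diag(q)
  if (q > 1) {
    off <- 10^seq(-7, -3, length.out = q * (q - 1))
    k <- 1L
    for (i in seq_len(q)) for (j in seq_len(q)) if (i != j) {
      trans[i, j] <- off[k]; k <- k + 1L
    }
    diag(trans) <- 0
    diag(trans) <- 1 - rowSums(trans)
  }
  if (pattern == "s-split") {
    n_hi <- ceiling(q / 2)
    evals <- seq(0.15, 0.85, length.out = max(n_hi, 2L))[seq_len(n_hi)]
    rows <- lapply(evals, function(e)
      c(0.95 * (1 - e), 0.95 * e, 0.05))                      # high-S
    rows <- c(rows, rep(list(c(0.05 * 0.5, 0.05 * 0.5, 0.95)),
                        q - n_hi))                            # low-S
  } else {
    n_fret <- if (r == 3 && q >= 3) q - 2L else q
    evals <- if (n_fret > 0) seq(0.15, 0.85, length.out = max(n_fret, 2L))[
      seq_len(n_fret)] else numeric(0)
    rows <- lapply(evals, function(e) {
      if (r == 3) c(0.5 * (1 - e), 0.5 * e, 0.5) else c(1 - e, e)
    })
    if (r == 3 && q >= 3) {
      rows <- c(rows, list(c(0.95 * 0.7, 0.95 * 0.3, 0.05)),  # high-S (dark A)
                list(c(0.15 * 0.5, 0.15 * 0.5, 0.85)))        # low-S (dark D)
    }
  }
  emission <- do.call(rbind, rows)
  set.seed(seed %% .Machine$integer.max)
  jit <- matrix(runif(q * r, 0.9, 1.1), q, r)
  emission <- emission * jit
  emission <- emission / rowSums(emission)
  state_model(prior, trans, emission)
}

#' Grow a model by one state
#'
#' Warm-start construction for incremental model scans: appends one state
#' with a flat (uninformative) emission row, slow symmetric transitions to
#' and from every existing state (1e-6 per tick), and a small prior share.
#' EM then pulls the new state toward whatever structure the current model
#' leaves unexplained.
#'
#' @param model A `state_model`.
#' @return A `state_model` with q + 1 states.
#' @export
grow_model <- function(model) {
  stopifnot(inherits(model, "state_model"))
  q <- model$q
  r <- model$r
  eps <- 1e-6
  trans <- cbind(model$trans * (1 - eps), rep(eps, q))
  newrow <- c(rep(eps, q), 1 - q * eps)
  trans <- rbind(trans, newrow)
  emission <- rbind(model$emission, rep(1 / r, r))
  prior <- c(model$prior * 0.95, 0.05)
  state_model(prior, trans, emission)
}

#' Exact matrix power of the per-tick transition matrix
#'
#' Computes `trans^dt` by binary exponentiation; `dt = 0` yields the
#' identity (simultaneous photons on different detectors advance no time).
#'
#' @param trans Row-stochastic q x q matrix.
#' @param dt Non-negative integer number of ticks.
#' @return The q x q matrix power.
#' @export
transition_power <- function(trans, dt) {
  if (length(dt) != 1 || is.na(dt) || dt < 0 || dt != floor(dt))
    stop("dt must be a single non-negative integer")
  cpp_transition_power(as.matrix(trans), as.numeric(dt))
}

#' Serialize a state model (or fit) to CSV
#'
#' One row per state: prior, `E_raw`, `S_raw`, the per-tick transition
#' probabilities and the per-second rate constants.
#'
#' @param model A `state_model` or `h2mm` fit.
#' @param path Output file.
#' @param clock_period Seconds per tick (taken from the fit if omitted).
#' @return `path`, invisibly.
#' @export
write_state_model_csv <- function(model, path, clock_period = NULL) {
  if (inherits(model, "h2mm")) {
    if (is.null(clock_period)) clock_period <- model$clock_period
    model <- model$model
  }
  stopifnot(inherits(model, "state_model"))
  es <- state_es(model)
  df <- data.frame(state = seq_len(model$q) - 1L, prior = model$prior,
                   E_raw = es$E_raw, S_raw = es$S_raw)
  for (j in seq_len(model$q))
    df[[paste0("trans_per_tick_to_", j - 1L)]] <- model$trans[, j]
  if (!is.null(clock_period)) {
    k <- rates_per_second(model, clock_period)
    for (j in seq_len(model$q))
      df[[paste0("rate_per_s_to_", j - 1L)]] <- k[, j]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
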