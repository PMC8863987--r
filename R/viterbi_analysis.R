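#' Segment Viterbi paths into dwells
#'
#' Consecutive photons assigned the same state form a single dwell. Each
#' dwell carries its per-stream photon counts, its raw E and S (same
#' definitions as [burst_ratios()], `NA` when undefined), its duration in
#' ticks measured photon-to-photon (first to last photon of the dwell; 0
#' for single-photon dwells — no extrapolation to burst edges), and a
#' position tag: `whole-burst`, `initial`, `internal` or `terminal`. Edge
#' dwells are truncated by the burst window, so duration analyses usually
#' restrict to `internal` dwells.
#'
#' @param paths List of per-burst Viterbi state vectors (0-based), as
#'   returned by [viterbi()] or [predict.h2mm()].
#' @param data The decoded [obs_set].
#' @return A `dwell_table` data frame: `burst_id`, `state`, `i_first`,
#'   `i_last` (0-based photon indices within the burst), `n_photons`,
#'   `n_DD`, `n_DA`, `n_AA`, `duration_ticks`, `E_raw`, `S_raw`,
#'   `position`.
#' @export
segment_dwells <- function(paths, data) {
  stopifnot(inherits(data, "obs_set"))
  streams <- split_by_burst(data$streams, data$lens)
  gaps <- split_by_burst(data$gaps, data$lens)
  out <- list()
  for (b in seq_along(paths)) {
    path <- paths[[b]]
    if (length(path) != data$lens[b])
      stop("path length does not match burst ", b - 1L, " photon count")
    tick <- cumsum(gaps[[b]])        # relative tick of each photon
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nd <- length(r$values)
    cnt <- t(vapply(seq_len(nd), function(d)
      tabulate(streams[[b]][starts[d]:ends[d]] + 1L, nbins = 3L),
      integer(3)))
    if (data$r == 2) cnt[, 3] <- 0L
    rat <- burst_ratios(cnt[, 1], cnt[, 2], cnt[, 3])
    pos <- rep("internal", nd)
    pos[1] <- "initial"
    pos[nd] <- "terminal"
    if (nd == 1) pos <- "whole-burst"
    out[[b]] <- data.frame(
      burst_id = b - 1L, state = r$values,
      i_first = starts - 1L, i_last = ends - 1L,
      n_photons = r$lengths,
      n_DD = cnt[, 1], n_DA = cnt[, 2], n_AA = cnt[, 3],
      duration_ticks = tick[ends] - tick[starts],
      E_raw = rat$E_raw, S_raw = rat$S_raw, position = pos)
  }
  res <- do.call(rbind, out)
  class(res) <- c("dwell_table", "data.frame")
  res
}

#' Classify bursts by the states present in their Viterbi path
#'
#' @param paths List of per-burst Viterbi state vectors (0-based).
#' @return Data frame `burst_id`, `states` (sorted, `+`-joined) and `label`
#'   (`pure-state-k` or `mixed-{...}`), with a `counts` attribute
#'   tabulating labels.
#' @export
classify_bursts <- function(paths) {
  states <- lapply(paths, function(p) sort(unique(p)))
  lab <- vapply(states, function(s) {
    if (length(s) == 1) paste0("pure-state-", s)
    else paste0("mixed-{", paste(s, collapse = ","), "}")
  }, "")
  out <- data.frame(burst_id = seq_along(paths) - 1L,
                    states = vapply(states, paste, "", collapse = "+"),
                    label = lab)
  attr(out, "counts") <- sort(table(lab), decreasing = TRUE)
  out
}

#' Weighted dwell statistics per state
#'
#' Photon-count-weighted mean, standard deviation and standard error of the
#' dwell-wise `E_raw` and `S_raw`, per state — the dwell-based proxy for
#' the standard error of the fitted model's state parameters. Weights match
#' the ratio denominators: donor-excitation photons (`n_DD + n_DA`) for E,
#' all photons for S. The standard error uses the effective sample size
#' `(sum w)^2 / sum(w^2)`.
#'
#' @param dwells A [segment_dwells()] table.
#' @return Data frame per state: `n_dwells`, `E_mean`, `E_sd`, `E_se`,
#'   `S_mean`, `S_sd`, `S_se` (NA when a state has no defined dwells).
#' @export
weighted_dwell_stats <- function(dwells) {
  wstats <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_))
    x <- x[ok]; w <- w[ok]
    m <- sum(w * x) / sum(w)
    v <- sum(w * (x - m)^2) / sum(w)
    neff <- sum(w)^2 / sum(w^2)
    c(m, sqrt(v), sqrt(v / neff))
  }
  sts <- sort(unique(dwells$state))
  rows <- lapply(sts, function(s) {
    d <- dwells[dwells$state == s, ]
    e <- wstats(d$E_raw, d$n_DD + d$n_DA)
    sv <- wstats(d$S_raw, d$n_photons)
    data.frame(state = s, n_dwells = nrow(d),
               E_mean = e[1], E_sd = e[2], E_se = e[3],
               S_mean = sv[1], S_sd = sv[2], S_se = sv[3])
  })
  do.call(rbind, rows)
}

#' Transition rate constants in s^-1
#'
#' Converts the per-tick transition matrix to rate constants:
#' `k_ij = A_ij / clock_period` for `i != j` (diagonal set to minus the row
#' sum, so columns of the returned generator-style matrix behave as
#' expected). Valid when per-tick off-diagonal probabilities are small; a
#' warning is issued when any exceeds 0.01 per tick. A matrix-logarithm
#' based alternative (`method = "matrix-log"`, exact for any tick
#' probability) is available when the pracma package is installed.
#'
#' @param model A `state_model` (or `h2mm` fit).
#' @param clock_period Seconds per tick (taken from a fit if omitted).
#' @param method `"linear"` (default) or `"matrix-log"`.
#' @return q x q matrix of rates in s^-1 (off-diagonal; diagonal is minus
#'   the row sum).
#' @export
rates_per_second <- function(model, clock_period = NULL,
                             method = c("linear", "matrix-log")) {
  method <- match.arg(method)
  if (inherits(model, "h2mm")) {
    if (is.null(clock_period)) clock_period <- model$clock_period
    model <- model$model
  }
  stopifnot(inherits(model, "state_model"), is.numeric(clock_period))
  A <- model$trans
  off <- A; diag(off) <- 0
  if (any(off > 0.01))
    warning("per-tick transition probabilities exceed 0.01; the linear ",
            "rate conversion k = A/clock is inaccurate - consider ",
            "method = 'matrix-log'")
  if (method == "linear") {
    k <- A / clock_period
    diag(k) <- 0
    diag(k) <- -rowSums(k)
  } else {
    if (!requireNamespace("pracma", quietly = TRUE))
      stop("method = 'matrix-log' requires the pracma package")
    k <- pracma::logm(A) / clock_period
  }
  k
}

#' Parameter error by variance of subsets
#'
#' Splits the bursts into `n_subsets` groups (round-robin after a seeded
#' shuffle), re-optimizes each subset starting from the full-data model, and
#' reports the standard deviation of every parameter (per-state `E_raw`,
#' `S_raw`, and the off-diagonal per-second rates) across the subsets.
#' Subset states are matched to the full-data model by greedy
#' nearest-neighbour assignment in (E, S), ties broken by lower state
#' index. A subset whose optimization fails is dropped and reported.
#'
#' @param data The full [obs_set].
#' @param fit The full-data `h2mm` fit.
#' @param n_subsets Number of subsets (>= 2; default 10).
#' @param seed Shuffle seed.
#' @param max_iter,tol Passed to the subset re-optimizations.
#' @return List with `E_sd`, `S_sd` (length q), `rate_sd` (q x q), the
#'   per-subset parameter arrays, and `n_failed`.
#' @export
variance_of_subsets <- function(data, fit, n_subsets = 10L, seed = 1L,
                                max_iter = 1000L, tol = 1e-3) {
  stopifnot(inherits(data, "obs_set"), inherits(fit, "h2mm"))
  if (n_subsets < 2) stop("n_subsets must be at least 2 (variance undefined)")
  nb <- length(data$lens)
  set.seed(seed %% .Machine$integer.max)
  ord <- sample.int(nb)
  groups <- split(ord, rep_len(seq_len(n_subsets), nb))
  ref <- state_es(fit$model)
  q <- fit$q
  E_arr <- S_arr <- matrix(NA_real_, n_subsets, q)
  rate_arr <- array(NA_real_, c(n_subsets, q, q))
  failed <- 0L
  for (g in seq_along(groups)) {
    sub <- obs_subset(data, sort(groups[[g]]))
    sf <- tryCatch(h2mm(sub, q, init = fit$model, max_iter = max_iter,
                        tol = tol),
                   error = function(e) NULL)
    if (is.null(sf)) { failed <- failed + 1L; next }
    es <- state_es(sf$model)
    perm <- greedy_match(es, ref)
    E_arr[g, ] <- es$E_raw[perm]
    S_arr[g, ] <- es$S_raw[perm]
    k <- rates_per_second(sf$model, data$clock_period)
    rate_arr[g, , ] <- k[perm, perm]
  }
  if (failed) warning(failed, " subset optimization(s) failed and were dropped")
  sd0 <- function(x) sd(x, na.rm = TRUE)
  list(E_sd = apply(E_arr, 2, sd0), S_sd = apply(S_arr, 2, sd0),
       rate_sd = apply(rate_arr, c(2, 3), sd0),
       E_subsets = E_arr, S_subsets = S_arr, rate_subsets = rate_arr,
       n_failed = failed)
}

# greedy nearest-neighbour state matching in (E, S); perm[k] = subset state
# matched to reference state k (1-based). Ties broken by lower index.
greedy_match <- function(es, ref) {
  q <- length(ref$E_raw)
  dmat <- outer(seq_len(q), seq_len(q), Vectorize(function(i, j) {
    dE <- ref$E_raw[i] - es$E_raw[j]
    dS <- ref$S_raw[i] - es$S_raw[j]
    dS[is.na(dS)] <- 0
    sqrt(dE^2 + dS^2)
  }))
  perm <- integer(q)
  for (step in seq_len(q)) {
    # smallest remaining distance; ties break toward the lower state index
    # because which() scans in column-major (hence lower-index-first) order
    idx <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    dmat[idx[1], ] <- Inf
    dmat[, idx[2]] <- Inf
  }
  perm
}

#' Export the dwell table as CSV
#'
#' Columns: `burst_id, state, n_DD, n_DA, n_AA, duration_ticks, E_raw,
#' S_raw, position`.
#' @param dwells A dwell table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dwells_csv <- function(dwells, path) {
  cols <- c("burst_id", "state", "n_DD", "n_DA", "n_AA", "duration_ticks",
            "E_raw", "S_raw", "position")
  write.csv(as.data.frame(dwells)[, cols], path, row.names = FALSE)
  invisible(path)
}
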