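#' Raw FRET efficiency and stoichiometry from stream counts
#'
#' `E_raw = n_DA / (n_DD + n_DA)` and
#' `S_raw = (n_DD + n_DA) / (n_DD + n_DA + n_AA)`: the raw (uncorrected)
#' ratios used throughout the package. No gamma, leakage or direct-excitation
#' corrections are applied. Ratios whose denominator is zero are returned as
#' `NA` rather than an error, so callers can carry an "undefined" flag.
#'
#' @param n_dd,n_da,n_aa Photon counts per stream (vectorized).
#' @return A list with numeric vectors `E_raw` and `S_raw`.
#' @examples
#' burst_ratios(30, 10, 40)  # E_raw 0.25, S_raw 0.5
#' @export
burst_ratios <- function(n_dd, n_da, n_aa) {
  den_e <- n_dd + n_da
  den_s <- n_dd + n_da + n_aa
  list(E_raw = ifelse(den_e > 0, n_da / den_e, NA_real_),
       S_raw = ifelse(den_s > 0, den_e / den_s, NA_real_))
}

# Build a burst_set from half-open photon index ranges (0-based, [i_start,
# i_stop)) into `series`. All interval conventions in the package are
# half-open with 0-based photon indices.
make_burst_set <- function(series, i_start, i_stop) {
  stopifnot(length(i_start) == length(i_stop))
  n <- length(i_start)
  cnt <- matrix(0L, n, 3L)
  start_tick <- stop_tick <- numeric(n)
  for (b in seq_len(n)) {
    idx <- (i_start[b] + 1L):i_stop[b]
    cnt[b, ] <- tabulate(series$stream_index[idx] + 1L, nbins = 3L)
    start_tick[b] <- series$timestamps[i_start[b] + 1L]
    stop_tick[b] <- series$timestamps[i_stop[b]] + 1
  }
  rat <- burst_ratios(cnt[, 1], cnt[, 2], cnt[, 3])
  structure(
    data.frame(burst_id = seq_len(n) - 1L, i_start = i_start, i_stop = i_stop,
               start_tick = start_tick, stop_tick = stop_tick,
               n_DD = cnt[, 1], n_DA = cnt[, 2], n_AA = cnt[, 3],
               E_raw = rat$E_raw, S_raw = rat$S_raw),
    clock_period = series$clock_period,
    class = c("burst_set", "data.frame"))
}

#' Build a burst set from tick windows
#'
#' Converts half-open time windows `[start_tick, stop_tick)` into photon
#' ranges over `series` (windows left empty of photons are dropped).
#' Useful for carrying burst windows across the acceptor-photon shift,
#' which reorders photons but keeps each inside its window, and for the
#' simulator's ground-truth windows.
#'
#' @param series A `photon_series`.
#' @param start_tick,stop_tick Numeric vectors of half-open tick windows.
#' @return A `burst_set`.
#' @export
bursts_from_ticks <- function(series, start_tick, stop_tick) {
  stopifnot(inherits(series, "photon_series"),
            length(start_tick) == length(stop_tick))
  i_start <- findInterval(start_tick - 0.5, series$timestamps)
  i_stop <- findInterval(stop_tick - 0.5, series$timestamps)
  keep <- i_stop > i_start
  make_burst_set(series, i_start[keep], i_stop[keep])
}

#' Sliding-window burst search
#'
#' A photon starts a "hot" window when the instantaneous rate of the window
#' of `m` consecutive photons beginning at it,
#' `m / (t[i+m-1] - t[i])`, is at least `F` times the local background rate.
#' A photon belongs to a burst when *any* hot window covers it; maximal runs
#' of covered photons become bursts (disjoint and ordered by construction).
#' The defaults m = 10, F = 6 are the standard sliding-window criterion for
#' diffusing-molecule burst detection. Ties at exactly `F x` background count
#' as hot.
#'
#' @param series A `photon_series`.
#' @param background A [estimate_background()] result computed on the same
#'   photon set (its `rate_all` column provides the local rate).
#' @param m Window size in photons (>= 2).
#' @param F Rate multiplier over background.
#' @return A `burst_set` data frame (possibly with zero rows): columns
#'   `burst_id`, `i_start`/`i_stop` (half-open 0-based photon range),
#'   `start_tick`/`stop_tick` (half-open), per-stream counts `n_DD`, `n_DA`,
#'   `n_AA`, and `E_raw`/`S_raw`.
#' @export
sliding_burst_search <- function(series, background, m = 10L, F = 6) {
  stopifnot(inherits(series, "photon_series"),
            inherits(background, "background_estimate"))
  if (m < 2) stop("window size m must be at least 2 photons")
  n <- length(series$timestamps)
  if (n < m) return(make_burst_set(series, integer(0), integer(0)))
  ts <- series$timestamps
  clock <- series$clock_period
  span <- (ts[m:n] - ts[1:(n - m + 1L)]) * clock       # seconds
  rate <- m / span                                      # Inf when span == 0
  bg <- local_bg_rate(background, ts[1:(n - m + 1L)] * clock)
  hot <- rate >= F * bg
  # photon j covered iff any hot window start i in [j-m+1, j]
  covered <- rep(FALSE, n)
  hs <- which(hot)
  if (length(hs)) {
    delta <- integer(n + 1L)
    delta[hs] <- delta[hs] + 1L
    delta[pmin(hs + m, n + 1L)] <- delta[pmin(hs + m, n + 1L)] - 1L
    covered <- cumsum(delta[seq_len(n)]) > 0L
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  make_burst_set(series, starts[keep] - 1L, ends[keep])
}

#' Dual-channel burst search (DCBS)
#'
#' Runs the sliding-window search independently on the donor-excitation
#' photon subset (streams 0 and 1) and on the acceptor-excitation subset
#' (stream 2), then keeps the time-intersections of overlapping burst pairs,
#' re-expressed as photon ranges over the full series. Requiring coincident
#' donor- and acceptor-excitation bursts removes donor-only and
#' acceptor-only single-dye species.
#'
#' @inheritParams sliding_burst_search
#' @param background_donor,background_acceptor Optional
#'   `background_estimate`s for the two photon subsets; estimated from the
#'   subsets when `NULL`.
#' @param slice_seconds,threshold_init Passed to [estimate_background()]
#'   when backgrounds are estimated here.
#' @return A `burst_set` over the full series.
#' @export
dcbs_search <- function(series, m = 10L, F = 6,
                        background_donor = NULL, background_acceptor = NULL,
                        slice_seconds = 30, threshold_init = 5e-4) {
  stopifnot(inherits(series, "photon_series"))
  if (!isTRUE(attr(series, "streams_assigned")) || n_streams(series) < 3L)
    stop("DCBS requires assigned streams with an acceptor-excitation stream",
         " (r = 3)")
  subset_series <- function(keep) {
    out <- photon_series(series$timestamps[keep], series$stream_index[keep],
                         series$clock_period, series$acquisition_duration,
                         streams_assigned = TRUE)
    out
  }
  don <- subset_series(series$stream_index %in% c(0L, 1L))
  acc <- subset_series(series$stream_index == 2L)
  if (!length(don$timestamps) || !length(acc$timestamps))
    return(make_burst_set(series, integer(0), integer(0)))
  if (is.null(background_donor))
    background_donor <- estimate_background(don, slice_seconds, threshold_init)
  if (is.null(background_acceptor))
    background_acceptor <- estimate_background(acc, slice_seconds,
                                               threshold_init)
  bd <- sliding_burst_search(don, background_donor, m, F)
  ba <- sliding_burst_search(acc, background_acceptor, m, F)
  if (!nrow(bd) || !nrow(ba))
    return(make_burst_set(series, integer(0), integer(0)))
  # intersect the two sorted interval lists
  st <- numeric(0); en <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(bd) && j <= nrow(ba)) {
    lo <- max(bd$start_tick[i], ba$start_tick[j])
    hi <- min(bd$stop_tick[i], ba$stop_tick[j])
    if (lo < hi) { st <- c(st, lo); en <- c(en, hi) }
    if (bd$stop_tick[i] < ba$stop_tick[j]) i <- i + 1L else j <- j + 1L
  }
  # photon ranges over the full series
  i_start <- findInterval(st - 0.5, series$timestamps)        # first ts >= lo
  i_stop <- findInterval(en - 0.5, series$timestamps)         # last ts < hi
  keep <- i_stop > i_start
  make_burst_set(series, i_start[keep], i_stop[keep])
}

#' Select bursts by total photon count
#'
#' Keeps bursts with at least `min_photons` photons in total between all
#' streams (default 30), preserving order.
#'
#' @param bursts A `burst_set`.
#' @param min_photons Minimum total photons (inclusive).
#' @return The filtered `burst_set`.
#' @export
select_bursts <- function(bursts, min_photons = 30L) {
  stopifnot(inherits(bursts, "burst_set"))
  tot <- bursts$n_DD + bursts$n_DA + bursts$n_AA
  out <- bursts[tot >= min_photons, , drop = FALSE]
  attr(out, "clock_period") <- attr(bursts, "clock_period")
  class(out) <- class(bursts)
  out
}

#' Export a burst table as CSV
#'
#' Columns: `burst_id, start_tick, stop_tick, n_DD, n_DA, n_AA, E_raw,
#' S_raw`.
#' @param bursts A `burst_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bursts_csv <- function(bursts, path) {
  cols <- c("burst_id", "start_tick", "stop_tick", "n_DD", "n_DA", "n_AA",
            "E_raw", "S_raw")
  write.csv(as.data.frame(bursts)[, cols], path, row.names = FALSE)
  invisible(path)
}
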