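#' Observation set: photon sequences ready for the HMM
#'
#' Converts bursts of a `photon_series` into the flat form consumed by the
#' HMM engine: per burst, the photon stream indices and the integer
#' inter-photon gaps (ticks between consecutive photons; the first photon of
#' each burst carries no gap). Optionally restricts to a subset of streams —
#' `streams = 0:1` yields the single-parameter (donor-excitation only,
#' r = 2) view of the same data, dropping acceptor-excitation photons and
#' recomputing the gaps.
#'
#' @param series A `photon_series` with assigned streams.
#' @param bursts A `burst_set` into `series` (or `NULL` to treat the whole
#'   series as one burst).
#' @param streams Streams to keep (default: all present). Bursts left empty
#'   by the restriction are dropped.
#' @return An object of class `obs_set`: list with `streams` (0-based,
#'   flattened), `gaps` (ticks, flattened, 0 for each burst's first photon),
#'   `lens` (photons per burst), `r`, `n` (total photons) and
#'   `clock_period`.
#' @export
as_obs_set <- function(series, bursts = NULL, streams = NULL) {
  stopifnot(inherits(series, "photon_series"))
  if (!isTRUE(attr(series, "streams_assigned")))
    stop("streams must be assigned before building an observation set")
  if (is.null(bursts)) {
    i_start <- 0L
    i_stop <- length(series$timestamps)
  } else {
    i_start <- bursts$i_start
    i_stop <- bursts$i_stop
  }
  keep_stream <- if (is.null(streams)) sort(unique(series$stream_index))
                 else as.integer(streams)
  if (!all(diff(keep_stream) == 1L) || keep_stream[1] != 0L)
    stop("streams must be a contiguous 0-based set, e.g. 0:1 or 0:2")
  str_l <- list(); gap_l <- list(); lens <- integer(0)
  for (b in seq_along(i_start)) {
    idx <- (i_start[b] + 1L):i_stop[b]
    s <- series$stream_index[idx]
    t <- series$timestamps[idx]
    sel <- s %in% keep_stream
    if (!any(sel)) next
    s <- s[sel]; t <- t[sel]
    str_l[[length(str_l) + 1L]] <- s
    gap_l[[length(gap_l) + 1L]] <- c(0, diff(t))
    lens <- c(lens, length(s))
  }
  structure(list(streams = as.integer(unlist(str_l)),
                 gaps = as.numeric(unlist(gap_l)),
                 lens = lens, r = length(keep_stream),
                 n = sum(lens), clock_period = series$clock_period),
            class = "obs_set")
}

#' Assemble an observation set directly from per-burst vectors
#'
#' Lower-level companion to [as_obs_set()] for synthetic or hand-built
#' sequences: takes lists of per-burst stream-index and gap vectors.
#'
#' @param streams List of integer vectors (0-based stream per photon).
#' @param gaps List of numeric vectors of the same lengths; element i is the
#'   tick gap to the previous photon (first element ignored/0).
#' @param r Number of streams.
#' @param clock_period Seconds per tick.
#' @return An `obs_set`.
#' @export
obs_set <- function(streams, gaps, r, clock_period = 1) {
  stopifnot(is.list(streams), is.list(gaps),
            length(streams) == length(gaps))
  lens <- vapply(streams, length, 1L)
  stopifnot(all(lens == vapply(gaps, length, 1L)), all(lens >= 1L))
  st <- as.integer(unlist(streams))
  if (any(st < 0L | st >= r)) stop("stream indices must lie in [0, r)")
  gp <- as.numeric(unlist(gaps))
  if (any(gp < 0) || any(gp != floor(gp)))
    stop("gaps must be non-negative integers (ticks)")
  structure(list(streams = st, gaps = gp, lens = lens, r = as.integer(r),
                 n = sum(lens), clock_period = clock_period),
            class = "obs_set")
}

#' @export
print.obs_set <- function(x, ...) {
  cat("<obs_set> ", length(x$lens), " bursts, ", x$n, " photons, r = ",
      x$r, " streams\n", sep = "")
  invisible(x)
}

# subset an obs_set by burst index (1-based)
obs_subset <- function(x, which_bursts) {
  stopifnot(inherits(x, "obs_set"))
  ends <- cumsum(x$lens)
  starts <- ends - x$lens + 1L
  idx <- unlist(lapply(which_bursts, function(b) starts[b]:ends[b]))
  structure(list(streams = x$streams[idx], gaps = x$gaps[idx],
                 lens = x$lens[which_bursts], r = x$r,
                 n = sum(x$lens[which_bursts]),
                 clock_period = x$clock_period),
            class = "obs_set")
}

# split flattened per-photon vector into per-burst list
split_by_burst <- function(values, lens) {
  split(values, rep(seq_along(lens), lens))
}
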