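#' Photon series
#'
#' Container for a photon-by-photon record: integer arrival times in clock
#' ticks and a per-photon stream (or provisional detector) index. This is the
#' common currency of the package: burst search, the HMM and the simulator
#' all operate on `photon_series` objects.
#'
#' Stream indices follow the ALEX convention used throughout: 0 = donor
#' excitation, donor emission (DD); 1 = donor excitation, acceptor emission
#' (DA); 2 = acceptor excitation, acceptor emission (AA). Until
#' [assign_streams()] has been applied, `stream_index` may hold raw detector
#' ids instead (`streams_assigned` attribute is `FALSE`).
#'
#' Timestamps are kept in native integer ticks (stored as doubles, which are
#' exact up to 2^53); seconds are always derived via `clock_period`, never
#' stored, so the HMM works with exact integer gaps.
#'
#' @param timestamps Non-decreasing photon arrival times in clock ticks.
#' @param stream_index Integer per photon: stream (0/1/2) or detector id.
#' @param clock_period Seconds per clock tick (e.g. 50e-9 for 20 MHz nsALEX,
#'   12.5e-9 for usALEX).
#' @param acquisition_duration Total acquisition length in seconds. Defaults
#'   to the last timestamp.
#' @param nanotime Optional integer TCSPC bin per photon (nsALEX only).
#' @param streams_assigned Whether `stream_index` already holds DD/DA/AA
#'   stream labels rather than detector ids.
#' @return An object of class `photon_series`.
#' @seealso [assign_streams()], [shift_acceptor_photons()],
#'   [read_photon_table()], [read_photon_hdf5()]
#' @export
photon_series <- function(timestamps, stream_index, clock_period,
                          acquisition_duration = NULL, nanotime = NULL,
                          streams_assigned = TRUE) {
  timestamps <- as.numeric(timestamps)
  stream_index <- as.integer(stream_index)
  if (length(timestamps) != length(stream_index))
    stop("timestamps and stream_index must have equal length")
  if (length(timestamps) && any(timestamps < 0))
    stop("timestamps must be non-negative")
  bad <- which(diff(timestamps) < 0)
  if (length(bad))
    stop("timestamps must be non-decreasing; first violation at index ",
         bad[1] + 1L)
  if (!is.numeric(clock_period) || length(clock_period) != 1L ||
      clock_period <= 0)
    stop("clock_period must be a single positive number (seconds per tick)")
  if (length(stream_index) && any(stream_index < 0))
    stop("stream_index must be non-negative")
  if (!is.null(nanotime)) {
    nanotime <- as.integer(nanotime)
    if (length(nanotime) != length(timestamps))
      stop("nanotime must match timestamps in length")
  }
  if (is.null(acquisition_duration))
    acquisition_duration <- if (length(timestamps))
      timestamps[length(timestamps)] * clock_period else 0
  structure(
    list(timestamps = timestamps, stream_index = stream_index,
         clock_period = clock_period,
         acquisition_duration = acquisition_duration, nanotime = nanotime),
    streams_assigned = isTRUE(streams_assigned),
    dropped_photons = 0L,
    class = "photon_series")
}

#' @export
print.photon_series <- function(x, ...) {
  cat("<photon_series> ", length(x$timestamps), " photons, clock ",
      format(x$clock_period * 1e9), " ns, duration ",
      format(round(x$acquisition_duration, 3)), " s\n", sep = "")
  if (isTRUE(attr(x, "streams_assigned"))) {
    tab <- tabulate(x$stream_index + 1L, nbins = 3L)
    cat("  streams DD/DA/AA: ", paste(tab, collapse = "/"), sep = "")
    if (attr(x, "dropped_photons") > 0L)
      cat("  (", attr(x, "dropped_photons"), " dropped)", sep = "")
    cat("\n")
  } else {
    cat("  detector ids (streams not yet assigned): ",
        paste(sort(unique(x$stream_index)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.photon_series <- function(x) length(x$timestamps)

#' Number of photon streams in a series
#' @param series A `photon_series` with assigned streams.
#' @return Integer number of streams (2 or 3).
#' @export
n_streams <- function(series) {
  if (!length(series$stream_index)) return(0L)
  max(series$stream_index) + 1L
}

#' Alternation scheme
#'
#' Describes how excitation alternation separates donor- from
#' acceptor-excitation photons. For usALEX the laser is modulated in time, so
#' photons are gated by their position within the alternation period; for
#' nsALEX the lasers are interleaved at the pulse level and photons are gated
#' by their TCSPC nanotime.
#'
#' All windows and ranges are half-open `[from, to)` and expressed in ticks
#' (usALEX) or TCSPC bins (nsALEX).
#'
#' @param mode `"usALEX"` or `"nsALEX"`.
#' @param alternation_period usALEX: alternation period in clock ticks
#'   (e.g. 4000 ticks of 12.5 ns = 50 us, a 20 kHz alternation rate).
#' @param donor_window,acceptor_window usALEX: half-open tick ranges within
#'   the period, given as length-2 vectors `c(from, to)`.
#' @param donor_nanotime_range,acceptor_nanotime_range nsALEX: half-open
#'   TCSPC-bin ranges.
#' @return An object of class `alternation_scheme`.
#' @export
alternation_scheme <- function(mode = c("usALEX", "nsALEX"),
                               alternation_period = NULL,
                               donor_window = NULL, acceptor_window = NULL,
                               donor_nanotime_range = NULL,
                               acceptor_nanotime_range = NULL) {
  mode <- match.arg(mode)
  chk_range <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || x[2] <= x[1])
      stop(nm, " must be a non-empty half-open range c(from, to)")
    x
  }
  if (mode == "usALEX") {
    if (is.null(alternation_period) || alternation_period <= 0)
      stop("usALEX requires a positive alternation_period (ticks)")
    donor_window <- chk_range(donor_window, "donor_window")
    acceptor_window <- chk_range(acceptor_window, "acceptor_window")
    if (max(donor_window[2], acceptor_window[2]) > alternation_period ||
        min(donor_window[1], acceptor_window[1]) < 0)
      stop("windows must lie within [0, alternation_period)")
    if (donor_window[1] < acceptor_window[2] &&
        acceptor_window[1] < donor_window[2])
      stop("donor and acceptor windows must be disjoint")
  } else {
    donor_nanotime_range <- chk_range(donor_nanotime_range,
                                      "donor_nanotime_range")
    acceptor_nanotime_range <- chk_range(acceptor_nanotime_range,
                                         "acceptor_nanotime_range")
    if (donor_nanotime_range[1] < acceptor_nanotime_range[2] &&
        acceptor_nanotime_range[1] < donor_nanotime_range[2])
      stop("nanotime ranges must be disjoint")
  }
  structure(list(mode = mode, alternation_period = alternation_period,
                 donor_window = donor_window,
                 acceptor_window = acceptor_window,
                 donor_nanotime_range = donor_nanotime_range,
                 acceptor_nanotime_range = acceptor_nanotime_range),
            class = "alternation_scheme")
}

#' @export
print.alternation_scheme <- function(x, ...) {
  cat("<alternation_scheme> mode:", x$mode, "\n")
  if (x$mode == "usALEX")
    cat("  period", x$alternation_period, "ticks; donor window [",
        x$donor_window[1], ",", x$donor_window[2], "), acceptor window [",
        x$acceptor_window[1], ",", x$acceptor_window[2], ")\n")
  else
    cat("  donor nanotimes [", x$donor_nanotime_range[1], ",",
        x$donor_nanotime_range[2], "), acceptor nanotimes [",
        x$acceptor_nanotime_range[1], ",", x$acceptor_nanotime_range[2],
        ")\n")
  invisible(x)
}

#' Assign DD/DA/AA photon streams
#'
#' Labels every photon with its stream index: 0 (DD, donor excitation and
#' donor emission), 1 (DA, donor excitation and acceptor emission) or
#' 2 (AA, acceptor excitation and acceptor emission). The excitation source
#' is inferred from the alternation scheme (period position for usALEX,
#' nanotime gate for nsALEX); the emission channel comes from
#' `detector_map`. Donor-emission photons detected under acceptor excitation
#' carry no FRET information and are dropped, as are photons falling outside
#' every excitation window (dead-time guard bands); the number of dropped
#' photons is recorded in the `dropped_photons` attribute.
#'
#' @param series A `photon_series` whose `stream_index` holds detector ids.
#' @param scheme An [alternation_scheme()].
#' @param detector_map Named character vector mapping detector id to emission
#'   channel, e.g. `c("0" = "donor", "1" = "acceptor")`.
#' @return A `photon_series` with `stream_index` in \{0, 1, 2\} and
#'   `streams_assigned = TRUE`.
#' @export
assign_streams <- function(series, scheme, detector_map) {
  stopifnot(inherits(series, "photon_series"),
            inherits(scheme, "alternation_scheme"))
  if (!all(detector_map %in% c("donor", "acceptor")))
    stop("detector_map values must be 'donor' or 'acceptor'")
  emission <- unname(detector_map[as.character(series$stream_index)])
  if (anyNA(emission))
    stop("detector ids without a detector_map entry: ",
         paste(setdiff(unique(series$stream_index), names(detector_map)),
               collapse = ", "))
  if (scheme$mode == "nsALEX") {
    if (is.null(series$nanotime))
      stop("nsALEX stream assignment requires per-photon nanotimes")
    pos <- series$nanotime
    in_don <- pos >= scheme$donor_nanotime_range[1] &
      pos < scheme$donor_nanotime_range[2]
    in_acc <- pos >= scheme$acceptor_nanotime_range[1] &
      pos < scheme$acceptor_nanotime_range[2]
  } else {
    pos <- series$timestamps %% scheme$alternation_period
    in_don <- pos >= scheme$donor_window[1] & pos < scheme$donor_window[2]
    in_acc <- pos >= scheme$acceptor_window[1] & pos < scheme$acceptor_window[2]
  }
  stream <- rep(NA_integer_, length(series$timestamps))
  stream[in_don & emission == "donor"] <- 0L
  stream[in_don & emission == "acceptor"] <- 1L
  stream[in_acc & emission == "acceptor"] <- 2L
  keep <- !is.na(stream)
  out <- photon_series(series$timestamps[keep], stream[keep],
                       series$clock_period, series$acquisition_duration,
                       nanotime = if (is.null(series$nanotime)) NULL
                                  else series$nanotime[keep],
                       streams_assigned = TRUE)
  attr(out, "dropped_photons") <- sum(!keep)
  out
}

#' Shift acceptor-excitation photon times into the donor window
#'
#' In usALEX the donor- and acceptor-excitation photons of one alternation
#' period are separated in time by construction, so a photon-by-photon HMM
#' run on the raw clock times locks onto the laser alternation instead of
#' molecular dynamics (all states drift to stoichiometry 0 or 1 and the
#' fitted rates approach the alternation rate). The cure is to remap each
#' AA photon so that its fractional position inside the acceptor window
#' becomes the same fractional position inside the donor window of the same
#' alternation period. DD/DA photons are untouched; the result is re-sorted
#' stably. The operation is idempotent: after the first remap no AA photon
#' remains inside an acceptor window.
#'
#' @param series A `photon_series` with assigned streams.
#' @param scheme A usALEX [alternation_scheme()].
#' @return The shifted, stably re-sorted `photon_series`.
#' @export
shift_acceptor_photons <- function(series, scheme) {
  stopifnot(inherits(series, "photon_series"),
            inherits(scheme, "alternation_scheme"))
  if (scheme$mode != "usALEX")
    stop("shift_acceptor_photons applies to usALEX data only")
  if (!isTRUE(attr(series, "streams_assigned")))
    stop("streams must be assigned before shifting (see assign_streams)")
  ts <- series$timestamps
  per <- scheme$alternation_period
  pos <- ts %% per
  acc <- series$stream_index == 2L &
    pos >= scheme$acceptor_window[1] & pos < scheme$acceptor_window[2]
  don_len <- diff(scheme$donor_window)
  acc_len <- diff(scheme$acceptor_window)
  # fractional position in the acceptor window -> same fraction of the donor
  # window; exact integer arithmetic when the windows have equal length
  new_pos <- scheme$donor_window[1] +
    floor((pos[acc] - scheme$acceptor_window[1]) * don_len / acc_len)
  ts[acc] <- ts[acc] - pos[acc] + new_pos
  ord <- order(ts, method = "radix")  # stable: ties keep input order
  out <- photon_series(ts[ord], series$stream_index[ord],
                       series$clock_period, series$acquisition_duration,
                       nanotime = if (is.null(series$nanotime)) NULL
                                  else series$nanotime[ord],
                       streams_assigned = TRUE)
  attr(out, "dropped_photons") <- attr(series, "dropped_photons")
  out
}

# duplicate timestamps across detectors are legal (independent channels);
# within one detector they usually indicate a timing artifact
warn_same_detector_duplicates <- function(ts, det) {
  if (anyDuplicated(paste(ts, det))) {
    n <- sum(duplicated(paste(ts, det)))
    warning(n, " duplicate timestamp(s) within a single detector channel",
            call. = FALSE)
  }
  invisible(NULL)
}

#' Read / write the plain-text photon table
#'
#' Whitespace-delimited columns `timestamp_ticks stream_index` (plus an
#' optional `nanotime` column), preceded by `#`-comment header lines carrying
#' `clock_period` and optionally `acquisition_duration`. The format is
#' deliberately simple enough to write by hand; gzip-compressed files are
#' read and written transparently when the path ends in `.gz`.
#'
#' @param path File path (plain or `.gz`).
#' @return `read_photon_table` returns a `photon_series`;
#'   `write_photon_table` returns `path` invisibly.
#' @export
read_photon_table <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    hit <- grep(paste0("^#\\s*", name), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    as.numeric(sub(paste0("^#\\s*", name, "[= ]+"), "", hit[1]))
  }
  clock <- get_field("clock_period")
  if (is.null(clock) || is.na(clock))
    stop("photon table is missing a '# clock_period' header line")
  dat <- read.table(text = lines[!grepl("^#|^\\s*$", lines)])
  photon_series(dat[[1]], dat[[2]], clock,
                acquisition_duration = get_field("acquisition_duration"),
                nanotime = if (ncol(dat) >= 3) dat[[3]] else NULL,
                streams_assigned = TRUE)
}

#' @param series A `photon_series`.
#' @rdname read_photon_table
#' @export
write_photon_table <- function(series, path) {
  stopifnot(inherits(series, "photon_series"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# clock_period %.17g", series$clock_period),
               sprintf("# acquisition_duration %.17g",
                       series$acquisition_duration)), con)
  dat <- data.frame(format(series$timestamps, scientific = FALSE,
                           trim = TRUE),
                    series$stream_index)
  if (!is.null(series$nanotime)) dat[[3]] <- series$nanotime
  write.table(dat, con, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
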