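#' Read a photon-HDF5 file
#'
#' Reads the mandatory photon-HDF5 groups: `/photon_data/timestamps`,
#' `/photon_data/detectors` and
#' `/photon_data/timestamps_specs/timestamps_unit`. Timestamps are returned
#' as integer clock ticks at the file's declared unit. The detector to
#' stream mapping is *not* applied here: `stream_index` provisionally holds
#' the raw detector ids (see [assign_streams()]). If the writer stored
#' alternation metadata (under `/setup`), it is returned alongside as an
#' [alternation_scheme()].
#'
#' Only the minimal photon-data subset of the schema is covered; sample and
#' identity metadata groups are ignored.
#'
#' @param path Path to a photon-HDF5 file.
#' @return A list with elements `series` (a `photon_series`) and `scheme`
#'   (an `alternation_scheme` or `NULL`).
#' @export
read_photon_hdf5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading photon-HDF5 requires the rhdf5 package")
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  full <- file.path(contents$group, contents$name)
  full <- sub("^//", "/", full)
  need <- c("/photon_data/timestamps", "/photon_data/detectors",
            "/photon_data/timestamps_specs/timestamps_unit")
  missing <- setdiff(need, full)
  if (length(missing))
    stop("not a photon-HDF5 file: missing mandatory group(s) ",
         paste(missing, collapse = ", "))
  ts <- as.numeric(rhdf5::h5read(path, "/photon_data/timestamps",
                                 bit64conversion = "double"))
  det <- as.integer(rhdf5::h5read(path, "/photon_data/detectors"))
  unit <- as.numeric(rhdf5::h5read(
    path, "/photon_data/timestamps_specs/timestamps_unit"))
  nano <- if ("/photon_data/nanotimes" %in% full)
    as.integer(rhdf5::h5read(path, "/photon_data/nanotimes")) else NULL
  scheme <- NULL
  if ("/setup/alternation_mode" %in% full) {
    mode <- as.character(rhdf5::h5read(path, "/setup/alternation_mode"))
    rd <- function(nm) if (file.path("/setup", nm) %in% full)
      as.numeric(rhdf5::h5read(path, file.path("/setup", nm))) else NULL
    scheme <- alternation_scheme(
      mode = mode,
      alternation_period = rd("alternation_period"),
      donor_window = rd("donor_window"),
      acceptor_window = rd("acceptor_window"),
      donor_nanotime_range = rd("donor_nanotime_range"),
      acceptor_nanotime_range = rd("acceptor_nanotime_range"))
  }
  series <- photon_series(ts, det, unit, nanotime = nano,
                          streams_assigned = FALSE)
  warn_same_detector_duplicates(ts, det)
  list(series = series, scheme = scheme)
}

#' Write the minimal photon-HDF5 subset
#'
#' Writes `/photon_data/timestamps`, `/photon_data/detectors`,
#' `/photon_data/timestamps_specs/timestamps_unit` and (optionally)
#' `/photon_data/nanotimes` plus the alternation metadata under `/setup`.
#' Round-trips through [read_photon_hdf5()] are the identity on timestamps,
#' detector ids and clock period.
#'
#' @param series A `photon_series` (its `stream_index` is written to the
#'   detectors dataset).
#' @param path Output path; overwritten if it exists.
#' @param scheme Optional [alternation_scheme()] stored under `/setup`.
#' @return `path`, invisibly.
#' @export
write_photon_hdf5 <- function(series, path, scheme = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("writing photon-HDF5 requires the rhdf5 package")
  stopifnot(inherits(series, "photon_series"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "photon_data")
  rhdf5::h5createGroup(path, "photon_data/timestamps_specs")
  rhdf5::h5write(series$timestamps, path, "photon_data/timestamps")
  rhdf5::h5write(series$stream_index, path, "photon_data/detectors")
  rhdf5::h5write(series$clock_period, path,
                 "photon_data/timestamps_specs/timestamps_unit")
  if (!is.null(series$nanotime))
    rhdf5::h5write(series$nanotime, path, "photon_data/nanotimes")
  if (!is.null(scheme)) {
    rhdf5::h5createGroup(path, "setup")
    rhdf5::h5write(scheme$mode, path, "setup/alternation_mode")
    wr <- function(x, nm) if (!is.null(x))
      rhdf5::h5write(as.numeric(x), path, file.path("setup", nm))
    wr(scheme$alternation_period, "alternation_period")
    wr(scheme$donor_window, "donor_window")
    wr(scheme$acceptor_window, "acceptor_window")
    wr(scheme$donor_nanotime_range, "donor_nanotime_range")
    wr(scheme$acceptor_nanotime_range, "acceptor_nanotime_range")
  }
  invisible(path)
}
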