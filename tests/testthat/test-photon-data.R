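test_that("photon series validates its invariants", {
  s <- photon_series(c(0, 4, 4, 9), c(0L, 1L, 2L, 0L), 12.5e-9)
  expect_s3_class(s, "photon_series")
  expect_identical(s$timestamps, c(0, 4, 4, 9))  # duplicate ticks are legal
  expect_error(photon_series(c(5, 3), c(0L, 0L), 1e-9),
               "non-decreasing.*index 2")
  expect_error(photon_series(0:3, 0:2, 1e-9), "equal length")
  expect_error(photon_series(0:3, rep(0L, 4), -1), "clock_period")
})

test_that("text photon table round-trips exactly, gzip included", {
  s <- photon_series(sort(sample(0:1e7, 100)), sample(0:2, 100, TRUE),
                     50e-9, acquisition_duration = 1)
  for (ext in c(".txt", ".txt.gz")) {
    path <- tempfile(fileext = ext)
    write_photon_table(s, path)
    s2 <- read_photon_table(path)
    expect_identical(s2$timestamps, s$timestamps)
    expect_identical(s2$stream_index, s$stream_index)
    expect_identical(s2$clock_period, s$clock_period)
    unlink(path)
  }
})

test_that("photon-HDF5 round-trips and rejects malformed files", {
  s <- photon_series(sort(sample(0:1e7, 100)), sample(0:1, 100, TRUE),
                     12.5e-9)
  sch <- alternation_scheme("usALEX", alternation_period = 4000,
                            donor_window = c(0, 2000),
                            acceptor_window = c(2000, 4000))
  path <- tempfile(fileext = ".h5")
  write_photon_hdf5(s, path, scheme = sch)
  rd <- read_photon_hdf5(path)
  expect_identical(rd$series$timestamps, s$timestamps)
  expect_identical(rd$series$stream_index, s$stream_index)
  expect_identical(rd$series$clock_period, s$clock_period)
  expect_false(attr(rd$series, "streams_assigned"))
  expect_equal(rd$scheme$alternation_period, 4000)
  expect_equal(rd$scheme$donor_window, c(0, 2000))
  unlink(path)

  # a file without the mandatory photon_data groups is rejected
  bad <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(bad)
  rhdf5::h5write(1:5, bad, "unrelated")
  rhdf5::h5closeAll()
  expect_error(read_photon_hdf5(bad), "missing mandatory")
  unlink(bad)
  expect_error(read_photon_hdf5(tempfile()), "no such file")

  # duplicate ticks on one detector are flagged, across detectors legal
  dup <- photon_series(c(0, 4, 4, 4), c(0L, 1L, 0L, 1L), 1e-8)
  p2 <- tempfile(fileext = ".h5")
  write_photon_hdf5(dup, p2)
  expect_warning(read_photon_hdf5(p2), "duplicate timestamp")
  unlink(p2)
})

test_that("tiny tick series survives HDF5 round-trip field-by-field", {
  s <- photon_series(c(0, 4, 4), c(0L, 1L, 0L), 12.5e-9)
  path <- tempfile(fileext = ".h5")
  write_photon_hdf5(s, path)
  rd <- read_photon_hdf5(path)
  expect_identical(rd$series$timestamps, c(0, 4, 4))
  expect_identical(rd$series$stream_index, c(0L, 1L, 0L))
  expect_identical(rd$series$clock_period, 12.5e-9)
  unlink(path)
})

usalex_scheme <- function()
  alternation_scheme("usALEX", alternation_period = 4000,
                     donor_window = c(0, 2000),
                     acceptor_window = c(2000, 4000))

test_that("usALEX stream assignment follows the excitation windows", {
  dm <- c("0" = "donor", "1" = "acceptor")
  # photon at tick 6500 (position 2500, acceptor window) on the acceptor
  # detector becomes stream 2; a donor-detector photon in the acceptor
  # window is dropped
  s <- photon_series(c(500, 1500, 6500, 6600), c(0L, 1L, 1L, 0L),
                     12.5e-9, streams_assigned = FALSE)
  out <- assign_streams(s, usalex_scheme(), dm)
  expect_identical(out$stream_index, c(0L, 1L, 2L))
  expect_identical(out$timestamps, c(500, 1500, 6500))
  expect_identical(attr(out, "dropped_photons"), 1L)
})

test_that("stream assignment matches a per-photon brute-force loop", {
  set.seed(11)
  n <- 1e4
  ts <- sort(sample(0:5e6, n))
  det <- sample(0:1, n, TRUE)
  s <- photon_series(ts, det, 12.5e-9, streams_assigned = FALSE)
  sch <- usalex_scheme()
  out <- assign_streams(s, sch, c("0" = "donor", "1" = "acceptor"))
  # independent per-photon classification
  expected <- integer(0)
  kept <- 0L
  for (i in seq_len(n)) {
    pos <- ts[i] %% 4000
    st <- if (pos < 2000) {
      if (det[i] == 0) 0L else 1L
    } else {
      if (det[i] == 1) 2L else NA_integer_
    }
    if (!is.na(st)) { expected <- c(expected, st); kept <- kept + 1L }
  }
  expect_identical(out$stream_index, expected)
  # partition: retained + dropped = input
  expect_identical(length(out$timestamps) + attr(out, "dropped_photons"),
                   as.integer(n))
})

test_that("nsALEX assignment gates on nanotimes and requires them", {
  sch <- alternation_scheme("nsALEX", donor_nanotime_range = c(0, 2000),
                            acceptor_nanotime_range = c(2000, 4000))
  s <- photon_series(c(10, 20, 30), c(0L, 1L, 1L), 50e-9,
                     nanotime = c(100L, 150L, 2500L),
                     streams_assigned = FALSE)
  out <- assign_streams(s, sch, c("0" = "donor", "1" = "acceptor"))
  expect_identical(out$stream_index, c(0L, 1L, 2L))
  s2 <- photon_series(c(10, 20), c(0L, 1L), 50e-9, streams_assigned = FALSE)
  expect_error(assign_streams(s2, sch, c("0" = "donor", "1" = "acceptor")),
               "nanotime")
})

test_that("acceptor shift maps window fractions and is idempotent", {
  sch <- usalex_scheme()
  s <- photon_series(c(1700, 2500), c(0L, 2L), 12.5e-9)
  out <- shift_acceptor_photons(s, sch)
  # stream-2 photon at position 2500 -> 500; stream-0 photon untouched
  expect_identical(out$timestamps[out$stream_index == 2L], 500)
  expect_identical(out$timestamps[out$stream_index == 0L], 1700)

  set.seed(21)
  n <- 3000
  ts <- sort(sample(0:2e6, n))
  st <- sample(0:2, n, TRUE)
  pos <- ts %% 4000
  st[pos >= 2000] <- 2L         # make window contents consistent
  st[pos < 2000 & st == 2L] <- sample(0:1, sum(pos < 2000 & st == 2L), TRUE)
  big <- photon_series(ts, st, 12.5e-9)
  once <- shift_acceptor_photons(big, sch)
  twice <- shift_acceptor_photons(once, sch)
  expect_identical(twice$timestamps, once$timestamps)
  expect_identical(twice$stream_index, once$stream_index)
  # no stream-2 photon remains inside an acceptor window
  pos2 <- once$timestamps[once$stream_index == 2L] %% 4000
  expect_true(all(pos2 < 2000))
  # photon count and per-stream counts unchanged
  expect_identical(tabulate(once$stream_index + 1L, 3L),
                   tabulate(big$stream_index + 1L, 3L))
})

test_that("alternation scheme rejects overlapping or empty windows", {
  expect_error(alternation_scheme("usALEX", 4000, c(0, 2500), c(2000, 4000)),
               "disjoint")
  expect_error(alternation_scheme("usALEX", 4000, c(0, 0), c(2000, 4000)),
               "non-empty")
  expect_error(alternation_scheme("usALEX", NULL, c(0, 2000), c(2000, 4000)),
               "alternation_period")
})
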