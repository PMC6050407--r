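test_that("event_table enforces its invariants", {
  m <- matrix(1:6 / 2, 3, 2)
  ev <- event_table(m, c("FSC", "PE"))
  expect_equal(ev$n_events, 3)
  expect_equal(ev$channels, c("FSC", "PE"))
  expect_error(event_table(m, c("PE", "PE")), "unique")
  expect_error(event_table(m, "PE"), "channel names")
  expect_error(event_table(m[0, , drop = FALSE], c("A", "B")), "at least one")
  m[2, 1] <- NA
  expect_error(event_table(m, c("A", "B")), "finite")
})

test_that("CSV round trip is lossless at full precision", {
  withr::with_seed(11, {
    for (i in 1:5) {
      n <- sample(2:40, 1); p <- sample(1:5, 1)
      m <- matrix(rnorm(n * p, 0, 10^runif(1, -2, 5)), n, p)
      ev <- event_table(m, paste0("ch", seq_len(p)), sample_id = "rt")
      f <- withr::local_tempfile(fileext = ".csv")
      write_events_csv(ev, f)
      back <- read_events_csv(f, sample_id = "rt")
      expect_identical(back$channels, ev$channels)
      expect_identical(back$intensities, ev$intensities)
    }
  })
})

test_that("CSV reader preserves order, reports bad cells with coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("B,A", "1.5,2.5", "-3,4e2", "0.25,6"), f)
  ev <- read_events_csv(f)
  expect_equal(ev$channels, c("B", "A"))
  expect_equal(ev$intensities,
               matrix(c(1.5, -3, 0.25, 2.5, 400, 6), 3, 2,
                      dimnames = list(NULL, c("B", "A"))))
  writeLines(c("B,A", "1,2", "NA,4"), f)
  expect_error(read_events_csv(f), "row 2, column 'B'")
  writeLines(c("B,A"), f)
  expect_error(read_events_csv(f), "no events")
})

test_that("FCS write/read round trip preserves values within float32", {
  withr::with_seed(5, {
    m <- matrix(c(rnorm(150, 1000, 300), rnorm(150, -5, 20),
                  10^runif(100, 0, 5)), 100, 4)
    ev <- event_table(m, c("FSC-A", "SSC-A", "PE-A", "APC-A"),
                      panel = list(`PE-A` = "VEGFR2"))
    f <- withr::local_tempfile(fileext = ".fcs")
    write_fcs(ev, f)
    back <- read_fcs(f)
    expect_equal(back$n_events, 100)
    expect_identical(back$channels, ev$channels)
    expect_equal(back$intensities, ev$intensities, tolerance = 1e-6)
    expect_equal(back$panel[["PE-A"]], "VEGFR2")
  })
})

test_that("FCS files from an independent writer are read exactly", {
  # float32-exact values so the comparison is exact, not approximate
  m <- matrix(c(0.5, 1.25, -2.75, 1024, 123.5, 0.0078125,
                65536, 3.5, -0.125, 7, 100, 2.5), 4, 3, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".fcs")
  assemble_fcs_bytes(f, c("FL1", "FL2", "FL3"), m)
  ev <- read_fcs(f)
  expect_equal(ev$channels, c("FL1", "FL2", "FL3"))
  expect_equal(round(ev$intensities, 6),
               round(matrix(m, 4, 3, dimnames = list(NULL, ev$channels)), 6))
})

test_that("malformed and degenerate FCS inputs give named errors", {
  f <- withr::local_tempfile(fileext = ".fcs")
  assemble_fcs_bytes(f, "FL1", matrix(1:4 / 2, 4, 1))
  bytes <- readBin(f, "raw", file.size(f))
  # patch keywords inside the TEXT segment (same-length substitutions)
  text_end <- as.integer(substr(rawToChar(bytes[1:58]), 19, 26))
  text_idx <- 59:(text_end + 1)
  patched <- function(pattern, replacement) {
    out <- bytes
    out[text_idx] <- charToRaw(sub(pattern, replacement, fixed = TRUE,
                                   rawToChar(bytes[text_idx])))
    out
  }
  # zero events
  writeBin(patched("$TOT|4", "$TOT|0"), f)
  expect_error(read_fcs(f), "zero events")
  # FCS 2.0 rejected
  writeBin(c(charToRaw("FCS2.0"), bytes[-(1:6)]), f)
  expect_error(read_fcs(f), "FCS 2.0")
  # missing required keyword is named
  writeBin(patched("$PAR|1", "$XAR|1"), f)
  expect_error(read_fcs(f), "\\$PAR")
})

test_that("config defaults, validation and round trip behave", {
  f <- withr::local_tempfile(fileext = ".json")
  write_minimal_config_json(f)
  cfg <- load_config(f)
  expect_equal(cfg$bins, 500L)
  expect_equal(cfg$k_range, c(1L, 9L))
  expect_equal(cfg$qe_threshold, 0.7)
  expect_equal(cfg$criteria$qe_max, 0.7)

  write_minimal_config_json(f, list(bins = 1))
  expect_error(load_config(f), "bins")
  # all violations reported at once
  write_minimal_config_json(f, list(bins = 1, k_range = c(0, 12),
                                    qe_threshold = -1))
  err <- tryCatch(load_config(f), error = conditionMessage)
  expect_match(err, "bins")
  expect_match(err, "k_range")
  expect_match(err, "qe_threshold")

  # serialize -> parse round trip
  cfg2 <- pipeline_config(panel = list(PE = "VEGFR1"),
                          gates = gate_node(label = "all"),
                          bins = 250L, qe_threshold = 0.6, seed = 9L)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_config(cfg2, f2)
  back <- load_config(f2)
  for (field in c("panel", "bins", "k_range", "qe_threshold", "min_cells",
                  "seed", "markers")) {
    expect_equal(back[[field]], cfg2[[field]], info = field)
  }
  expect_equal(unclass(back$criteria), unclass(cfg2$criteria))
})
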