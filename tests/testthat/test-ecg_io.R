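make_rec <- function(seed = 1, duration = 12, label = "healthy") {
  synth_record(synth_config(duration = duration, class_label = label,
                            seed = seed))
}

test_that("minimal CSV record reads with declared rate", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.0", "1,1.0", "2,0.0"), p)
  rec <- read_record(p, format = "csv", fs = 256)
  expect_s3_class(rec, "ecg_record")
  expect_equal(length(rec$samples), 3)
  expect_equal(rec$samples, c(0, 1, 0))
  expect_equal(rec$fs, 256)
  expect_null(rec$r_peaks)
})

test_that("CSV rate is inferred from a time column when not declared", {
  p <- withr::local_tempfile(fileext = ".csv")
  t <- (0:99) / 200
  writeLines(c("time,amplitude", paste(t, sin(t * 50), sep = ",")), p)
  rec <- read_record(p, format = "csv")
  expect_equal(rec$fs, 200, tolerance = 1e-9)
})

test_that("CSV format errors name the problem", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.1", "1,NaN", "2,0.3"), p)
  expect_error(read_record(p, format = "csv", fs = 10), "row 2")
  writeLines(c("0,0.1", "2,0.2", "1,0.3"), p)
  expect_error(read_record(p, format = "csv", fs = 10), "increasing")
  expect_error(read_record(file.path(tempdir(), "nope.csv"), format = "csv"),
               "not found")
})

test_that("WFDB round-trip: samples within quantization, peaks bit-exact", {
  rec <- make_rec(seed = 5, label = "epilepsy")
  td <- withr::local_tempdir()
  base <- file.path(td, "rec01")
  write_record(rec, base, "wfdb")
  expect_true(all(file.exists(paste0(base, c(".hea", ".dat", ".atr")))))
  back <- read_record(base)
  expect_equal(back$fs, rec$fs)
  expect_equal(length(back$samples), length(rec$samples))
  # 12-bit quantization over a 10-unit range: step 10/2^12
  expect_lt(max(abs(back$samples - rec$samples)), 10 / 2^12)
  expect_identical(back$r_peaks, rec$r_peaks)
  expect_equal(back$label, "epilepsy")
  expect_equal(back$subject_id, rec$subject_id)
})

test_that("CSV round-trip is exact to printed precision and keeps peaks", {
  rec <- make_rec(seed = 6)
  td <- withr::local_tempdir()
  p <- file.path(td, "rec02.csv")
  write_record(rec, p, "csv")
  back <- read_record(p)
  expect_lt(max(abs(back$samples - rec$samples)), 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$r_peaks, rec$r_peaks)
})

test_that("unknown label is not emitted and reads back as unknown", {
  rec <- ecg_record(sin(1:600 / 5), fs = 100, subject_id = "anon")
  td <- withr::local_tempdir()
  p <- file.path(td, "anon.csv")
  write_record(rec, p, "csv")
  expect_false(any(grepl("label", readLines(p))))
  expect_equal(read_record(p)$label, "unknown")
})

test_that("round-trip identity holds over 100 seeded generator records", {
  td <- withr::local_tempdir()
  step <- 10 / 2^12
  for (i in 1:100) {
    rec <- synth_record(synth_config(
      duration = 6, seed = 1000L + i,
      class_label = if (i %% 2) "healthy" else "epilepsy",
      noise = list(instrumentation = 0.02)))
    fmt <- if (i %% 2) "wfdb" else "csv"
    base <- file.path(td, sprintf("r%03d", i))
    write_record(rec, base, fmt)
    back <- read_record(if (fmt == "csv") paste0(base, ".csv") else base)
    tol <- if (fmt == "wfdb") step else 1e-12
    expect_lt(max(abs(back$samples - rec$samples)), tol)
    expect_identical(back$r_peaks, rec$r_peaks)
    expect_equal(back$label, rec$label)
  }
})

test_that("annotation indices above the SKIP threshold survive exactly", {
  n <- 300000L
  rec <- ecg_record(sin(seq_len(n) / 40), fs = 256,
                    r_peaks = c(3L, 900L, 150000L, 299999L))
  td <- withr::local_tempdir()
  base <- file.path(td, "long")
  write_record(rec, base, "wfdb")
  expect_identical(read_record(base)$r_peaks, rec$r_peaks)
})

test_that("1-based annotation sidecars convert at the boundary", {
  td <- withr::local_tempdir()
  p <- file.path(td, "ix.csv")
  writeLines(c("# fs: 100", "time,amplitude",
               paste((0:49) / 100, cos(0:49), sep = ",")), p)
  writeLines(c("10", "20"), file.path(td, "ix.rpeaks"))
  rec0 <- read_record(p)                   # sidecar read as 0-based
  rec1 <- read_record(p, index_base = 1L)  # declared 1-based
  expect_equal(rec0$r_peaks, c(11L, 21L))
  expect_equal(rec1$r_peaks, c(10L, 20L))
})

test_that("invalid records are rejected at construction", {
  expect_error(ecg_record(numeric(0), 256), "non-empty")
  expect_error(ecg_record(c(1, NA, 2), 256), "non-finite")
  expect_error(ecg_record(1:10, -1), "positive")
  expect_error(ecg_record(1:10, 256, r_peaks = c(5, 5)), "increasing")
  expect_error(ecg_record(1:10, 256, r_peaks = c(2, 11)), "increasing")
})
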