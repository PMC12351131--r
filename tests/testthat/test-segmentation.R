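test_that("segmentation arithmetic matches the 400/600 ms contract at 256 Hz", {
  cfg <- segmentation_config(0.4, 0.6, fs = 256)
  expect_equal(cfg$L, 256L)          # round(256 * 1.0)
  expect_equal(cfg$r_offset, 102L)   # round-half-away(256 * 0.4) = 102
  x <- seq_len(2000) / 7
  rec <- ecg_record(x, 256)
  # R-peak at 0-based 1000 (1-based 1001): window = 0-based [898, 1154)
  cs <- segment_cycles(rec, peaks = 1001L, cfg)
  expect_equal(dim(cs$cycles), c(1, 256))
  expect_equal(cs$cycles[1, ], x[899:1154])
  expect_equal(cs$cycles[1, cs$r_offset + 1L], x[1001])
})

test_that("out-of-bounds windows are dropped and counted", {
  x <- rnorm(600)
  rec <- ecg_record(x, 256)
  # 0-based PR=50 -> 1-based 51: start would be negative -> dropped
  cs <- segment_cycles(rec, peaks = c(51L, 300L), segmentation_config())
  expect_equal(nrow(cs$cycles), 1)
  expect_equal(attr(cs, "dropped"), 1L)
  expect_equal(cs$source_peaks, 300L)
  expect_error(segment_cycles(rec, peaks = 51L), "no cycle window")
})

test_that("non-integer fs*lambda rounds half away from zero, L fixed first", {
  cfg <- segmentation_config(0.4, 0.6, fs = 250)
  expect_equal(cfg$L, 250L)
  expect_equal(cfg$r_offset, 100L)
  cfg2 <- segmentation_config(0.4, 0.6, fs = 257)  # 102.8 -> 103
  expect_equal(cfg2$L, 257L)
  expect_equal(cfg2$r_offset, 103L)
  expect_error(segmentation_config(0.5, 0.6), "exceed 1")
})

test_that("constant-rate record: peak of each cycle sits at the R column", {
  rec <- synth_record(synth_config(duration = 106, hr_mean = 60, hr_sd = 0,
                                   amp_jitter_sd = 0, morph_deform_prob = 0,
                                   seed = 31))
  cs <- segment_cycles(rec, rec$r_peaks)
  expect_gte(nrow(cs$cycles), 100)
  argmaxes <- apply(cs$cycles, 1, which.max)
  expect_true(all(abs(argmaxes - (cs$r_offset + 1L)) <= 2))
})

test_that("segmenting a concatenation equals concatenating segmentations", {
  r1 <- synth_record(synth_config(duration = 15, seed = 41))
  r2 <- synth_record(synth_config(duration = 15, seed = 42,
                                  class_label = "epilepsy"))
  n1 <- length(r1$samples)
  cat_rec <- ecg_record(c(r1$samples, r2$samples), r1$fs)
  peaks <- c(r1$r_peaks, r2$r_peaks + n1)
  cs_cat <- segment_cycles(cat_rec, peaks)
  cs1 <- segment_cycles(r1, r1$r_peaks)
  cs2 <- segment_cycles(r2, r2$r_peaks)
  # the concatenated record retains windows that straddle the join; rows for
  # peaks whose windows fit in the halves must agree exactly
  rows1 <- nrow(cs1$cycles)
  expect_equal(cs_cat$cycles[seq_len(rows1), ], cs1$cycles)
  tail_rows <- cs_cat$source_peaks > n1 + cs_cat$r_offset
  expect_equal(
    cs_cat$cycles[which(tail_rows)[seq_len(nrow(cs2$cycles))], ],
    cs2$cycles)
})

test_that("overlapping cycles (RR < window) are retained and bit-faithful", {
  rec <- synth_record(synth_config(duration = 30, class_label = "epilepsy",
                                   hr_mean = 110, hr_sd = 2, seed = 17))
  cs <- segment_cycles(rec, rec$r_peaks)
  rr <- diff(cs$source_peaks)
  expect_true(any(rr < cs$L))  # overlap present at 110 bpm
  for (i in seq_len(nrow(cs$cycles))) {
    start <- cs$source_peaks[i] - cs$r_offset
    expect_identical(cs$cycles[i, ], rec$samples[start:(start + cs$L - 1L)])
  }
})

test_that("cycle sets round-trip through CSV + JSON sidecar", {
  rec <- synth_record(synth_config(duration = 12, seed = 51))
  cs <- segment_cycles(rec, rec$r_peaks)
  td <- withr::local_tempdir()
  p <- file.path(td, "cycles.csv")
  write_cycle_set(cs, p)
  back <- read_cycle_set(p)
  expect_equal(back$cycles, cs$cycles, tolerance = 1e-12)
  expect_identical(back$source_peaks, cs$source_peaks)
  expect_equal(back[c("L", "r_offset", "fs", "subject_id", "label")],
               cs[c("L", "r_offset", "fs", "subject_id", "label")])
})
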