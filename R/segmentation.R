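#' Segmentation configuration
#'
#' A statistical cycle is a fixed-length window cut around each R-peak:
#' `lambda_pre` seconds before the peak and `theta_post` after it, with
#' `lambda_pre + theta_post <= 1` so each cycle spans at most one second.
#' Defaults follow the standard split of 400 ms before / 600 ms after the
#' R wave at 256 Hz.
#'
#' Non-integer `fs * lambda_pre` is resolved by rounding half away from
#' zero, with the total cycle length `L = round(fs * (lambda_pre +
#' theta_post))` fixed first and the post-window taking the remainder, so
#' every cycle has exactly `L` samples.
#'
#' @param lambda_pre Seconds before the R-peak (default 0.4).
#' @param theta_post Seconds after the R-peak (default 0.6).
#' @param fs Sampling rate in Hz (default 256).
#' @return A list of class `segmentation_config` with derived fields `L`
#'   (samples per cycle) and `r_offset` (samples before R within a cycle; the
#'   R sample sits at column `r_offset + 1`).
#' @export
segmentation_config <- function(lambda_pre = 0.4, theta_post = 0.6, fs = 256) {
  if (lambda_pre < 0 || theta_post <= 0) {
    stop("window extents must be positive", call. = FALSE)
  }
  if (lambda_pre + theta_post > 1 + 1e-12) {
    stop("lambda_pre + theta_post must not exceed 1 second", call. = FALSE)
  }
  L <- as.integer(round_half_away(fs * (lambda_pre + theta_post)))
  r_offset <- as.integer(round_half_away(fs * lambda_pre))
  structure(list(lambda_pre = lambda_pre, theta_post = theta_post, fs = fs,
                 L = L, r_offset = r_offset),
            class = "segmentation_config")
}

#' Cut a recording into statistical cycles
#'
#' Extracts one fixed-length cycle per R-peak. A cycle spans `L` samples
#' starting `r_offset` samples before its peak; peaks whose full window does
#' not fit inside the record are dropped (and counted in the `dropped`
#' attribute of the result). Consecutive cycles may overlap when the RR
#' interval is shorter than the window -- the window length is fixed
#' irrespective of heart rate -- and overlapping rows are bit-faithful copies
#' of the source samples.
#'
#' @param rec An [ecg_record()].
#' @param peaks Integer vector of strictly increasing 1-based R-peak indices;
#'   defaults to the record's annotations via [get_r_peaks()].
#' @param cfg A [segmentation_config()]; its `fs` is taken from the record.
#' @return A `cycle_set`: list with `cycles` (n x L numeric matrix), `L`,
#'   `r_offset`, `fs`, `subject_id`, `label` and `source_peaks` (the peak
#'   index that produced each row). Attribute `dropped` counts out-of-bounds
#'   peaks.
#' @export
segment_cycles <- function(rec, peaks = get_r_peaks(rec),
                           cfg = segmentation_config(fs = rec$fs)) {
  stopifnot(inherits(rec, "ecg_record"))
  cfg <- segmentation_config(cfg$lambda_pre, cfg$theta_post, fs = rec$fs)
  peaks <- as.integer(peaks)
  if (length(peaks) && (any(diff(peaks) <= 0L) || peaks[1L] < 1L ||
                        peaks[length(peaks)] > length(rec$samples))) {
    stop("`peaks` must be strictly increasing indices within the record",
         call. = FALSE)
  }
  n <- length(rec$samples)
  starts <- peaks - cfg$r_offset
  ok <- starts >= 1L & (starts + cfg$L - 1L) <= n
  dropped <- sum(!ok)
  kept <- peaks[ok]
  if (!length(kept)) {
    stop("no cycle window fits inside the record", call. = FALSE)
  }
  idx <- outer(starts[ok], 0:(cfg$L - 1L), `+`)
  cycles <- matrix(rec$samples[idx], nrow = length(kept), ncol = cfg$L)
  structure(
    list(cycles = cycles, L = cfg$L, r_offset = cfg$r_offset, fs = rec$fs,
         subject_id = rec$subject_id, label = rec$label,
         source_peaks = kept),
    class = "cycle_set", dropped = dropped
  )
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> subject %s (%s): %d cycles x %d samples (R at column %d), %d dropped at boundaries\n",
              x$subject_id, x$label, nrow(x$cycles), x$L, x$r_offset + 1L,
              attr(x, "dropped") %||% 0L))
  invisible(x)
}

#' @export
plot.cycle_set <- function(x, max_cycles = 50, ...) {
  t <- ((seq_len(x$L) - 1L) - x$r_offset) / x$fs
  m <- x$cycles[seq_len(min(nrow(x$cycles), max_cycles)), , drop = FALSE]
  graphics::matplot(t, t(m), type = "l", lty = 1,
                    col = grDevices::adjustcolor(1, alpha.f = 0.25),
                    xlab = "time from R-peak [s]", ylab = "amplitude",
                    main = sprintf("%s (%s)", x$subject_id, x$label), ...)
  invisible(x)
}

#' Write / read a cycle set
#'
#' Serializes a `cycle_set` as a CSV matrix (one cycle per row) plus a JSON
#' sidecar carrying the segmentation parameters and record metadata.
#'
#' @param cs A `cycle_set`.
#' @param path Output CSV path.
#' @return `write_cycle_set` invisibly returns `path`; `read_cycle_set`
#'   returns the reconstructed `cycle_set`.
#' @export
write_cycle_set <- function(cs, path) {
  utils::write.table(cs$cycles, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(L = cs$L, r_offset = cs$r_offset, fs = cs$fs,
               subject_id = cs$subject_id, label = cs$label,
               source_peaks = cs$source_peaks,
               dropped = attr(cs, "dropped") %||% 0L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cycle_set
#' @export
read_cycle_set <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(cycles = m, L = meta$L, r_offset = meta$r_offset, fs = meta$fs,
         subject_id = meta$subject_id, label = meta$label,
         source_peaks = as.integer(meta$source_peaks)),
    class = "cycle_set", dropped = meta$dropped
  )
}
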