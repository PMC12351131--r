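#' Single-lead ECG recording
#'
#' Container for a sampled single-lead ECG voltage trace together with its
#' sampling rate, subject identity, class label and (optionally) annotated
#' R-peak positions. All functions in the package consume and produce this
#' class; sample indices are 1-based throughout the package and converted to
#' the 0-based convention of annotation files only at the I/O boundary.
#'
#' @param samples Numeric vector of amplitudes (mV before normalization,
#'   arbitrary units after). Must be non-empty and finite.
#' @param fs Sampling rate in Hz, a single positive number.
#' @param subject_id Opaque subject identifier string.
#' @param label Class label: one of `"healthy"`, `"epilepsy"`, `"unknown"`.
#' @param r_peaks Optional integer vector of R-peak sample indices (1-based),
#'   strictly increasing, each within `[1, length(samples)]`. `NULL` when
#'   no annotation is available.
#'
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1.2 * seq(0, 5, by = 1 / 256)), fs = 256)
#' rec
#' @export
ecg_record <- function(samples, fs, subject_id = "unknown",
                       label = c("unknown", "healthy", "epilepsy"),
                       r_peaks = NULL) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("`samples` contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!is.null(r_peaks)) {
    r_peaks <- as.integer(round(r_peaks))
    if (length(r_peaks) && (any(diff(r_peaks) <= 0L) ||
                            r_peaks[1L] < 1L ||
                            r_peaks[length(r_peaks)] > length(samples))) {
      stop("`r_peaks` must be strictly increasing indices in [1, length(samples)]",
           call. = FALSE)
    }
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         subject_id = as.character(subject_id)[1L], label = label,
         r_peaks = r_peaks),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record> subject %s (%s)\n", x$subject_id, x$label))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), amplitude in [%.3g, %.3g]\n",
              length(x$samples), x$fs, dur,
              min(x$samples), max(x$samples)))
  if (is.null(x$r_peaks)) {
    cat("  r_peaks: none\n")
  } else {
    cat(sprintf("  r_peaks: %d annotated\n", length(x$r_peaks)))
  }
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, from = 0, to = min(10, length(x$samples) / x$fs),
                            ...) {
  i <- seq(max(1L, floor(from * x$fs) + 1L),
           min(length(x$samples), ceiling(to * x$fs)))
  t <- (i - 1) / x$fs
  graphics::plot(t, x$samples[i], type = "l", xlab = "time [s]",
                 ylab = "amplitude", main = sprintf("%s (%s)", x$subject_id,
                                                    x$label), ...)
  if (!is.null(x$r_peaks)) {
    rp <- x$r_peaks[x$r_peaks %in% i]
    graphics::points((rp - 1) / x$fs, x$samples[rp], col = 2, pch = 4)
  }
  invisible(x)
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# derive a child seed from a master seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}
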