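#' Preprocessing configuration
#'
#' Parameters for conditioning a raw ECG recording before segmentation:
#' target sampling rate, Butterworth bandpass corners and order, edge-trim
#' fraction and amplitude normalization mode.
#'
#' The default band (0.5--40 Hz, order 4, applied forward-backward for zero
#' phase) rejects the out-of-band noise sources typical of single-lead ECG --
#' baseline wander (~0.15--0.3 Hz, respiratory), 60 Hz powerline interference
#' and its harmonics, broadband EMG above the diagnostic band and
#' electrosurgical interference -- while preserving QRS energy.
#'
#' @param target_fs Working sampling rate in Hz (default 256).
#' @param bandpass_low,bandpass_high Passband corners in Hz;
#'   `0 < bandpass_low < bandpass_high < target_fs/2`.
#' @param filter_order Butterworth order per corner (even, default 4).
#' @param edge_trim_fraction Fraction of total duration removed from each end
#'   of the recording, in `[0, 0.5)` (default 0.01, i.e. 1%).
#' @param normalization `"max_abs"` scales to unit peak amplitude; `"none"`
#'   leaves amplitudes untouched.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 256, bandpass_low = 0.5,
                              bandpass_high = 40, filter_order = 4L,
                              edge_trim_fraction = 0.01,
                              normalization = c("max_abs", "none")) {
  normalization <- match.arg(normalization)
  if (!(0 < bandpass_low && bandpass_low < bandpass_high &&
        bandpass_high < target_fs / 2)) {
    stop("need 0 < bandpass_low < bandpass_high < target_fs/2", call. = FALSE)
  }
  if (edge_trim_fraction < 0 || edge_trim_fraction >= 0.5) {
    stop("`edge_trim_fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(target_fs = target_fs, bandpass_low = bandpass_low,
                 bandpass_high = bandpass_high,
                 filter_order = as.integer(filter_order),
                 edge_trim_fraction = edge_trim_fraction,
                 normalization = normalization),
            class = "preprocess_config")
}

#' Resample a recording to a new rate
#'
#' Cubic-spline interpolation onto the new sample grid, preceded by a
#' zero-phase anti-aliasing low-pass (0.45 of the new Nyquist) when
#' downsampling. Annotated R-peaks are rescaled by the rate ratio and rounded
#' to the nearest new sample. A record already at `target_fs` is returned
#' unchanged.
#'
#' @param rec An [ecg_record()].
#' @param target_fs New sampling rate in Hz (> 0).
#' @return An [ecg_record()] at `target_fs` with the same duration to within
#'   one sample period.
#' @export
resample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("`target_fs` must be a single positive number", call. = FALSE)
  }
  if (target_fs == rec$fs) {
    return(rec)
  }
  x <- rec$samples
  n <- length(x)
  if (target_fs < rec$fs) {
    x <- butter_lowpass_filtfilt(x, rec$fs, fc = 0.45 * target_fs, order = 8L)
  }
  t_old <- (seq_len(n) - 1) / rec$fs
  duration <- n / rec$fs
  n_new <- max(1L, round(duration * target_fs))
  t_new <- (seq_len(n_new) - 1) / target_fs
  y <- stats::spline(t_old, x, xout = pmin(t_new, t_old[n]))$y
  rp <- rec$r_peaks
  if (!is.null(rp)) {
    rp <- as.integer(round((rp - 1) * target_fs / rec$fs)) + 1L
    rp <- rp[rp >= 1L & rp <= n_new]
    rp <- unique(rp)
  }
  ecg_record(y, fs = target_fs, subject_id = rec$subject_id,
             label = rec$label, r_peaks = rp)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the configured Butterworth bandpass forward and backward
#' (zero phase), leaving R-peak annotations untouched: zero-phase filtering
#' does not displace the R wave.
#'
#' @param rec An [ecg_record()].
#' @param cfg A [preprocess_config()].
#' @return Filtered [ecg_record()].
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ecg_record"))
  if (cfg$bandpass_high >= rec$fs / 2) {
    stop("bandpass corners must lie below the record's Nyquist frequency",
         call. = FALSE)
  }
  y <- butter_bandpass_filtfilt(rec$samples, rec$fs, cfg$bandpass_low,
                                cfg$bandpass_high, cfg$filter_order)
  out <- rec
  out$samples <- y
  out
}

#' Normalize amplitude to unit peak
#'
#' Scales the signal by a positive scalar so its maximum absolute amplitude is
#' exactly 1; idempotent, shape-preserving.
#'
#' @param rec An [ecg_record()].
#' @return Normalized [ecg_record()].
#' @export
normalize_amplitude <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  m <- max(abs(rec$samples))
  if (m == 0) {
    stop("cannot normalize an all-zero signal", call. = FALSE)
  }
  out <- rec
  out$samples <- rec$samples / m
  out
}

#' Trim record edges
#'
#' Removes the first and last `floor(fraction * n)` samples to discard the
#' measurement artifacts that concentrate at the start and end of ambulatory
#' recordings (the conventional exclusion is 1% of total duration at each
#' end). R-peak annotations are shifted into the new coordinate frame and
#' peaks falling in the removed spans are dropped.
#'
#' @param rec An [ecg_record()].
#' @param fraction Fraction in `[0, 0.5)` of samples removed from each end.
#' @return Trimmed [ecg_record()].
#' @export
trim_edges <- function(rec, fraction = 0.01) {
  stopifnot(inherits(rec, "ecg_record"))
  if (fraction < 0 || fraction >= 0.5) {
    stop("`fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  n <- length(rec$samples)
  k <- floor(fraction * n)
  if (n - 2 * k < 1) {
    stop("trimming would leave an empty record", call. = FALSE)
  }
  if (k == 0) {
    return(rec)
  }
  keep <- (k + 1L):(n - k)
  rp <- rec$r_peaks
  if (!is.null(rp)) {
    rp <- rp[rp >= k + 1L & rp <= n - k] - k
    rp <- as.integer(rp)
  }
  ecg_record(rec$samples[keep], fs = rec$fs, subject_id = rec$subject_id,
             label = rec$label, r_peaks = rp)
}

#' Full preprocessing chain
#'
#' Resample to the working rate, bandpass filter, normalize amplitude and trim
#' edges, in that order.
#'
#' @param rec An [ecg_record()].
#' @param cfg A [preprocess_config()].
#' @return Conditioned [ecg_record()].
#' @export
preprocess_record <- function(rec, cfg = preprocess_config()) {
  rec <- resample(rec, cfg$target_fs)
  rec <- bandpass(rec, cfg)
  if (cfg$normalization == "max_abs") {
    rec <- normalize_amplitude(rec)
  }
  trim_edges(rec, cfg$edge_trim_fraction)
}
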