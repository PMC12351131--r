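#' Pan-Tompkins QRS detection
#'
#' Locates R-peaks with the classic Pan-Tompkins cascade: bandpass (5--15 Hz,
#' the QRS energy band), five-point derivative, squaring, 150 ms
#' moving-window integration, then adaptive dual-threshold decision logic
#' with a 200 ms refractory period, T-wave rejection by slope comparison for
#' candidates within 360 ms of the previous beat, and search-back at half
#' threshold when an expected beat is missed. Thresholds are initialized from
#' the first two seconds of the integrated signal and adapt as running
#' averages of signal and noise peak levels, which makes detection invariant
#' to overall amplitude scaling. Each accepted detection is refined to the
#' local maximum of the (zero-phase) bandpassed signal, then to the local
#' maximum of the input samples, so the returned indices are R-wave aligned
#' for segmentation.
#'
#' @param rec An [ecg_record()] at least 2 s long.
#' @param fs Sampling rate in Hz; defaults to `rec$fs`.
#' @param keep_traces If `TRUE`, per-stage signals (filtered, derivative,
#'   squared, integrated) are attached for diagnostics.
#' @return An object of class `qrs_detection`: list with `r_peaks`
#'   (strictly increasing 1-based sample indices, >= 200 ms apart) and
#'   `stage_traces` (`NULL` unless requested).
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Trans. Biomed. Eng. 32(3):230-236.
#' @export
pan_tompkins <- function(rec, fs = rec$fs, keep_traces = FALSE) {
  stopifnot(inherits(rec, "ecg_record"))
  x <- rec$samples
  n <- length(x)
  if (n < 2 * fs) {
    stop("record must be at least 2 s long for QRS detection", call. = FALSE)
  }
  refractory <- round(0.200 * fs)
  twave_win <- round(0.360 * fs)

  # stage 1: QRS-band filter (zero phase, so no delay bookkeeping)
  bp <- butter_bandpass_filtfilt(x, fs, low = 5, high = 15, order = 2L)
  # stage 2: centered five-point derivative (zero group delay)
  der <- as.numeric(stats::filter(bp, c(1, 2, 0, -2, -1) * fs / 8,
                                  method = "convolution", sides = 2))
  der[is.na(der)] <- 0
  # stage 3: squaring
  sq <- der^2
  # stage 4: moving-window integration over 150 ms (centered)
  wlen <- max(1L, round(0.150 * fs))
  if (wlen %% 2L == 0L) wlen <- wlen + 1L
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen),
                                  method = "convolution", sides = 2))
  mwi[is.na(mwi)] <- 0

  peaks <- local_maxima(mwi)
  traces <- if (keep_traces) {
    list(filtered = bp, derivative = der, squared = sq, integrated = mwi)
  }
  if (!length(peaks) || max(mwi) <= 0) {
    return(structure(list(r_peaks = integer(0), stage_traces = traces),
                     class = "qrs_detection"))
  }

  # threshold initialization from the first 2 s
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)

  rr_hist <- numeric(0)
  accepted <- integer(0)
  last_qrs <- -Inf
  i <- 1L
  while (i <= length(peaks)) {
    p <- peaks[i]
    thr1 <- npki + 0.25 * (spki - npki)
    rr_avg <- if (length(rr_hist)) mean(rr_hist) else NA_real_

    # search-back: expected beat overdue?
    if (!is.na(rr_avg) && is.finite(last_qrs) &&
        (p - last_qrs) > 1.66 * rr_avg) {
      window <- peaks[peaks > last_qrs + refractory & peaks < p]
      if (length(window)) {
        cand <- window[which.max(mwi[window])]
        if (mwi[cand] > 0.5 * thr1) {
          accepted <- c(accepted, cand)
          rr_hist <- update_rr(rr_hist, cand - last_qrs)
          last_qrs <- cand
          spki <- 0.25 * mwi[cand] + 0.75 * spki
          next  # re-examine current peak against the new rhythm state
        }
      }
    }

    if (mwi[p] > thr1 && (p - last_qrs) > refractory) {
      is_twave <- FALSE
      if (is.finite(last_qrs) && (p - last_qrs) < twave_win) {
        # T waves have markedly lower maximal slope than the QRS
        s_now <- max_slope(der, p, fs)
        s_prev <- max_slope(der, last_qrs, fs)
        is_twave <- s_now < 0.5 * s_prev
      }
      if (is_twave) {
        npki <- 0.125 * mwi[p] + 0.875 * npki
      } else {
        accepted <- c(accepted, p)
        if (is.finite(last_qrs)) {
          rr_hist <- update_rr(rr_hist, p - last_qrs)
        }
        last_qrs <- p
        spki <- 0.125 * mwi[p] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    i <- i + 1L
  }

  r_peaks <- refine_peaks(accepted, bp, x, fs)
  r_peaks <- enforce_refractory(r_peaks, mwi, refractory)
  structure(list(r_peaks = r_peaks, stage_traces = traces),
            class = "qrs_detection")
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat(sprintf("<qrs_detection> %d R-peaks\n", length(x$r_peaks)))
  invisible(x)
}

#' R-peak retrieval policy
#'
#' Returns R-peak indices for a record, either preferring existing
#' annotations (`"annotations_first"`) or always running the Pan-Tompkins
#' detector (`"always_detect"`).
#'
#' @param rec An [ecg_record()].
#' @param policy Dispatch policy.
#' @return Integer vector of strictly increasing 1-based R-peak indices.
#' @export
get_r_peaks <- function(rec, policy = c("annotations_first", "always_detect")) {
  policy <- match.arg(policy)
  if (policy == "annotations_first" && !is.null(rec$r_peaks)) {
    return(rec$r_peaks)
  }
  pan_tompkins(rec)$r_peaks
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

max_slope <- function(der, idx, fs) {
  w <- round(0.075 * fs)
  lo <- max(1L, idx - w)
  hi <- min(length(der), idx + w)
  max(abs(der[lo:hi]))
}

update_rr <- function(rr_hist, rr) {
  rr_hist <- c(rr_hist, rr)
  if (length(rr_hist) > 8L) rr_hist <- rr_hist[(length(rr_hist) - 7L):length(rr_hist)]
  rr_hist
}

# refine integrator fiducials: local max of bandpassed signal within ±75 ms,
# then local max of the raw samples within ±25 ms (R waves are positive after
# the package's zero-phase conditioning)
refine_peaks <- function(fiducials, bp, x, fs) {
  if (!length(fiducials)) return(integer(0))
  w1 <- round(0.075 * fs)
  w2 <- round(0.025 * fs)
  out <- vapply(fiducials, function(p) {
    lo <- max(1L, as.integer(p - w1)); hi <- min(length(bp), as.integer(p + w1))
    p1 <- lo + which.max(bp[lo:hi]) - 1L
    lo2 <- max(1L, p1 - as.integer(w2)); hi2 <- min(length(x), p1 + as.integer(w2))
    lo2 + which.max(x[lo2:hi2]) - 1L
  }, integer(1))
  sort(unique(out))
}

# after refinement two fiducials can collapse near one beat; keep the one
# with the larger integrator response
enforce_refractory <- function(pks, mwi, refractory) {
  if (length(pks) < 2L) return(pks)
  keep <- pks[1L]
  for (p in pks[-1L]) {
    last <- keep[length(keep)]
    if (p - last <= refractory) {
      if (mwi[p] > mwi[last]) keep[length(keep)] <- p
    } else {
      keep <- c(keep, p)
    }
  }
  keep
}
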