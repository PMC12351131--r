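# Butterworth biquad design and zero-phase filtering.
#
# No DSP package ships with the supported toolchain, so the small amount of
# filter machinery the package needs is implemented here: even-order
# Butterworth low-/high-pass sections via the bilinear transform (frequency
# prewarped), applied as cascaded biquads with stats::filter (C speed), and a
# forward-backward pass with odd-reflection padding for zero phase.

# Second-order sections of an even-order Butterworth low- or high-pass.
# Each section is list(b, a) with a[1] == 1.
butter_sections <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2 != 0 || order < 2) {
    stop("`order` must be a positive even integer", call. = FALSE)
  }
  if (fc <= 0 || fc >= fs / 2) {
    stop("corner frequency must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  w0 <- 2 * pi * fc / fs
  lapply(seq_len(order %/% 2), function(k) {
    # pole-pair quality factors of the Butterworth cascade
    q <- 1 / (2 * sin((2 * k - 1) * pi / (2 * order)))
    alpha <- sin(w0) / (2 * q)
    c0 <- cos(w0)
    a0 <- 1 + alpha
    b <- if (type == "low") {
      c((1 - c0) / 2, 1 - c0, (1 - c0) / 2)
    } else {
      c((1 + c0) / 2, -(1 + c0), (1 + c0) / 2)
    }
    list(b = b / a0, a = c(1, -2 * c0, 1 - alpha) / a0)
  })
}

# single-pass biquad (direct form, zero initial conditions)
biquad_once <- function(x, b, a) {
  n <- length(x)
  # moving-average part: pad so stats::filter's one-sided convolution has
  # history for the first samples
  xp <- c(0, 0, x)
  ma <- stats::filter(xp, filt = b, method = "convolution", sides = 1)
  ma <- as.numeric(ma)[3:(n + 2)]
  as.numeric(stats::filter(ma, filt = -a[2:3], method = "recursive"))
}

apply_sections <- function(x, sections) {
  for (s in sections) x <- biquad_once(x, s$b, s$a)
  x
}

# Zero-phase filtering: odd-reflection pad both ends, filter forward and
# backward through every section, strip the pad. Pad length should cover the
# slowest section's transient.
filtfilt_sections <- function(x, sections, padlen) {
  n <- length(x)
  padlen <- min(as.integer(padlen), n - 1L)
  if (padlen > 0L) {
    head_pad <- 2 * x[1L] - x[(padlen + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    xe <- c(head_pad, x, tail_pad)
  } else {
    xe <- x
  }
  y <- apply_sections(xe, sections)
  y <- rev(apply_sections(rev(y), sections))
  y[(padlen + 1L):(padlen + n)]
}

# Zero-phase Butterworth low-pass (anti-aliasing etc.)
butter_lowpass_filtfilt <- function(x, fs, fc, order = 8L) {
  sections <- butter_sections(order, fc, fs, "low")
  filtfilt_sections(x, sections, padlen = ceiling(4 * fs / fc))
}

# Zero-phase Butterworth bandpass: cascade of high-pass(low corner) and
# low-pass(high corner) sections of the given order each.
butter_bandpass_filtfilt <- function(x, fs, low, high, order = 4L) {
  if (!(0 < low && low < high && high < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  sections <- c(butter_sections(order, low, fs, "high"),
                butter_sections(order, high, fs, "low"))
  # transient of the low-corner high-pass dominates; ~4 periods of the corner
  padlen <- ceiling(4 * fs / low)
  filtfilt_sections(x, sections, padlen)
}
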