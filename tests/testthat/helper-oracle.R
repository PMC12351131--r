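# Independent brute-force oracle for the moment statistics: explicit loops
# and a sort-based median, sharing no code with the package implementation.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_moments <- function(x, center = c("median", "mean"), raw = FALSE) {
  center <- match.arg(center)
  n <- length(x)
  c0 <- if (center == "median") oracle_median(x) else sum(x) / n
  s2 <- 0; s3 <- 0; s4 <- 0
  for (xi in x) {
    d <- xi - c0
    s2 <- s2 + d^2
    s3 <- s3 + d^3
    s4 <- s4 + d^4
  }
  v <- s2 / n
  sd_ <- sqrt(v)
  skew <- s3 / sd_^3
  kurt <- s4 / sd_^4
  if (!raw) {
    skew <- skew / n
    kurt <- kurt / n
  }
  list(center = c0, variance = v, std = sd_, skewness = skew, kurtosis = kurt)
}

# mixed relative/absolute closeness: |a - b| <= tol * max(1, |b|); the floor
# keeps cancellation noise on analytically-zero quantities from being
# amplified into an unbounded "relative" error
expect_relerr <- function(actual, expected, tol = 1e-9) {
  expect_lte(abs(actual - expected), tol * max(1, abs(expected)))
}

# match detected peaks against ground truth within a tolerance (samples);
# greedy one-to-one matching in time order
match_peaks <- function(detected, truth, tol) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fn = length(truth) - tp, fp = sum(!used))
}

rms <- function(x) sqrt(mean(x^2))

# dominant frequency of a signal by FFT magnitude (Hz)
dominant_freq <- function(x, fs) {
  n <- length(x)
  spec <- abs(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  freq[which.max(spec)]
}
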