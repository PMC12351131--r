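#' Median-centered moment statistics
#'
#' Robust analogues of the classical moments in which deviations are taken
#' from the sample median \eqn{\eta} instead of the mean. Because the median
#' is insensitive to outliers, these statistics resist the impulsive
#' contamination (powerline bursts, muscle activity, electrode motion) that
#' inflates mean-centered moments:
#' \deqn{\sigma_\eta^2 = \frac{1}{N}\sum_i (x_i - \eta)^2, \qquad
#'       \sigma_\eta = \sqrt{\sigma_\eta^2},}
#' \deqn{\psi_\eta = \frac{1}{N}\sum_i (x_i - \eta)^3 / \sigma_\eta^3, \qquad
#'       \kappa_\eta = \frac{1}{N}\sum_i (x_i - \eta)^4 / \sigma_\eta^4.}
#' The median is the standard sample median (middle element for odd N, mean
#' of the two middle elements for even N). All denominators use the
#' population convention (1/N), so \eqn{\sigma_\eta^2 \ge \sigma^2} always
#' (the mean minimizes the sum of squared deviations) and
#' \eqn{\kappa_\eta \ge 1} by the power-mean inequality.
#'
#' `raw = TRUE` switches the skewness and kurtosis to the unnormalized
#' convention \eqn{\sum_i (x_i-\eta)^k / \sigma_\eta^k} (no 1/N). That form
#' grows linearly with N, making values incomparable across cycle lengths, so
#' the normalized convention is the default: with it the median kurtosis of a
#' large normal sample is ~3, on the same scale as the classical moments.
#'
#' @param x Non-empty numeric vector.
#' @param raw Use the unnormalized (no 1/N) convention for the standardized
#'   moments.
#' @return A single number.
#' @examples
#' median_variance(c(1, 2, 3, 4, 10)) # 11: larger than the variance, 10
#' median_skewness(c(1, 2, 3, 4, 10))
#' @name median_moments
NULL

#' @rdname median_moments
#' @export
median_center <- function(x) {
  if (!length(x)) stop("`x` must be non-empty", call. = FALSE)
  stats::median(x)
}

#' @rdname median_moments
#' @export
median_variance <- function(x) {
  if (!length(x)) stop("`x` must be non-empty", call. = FALSE)
  mean((x - stats::median(x))^2)
}

#' @rdname median_moments
#' @export
median_std <- function(x) {
  sqrt(median_variance(x))
}

#' @rdname median_moments
#' @export
median_skewness <- function(x, raw = FALSE) {
  d <- x - median_center(x)
  s <- sqrt(mean(d^2))
  if (s == 0) {
    stop("standardized moment undefined: zero dispersion", call. = FALSE)
  }
  tot <- sum(d^3) / s^3
  if (raw) tot else tot / length(x)
}

#' @rdname median_moments
#' @export
median_kurtosis <- function(x, raw = FALSE) {
  d <- x - median_center(x)
  s <- sqrt(mean(d^2))
  if (s == 0) {
    stop("standardized moment undefined: zero dispersion", call. = FALSE)
  }
  tot <- sum(d^4) / s^4
  if (raw) tot else tot / length(x)
}

#' Classical mean-centered moments
#'
#' Mean, population variance, skewness and kurtosis under the same 1/N
#' conventions as the median-centered statistics (see [median_moments]),
#' so the two families are directly comparable.
#'
#' @inheritParams median_moments
#' @return Named numeric vector `(mean, variance, skewness, kurtosis)`.
#' @export
classical_moments <- function(x, raw = FALSE) {
  if (!length(x)) stop("`x` must be non-empty", call. = FALSE)
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  if (v == 0) {
    stop("standardized moment undefined: zero dispersion", call. = FALSE)
  }
  s3 <- sum(d^3) / v^1.5
  s4 <- sum(d^4) / v^2
  if (!raw) {
    s3 <- s3 / length(x)
    s4 <- s4 / length(x)
  }
  c(mean = m, variance = v, skewness = s3, kurtosis = s4)
}

#' Per-cycle moment features
#'
#' Computes the location, variance, skewness and kurtosis of every cycle in a
#' `cycle_set` about the chosen center statistic. Cycles with zero dispersion
#' (flat rows), for which the standardized moments are undefined, are
#' excluded with a message and counted in the `n_excluded` attribute rather
#' than propagated as sentinel values.
#'
#' @param cs A `cycle_set` from [segment_cycles()].
#' @param center_kind `"median"` for the robust features, `"mean"` for the
#'   classical ones.
#' @param raw Use the unnormalized standardized-moment convention.
#' @return A `cycle_features` data frame with columns `subject_id`, `label`,
#'   `center_kind`, `cycle`, `center`, `variance`, `skewness`, `kurtosis`.
#' @export
extract_features <- function(cs, center_kind = c("median", "mean"),
                             raw = FALSE) {
  stopifnot(inherits(cs, "cycle_set"))
  center_kind <- match.arg(center_kind)
  m <- cs$cycles
  ctr <- if (center_kind == "median") {
    apply(m, 1L, stats::median)
  } else {
    rowMeans(m)
  }
  d <- m - ctr
  v <- rowMeans(d^2)
  ok <- v > 0
  if (any(!ok)) {
    message(sum(!ok), " zero-dispersion cycle(s) excluded from features")
  }
  nfac <- if (raw) 1 else ncol(m)
  skew <- rowSums(d^3) / v^1.5 / nfac
  kurt <- rowSums(d^4) / v^2 / nfac
  out <- data.frame(
    subject_id = cs$subject_id,
    label = cs$label,
    center_kind = center_kind,
    cycle = seq_len(nrow(m)),
    center = ctr,
    variance = v,
    skewness = skew,
    kurtosis = kurt,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cycle_features", "data.frame"),
            n_excluded = sum(!ok))
}

#' Feature tables for a collection of recordings
#'
#' Convenience wrapper: segments each record (using annotations when present,
#' Pan-Tompkins otherwise) and stacks per-cycle features for all records into
#' one table. At most `max_cycles` cycles are taken per record, from the
#' start, so dataset sizes are reproducible.
#'
#' @param records List of [ecg_record()]s.
#' @param center_kind Passed to [extract_features()].
#' @param seg_cfg A [segmentation_config()].
#' @param max_cycles Per-record cap on cycles used (`Inf` for all).
#' @param raw Passed to [extract_features()].
#' @return A `cycle_features` data frame covering all records.
#' @export
features_from_records <- function(records, center_kind = c("median", "mean"),
                                  seg_cfg = segmentation_config(),
                                  max_cycles = Inf, raw = FALSE) {
  center_kind <- match.arg(center_kind)
  tabs <- lapply(records, function(rec) {
    cs <- segment_cycles(rec, cfg = seg_cfg)
    if (is.finite(max_cycles) && nrow(cs$cycles) > max_cycles) {
      keep <- seq_len(max_cycles)
      cs$cycles <- cs$cycles[keep, , drop = FALSE]
      cs$source_peaks <- cs$source_peaks[keep]
    }
    extract_features(cs, center_kind, raw = raw)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  structure(out, class = c("cycle_features", "data.frame"))
}
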