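# Acceleration norm and the per-window descriptive statistics. All features
# are functions of the norm series alone, which makes the whole feature
# vector invariant to the sensor's mounting orientation.

FEATURE_NAMES <- c("mean_g", "std_g", "p10_g", "p50_g", "p95_g", "min_g",
                   "max_g", "skewness", "kurtosis", "rms_g", "avg_freq_hz",
                   "entropy_bits")

#' Acceleration norm (signal magnitude vector)
#'
#' Element-wise Euclidean magnitude `sqrt(ax^2 + ay^2 + az^2)`. Using the
#' norm instead of individual axes removes the dependence on how the sensor
#' happens to be oriented on the body.
#'
#' @param ax,ay,az Acceleration channels in g, equal lengths.
#' @return Numeric vector of per-sample magnitudes in g.
#' @export
acceleration_norm <- function(ax, ay, az) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    stop("acceleration channels must have equal length", call. = FALSE)
  }
  sqrt(ax^2 + ay^2 + az^2)
}

# One-sided periodogram of the mean-removed series, DC bin excluded.
# Returns frequencies (Hz) and power; both empty for n < 2.
periodogram_onesided <- function(x, fs) {
  n <- length(x)
  sp <- stats::fft(x - mean(x))
  kmax <- n %/% 2
  k <- seq_len(kmax)
  list(freq = k * fs / n, power = Mod(sp[k + 1L])^2)
}

#' Per-window feature vector
#'
#' The descriptive statistics computed on each window of the acceleration
#' norm: mean, standard deviation (population), 10th/50th/95th percentiles,
#' minimum, maximum, skewness, excess kurtosis, root mean square, average
#' frequency, and spectral entropy. Average frequency is the power-weighted
#' mean frequency (spectral centroid) of the mean-removed window's one-sided
#' periodogram; entropy is the Shannon entropy in bits of the same
#' periodogram normalised to a probability distribution. Zero-variance
#' windows have skewness, kurtosis, average frequency and entropy defined
#' as 0.
#'
#' @param norm Acceleration-norm series in g, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of the 12 features (the 50th percentile
#'   doubles as the median).
#' @export
extract_features <- function(norm, fs = 100) {
  n <- length(norm)
  if (n < 2L) stop("feature extraction requires at least 2 samples", call. = FALSE)
  if (any(!is.finite(norm))) stop("non-finite values in norm series", call. = FALSE)
  m <- mean(norm)
  centered <- norm - m
  m2 <- mean(centered^2)
  qs <- unname(stats::quantile(norm, c(0.10, 0.50, 0.95), type = 7))
  if (m2 > 0) {
    skew <- mean(centered^3) / m2^1.5
    kurt <- mean(centered^4) / m2^2 - 3
    pg <- periodogram_onesided(norm, fs)
    total <- sum(pg$power)
    if (total > 0) {
      p <- pg$power / total
      avg_freq <- sum(pg$freq * p)
      nz <- p > 0
      entropy <- -sum(p[nz] * log2(p[nz]))
    } else {
      avg_freq <- 0
      entropy <- 0
    }
  } else {
    skew <- 0
    kurt <- 0
    avg_freq <- 0
    entropy <- 0
  }
  out <- c(m, sqrt(m2), qs[1], qs[2], qs[3], min(norm), max(norm),
           skew, kurt, sqrt(mean(norm^2)), avg_freq, entropy)
  names(out) <- FEATURE_NAMES
  out
}

#' Feature matrix for a set of segments
#'
#' Stacks [extract_features()] over labeled segments, one row per segment in
#' input order.
#'
#' @param segments List of segments from [segment_session()] or
#'   [segment_recording()]; every segment must carry a resolved label.
#' @param fs Sampling rate in Hz.
#' @return A list with `X` (numeric matrix, segments x 12) and `y`
#'   (character label vector).
#' @export
feature_matrix <- function(segments, fs = 100) {
  if (length(segments) == 0L) {
    return(list(X = matrix(numeric(0), 0, length(FEATURE_NAMES),
                           dimnames = list(NULL, FEATURE_NAMES)),
                y = character(0)))
  }
  labs <- vapply(segments, function(s) s$label, character(1))
  if (any(labs == "unlabeled")) {
    stop("unlabeled segment at position ", which(labs == "unlabeled")[1],
         "; filter before building the feature matrix", call. = FALSE)
  }
  X <- t(vapply(segments, function(s) extract_features(s$norm, fs),
                numeric(length(FEATURE_NAMES))))
  colnames(X) <- FEATURE_NAMES
  list(X = X, y = labs)
}
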