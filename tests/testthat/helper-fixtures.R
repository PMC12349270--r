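# Shared fixture builders. Everything is generated in code; no stored data.

# A small valid recording with deterministic pseudo-random channels.
make_recording <- function(n = 100, fs = 100, position = "head", seed = 1,
                           gyro = FALSE) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  imu_recording(
    t = t, ax = rnorm(n), ay = rnorm(n), az = rnorm(n),
    position = position, fs = fs,
    recording_id = paste0("fix", seed),
    gx = if (gyro) rnorm(n), gy = if (gyro) rnorm(n),
    gz = if (gyro) rnorm(n)
  )
}

# A reduced protocol for fast end-to-end tests.
small_protocol <- function(n_participants = 1, positions = "head") {
  default_protocol(n_participants = n_participants, positions = positions)
}

# Independent brute-force split oracle: enumerates every (feature, midpoint)
# candidate with plain loops and the textbook weighted-Gini formula. Kept
# deliberately separate from the package's vectorised search.
brute_force_split <- function(X, y) {
  gini_counts <- function(labs) {
    p <- table(labs) / length(labs)
    1 - sum(p^2)
  }
  n <- nrow(X)
  parent <- gini_counts(y)
  best <- NULL
  best_dec <- 1e-12  # same zero-decrease floor as the implementation
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- X[, j] <= thr
      nl <- sum(left)
      pl <- sum(y[left] == "aggressive")
      nr <- n - nl
      pr <- sum(y == "aggressive") - pl
      gl <- 1 - (pl / nl)^2 - ((nl - pl) / nl)^2
      gr <- 1 - (pr / nr)^2 - ((nr - pr) / nr)^2
      dec <- parent - (nl * gl + nr * gr) / n
      if (dec > best_dec) {
        best_dec <- dec
        best <- list(feature_index = j, threshold = thr,
                     impurity_decrease = dec)
      }
    }
  }
  best
}
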