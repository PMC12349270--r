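test_that("acceleration norm is the per-sample Euclidean magnitude", {
  expect_equal(acceleration_norm(3, 4, 0), 5)
  expect_equal(acceleration_norm(0, 0, 0), 0)
  expect_equal(acceleration_norm(c(1, 2), c(2, 3), c(2, 6)), c(3, 7))
  expect_error(acceleration_norm(1:3, 1:2, 1:3), "equal length")
})

test_that("degenerate and hand-computed feature values are exact", {
  const <- extract_features(rep(2.5, 100), fs = 100)
  expect_equal(unname(const[c("mean_g", "p10_g", "p50_g", "p95_g",
                              "min_g", "max_g", "rms_g")]),
               rep(2.5, 7))
  expect_equal(unname(const[c("std_g", "skewness", "kurtosis",
                              "avg_freq_hz", "entropy_bits")]),
               rep(0, 5))

  f <- extract_features(c(1, 2, 3, 4, 5), fs = 100)
  expect_equal(unname(f["mean_g"]), 3)
  expect_equal(unname(f["min_g"]), 1)
  expect_equal(unname(f["max_g"]), 5)
  expect_equal(unname(f["p50_g"]), 3)
  expect_equal(unname(f["rms_g"]), sqrt(11))          # (1+4+9+16+25)/5
  expect_equal(unname(f["std_g"]), sqrt(2))           # population variance 2
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 6.8 / 4 - 3)    # m4/m2^2 - 3

  expect_error(extract_features(1), "at least 2")
})

test_that("average frequency recovers a single tone", {
  fs <- 100
  t <- (0:299) / fs
  x <- 1.5 + 0.8 * sin(2 * pi * 4 * t)     # 4 Hz tone on an offset
  f <- extract_features(x, fs)
  expect_equal(unname(f["avg_freq_hz"]), 4.0, tolerance = 0.2)
  # a single spectral line has zero spectral entropy
  expect_lt(unname(f["entropy_bits"]), 1e-6)

  # entropy grows toward the flat-spectrum maximum for white noise
  set.seed(1)
  fn <- extract_features(rnorm(300), fs)
  expect_gt(unname(fn["entropy_bits"]), 5)
  expect_lte(unname(fn["entropy_bits"]), log2(150))
})

test_that("feature vectors are rotation invariant", {
  p <- default_protocol()
  for (seed in 1:10) {
    sim <- simulate_task(as.list(p$tasks[(seed %% 18) + 1, ]), "head",
                         seed = seed)
    rec <- sim$recording
    rot <- rotate_recording(rec, random_orientation(seed + 100))
    f1 <- extract_features(acceleration_norm(rec$ax, rec$ay, rec$az)[1:300])
    f2 <- extract_features(acceleration_norm(rot$ax, rot$ay, rot$az)[1:300])
    expect_lt(max(abs(f1 - f2)), 1e-9)
  }
})

test_that("features scale and order as the statistics demand", {
  set.seed(42)
  scale_cols <- c("mean_g", "std_g", "p10_g", "p50_g", "p95_g", "min_g",
                  "max_g", "rms_g")
  shape_cols <- c("skewness", "kurtosis")
  for (i in 1:25) {
    x <- abs(rnorm(300, mean = 2)) + 0.1
    f <- extract_features(x, 100)
    # percentile ordering invariant
    expect_true(f["min_g"] <= f["p10_g"] && f["p10_g"] <= f["p50_g"] &&
                  f["p50_g"] <= f["p95_g"] && f["p95_g"] <= f["max_g"])
    expect_gte(unname(f["rms_g"]), abs(unname(f["mean_g"])))
    expect_gte(unname(f["std_g"]), 0)
    expect_gte(unname(f["entropy_bits"]), 0)
    # scale equivariance under k > 0
    k <- runif(1, 0.5, 4)
    fk <- extract_features(k * x, 100)
    expect_equal(unname(fk[scale_cols]), unname(k * f[scale_cols]),
                 tolerance = 1e-9)
    expect_equal(unname(fk[shape_cols]), unname(f[shape_cols]),
                 tolerance = 1e-9)
  }
})

test_that("the feature matrix preserves segment order and rejects unlabeled", {
  sess <- simulate_session(small_protocol(), seed = 12)
  segs <- segment_session(sess)$head
  fm <- feature_matrix(segs)
  expect_equal(dim(fm$X), c(18 * 7, 12))
  expect_equal(length(fm$y), 18 * 7)

  perm <- sample(length(segs))
  fm2 <- feature_matrix(segs[perm])
  expect_equal(fm2$X, fm$X[perm, ])
  expect_equal(fm2$y, fm$y[perm])

  empty <- feature_matrix(list())
  expect_equal(dim(empty$X), c(0, 12))

  bad <- segs
  bad[[3]]$label <- "unlabeled"
  expect_error(feature_matrix(bad), "unlabeled")
})

test_that("aggressive segments carry higher RMS than light ones", {
  sess <- simulate_session(small_protocol(n_participants = 8,
                                          positions = c("head", "chest")),
                           seed = 2)
  entries_label <- vapply(sess$entries, function(e) e$events$label[1],
                          character(1))
  rms_of <- function(e) {
    norm <- acceleration_norm(e$recording$ax, e$recording$ay, e$recording$az)
    w <- sliding_windows(length(norm), 100)
    vapply(seq_len(nrow(w)), function(i)
      extract_features(norm[(w[i, 1] + 1):w[i, 2]], 100)["rms_g"], numeric(1))
  }
  agg_rms <- unlist(lapply(sess$entries[entries_label == "aggressive"], rms_of))
  light_rms <- unlist(lapply(sess$entries[entries_label == "light"], rms_of))
  expect_gt(length(agg_rms) + length(light_rms), 1000)
  expect_gt(mean(agg_rms), mean(light_rms))
})
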