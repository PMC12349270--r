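test_that("default protocol matches the study design", {
  p <- default_protocol()
  expect_equal(nrow(p$tasks), 18)
  expect_equal(sum(p$tasks$risk == "high_risk"), 7)
  expect_equal(sort(p$tasks$task_id[p$tasks$risk == "high_risk"]),
               c(2, 4, 6, 7, 8, 10, 13))
  expect_equal(sum(p$tasks$care_class == "daily_care"), 5)
  expect_equal(p$tasks$task_id[p$tasks$care_class == "daily_care"], 14:18)
  # all high-risk tasks are shaking movements
  expect_true(all(p$tasks$care_class[p$tasks$risk == "high_risk"] == "shaking"))
  expect_equal(p$n_participants, 8)
  expect_equal(p$positions, sensor_positions())
  expect_equal(unique(p$tasks$duration_s), 15)
})

test_that("motion parameter validation rejects non-separating ranges", {
  expect_s3_class(motion_params(), "motion_params")
  expect_error(motion_params(amp_g = c(0.5, 1)), "above")
  expect_error(motion_params(light_amp_g = c(0.3, 3)), "below")
  expect_error(motion_params(attenuation = 0), "magnitudes")
  expect_error(motion_params(amp_g = c(6, 3)), "nondecreasing")
})

test_that("random orientations are proper rotations preserving the norm", {
  expect_equal(random_orientation(NULL), diag(3))
  for (seed in 1:20) {
    R <- random_orientation(seed)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
  # composition of rotations is a rotation
  R12 <- random_orientation(1) %*% random_orientation(2)
  expect_equal(det(R12), 1, tolerance = 1e-9)

  rec <- make_recording(n = 200, seed = 5)
  before <- acceleration_norm(rec$ax, rec$ay, rec$az)
  rot <- rotate_recording(rec, random_orientation(9))
  after <- acceleration_norm(rot$ax, rot$ay, rot$az)
  expect_lt(max(abs(after - before)), 1e-9)
})

test_that("simulated tasks have the protocol geometry and labels", {
  p <- default_protocol()
  sim <- simulate_task(as.list(p$tasks[2, ]), "head", seed = 1)
  expect_equal(n_samples(sim$recording), 1500)  # 15 s at 100 Hz
  expect_equal(sim$recording$fs, 100)
  expect_equal(nrow(sim$events), 1)
  expect_equal(sim$events$label, "aggressive")
  expect_equal(c(sim$events$start_s, sim$events$end_s), c(0, 15))

  expect_equal(simulate_task(as.list(p$tasks[1, ]), "head",
                             seed = 1)$events$label, "light")
  expect_equal(simulate_task(as.list(p$tasks[17, ]), "head",
                             seed = 1)$events$label, "daily_care")
})

test_that("a motionless noiseless task has norm identically gravity", {
  p <- default_protocol()
  params <- motion_params(amp_g = c(3, 6), light_amp_g = c(0, 0),
                          noise_sd_g = 0)
  sim <- simulate_task(as.list(p$tasks[1, ]), "chest", params, seed = 2)
  norm <- acceleration_norm(sim$recording$ax, sim$recording$ay,
                            sim$recording$az)
  expect_lt(max(abs(norm - 1)), 1e-9)
})

test_that("peak norm separates risk classes across 100 simulations each", {
  p <- default_protocol()
  params <- motion_params()
  high <- p$tasks[p$tasks$risk == "high_risk", ]
  low <- p$tasks[p$tasks$risk == "no_risk", ]
  peak <- function(task, seed) {
    sim <- simulate_task(as.list(task), "head", params, seed = seed)
    max(acceleration_norm(sim$recording$ax, sim$recording$ay,
                          sim$recording$az))
  }
  agg_peaks <- vapply(1:100, function(s)
    peak(high[(s %% nrow(high)) + 1, ], s), numeric(1))
  ben_peaks <- vapply(101:200, function(s)
    peak(low[(s %% nrow(low)) + 1, ], s), numeric(1))
  expect_true(all(agg_peaks > params$threshold_g))
  expect_true(all(ben_peaks < params$threshold_g))
})

test_that("sessions are seed-reproducible and correctly counted", {
  proto <- small_protocol(n_participants = 2,
                          positions = c("head", "left_leg"))
  s1 <- simulate_session(proto, seed = 5)
  s2 <- simulate_session(proto, seed = 5)
  s3 <- simulate_session(proto, seed = 6)
  expect_equal(length(s1$entries), 2 * 18 * 2)
  expect_identical(s1$entries[[10]]$recording$ax, s2$entries[[10]]$recording$ax)
  expect_false(identical(s1$entries[[10]]$recording$ax,
                         s3$entries[[10]]$recording$ax))

  counts <- session_counts(s1)
  expect_equal(counts$n_tasks, 36)
  expect_equal(counts$n_aggressive, 14)
  expect_equal(counts$n_recordings, 72)

  one <- simulate_session(small_protocol(), seed = 1)
  expect_equal(session_counts(one)$n_recordings, 18)
})

test_that("every sample of every simulated recording is inside one event", {
  sess <- simulate_session(small_protocol(n_participants = 1), seed = 4)
  for (entry in sess$entries) {
    t <- entry$recording$t
    ev <- entry$events
    inside <- rowSums(outer(t, ev$start_s, ">=") &
                        outer(t, ev$end_s, "<")) # [start, end)
    expect_true(all(inside == 1))
  }
})
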