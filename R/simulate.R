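# Synthetic IMU motion model. The norm-relevant signal is a gravity vector in
# a fixed random sensor orientation plus a sinusoid directed along the task's
# shake axis with per-cycle amplitude/frequency jitter, plus white noise.
# Aggressive and light amplitude ranges are chosen so that, at unit
# attenuation, the peak acceleration norm of every aggressive task exceeds
# the LED-analogue threshold and every benign task stays below it:
# peak >= sqrt(gravity^2 + amp^2) when the oscillation reverses sign, so the
# aggressive worst case (3 g * 0.9 jitter) gives 2.88 g > 2.5 g, while the
# light worst case is bounded by gravity + 1.1 g + noise < 2.5 g.

#' Motion-model parameters
#'
#' Amplitude and frequency ranges for the simulated shaking oscillation, the
#' additive sensor noise level, and the acceleration threshold standing in
#' for the training doll's LED feedback.
#'
#' @param shake_freq_hz Length-2 aggressive frequency range in Hz.
#' @param light_freq_hz Length-2 light-shaking frequency range in Hz.
#' @param amp_g Length-2 aggressive oscillation amplitude range in g.
#' @param light_amp_g Length-2 light-shaking amplitude range in g.
#' @param care_freq_hz,care_amp_g Daily-care motion ranges (low and slow).
#' @param noise_sd_g Additive white-noise standard deviation per axis, in g.
#' @param gravity_g Gravity magnitude in g.
#' @param attenuation Amplitude multiplier in (0, 1] for the sensor position.
#' @param threshold_g Norm threshold above which movement counts as
#'   harmful (the LED analogue).
#' @param jitter Per-cycle fractional amplitude/frequency jitter.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(shake_freq_hz = c(3, 5), light_freq_hz = c(1, 2),
                          amp_g = c(3, 6), light_amp_g = c(0.3, 1.0),
                          care_freq_hz = c(0.3, 1), care_amp_g = c(0.1, 0.5),
                          noise_sd_g = 0.05, gravity_g = 1.0,
                          attenuation = 1.0, threshold_g = 2.5,
                          jitter = 0.1) {
  p <- list(shake_freq_hz = shake_freq_hz, light_freq_hz = light_freq_hz,
            amp_g = amp_g, light_amp_g = light_amp_g,
            care_freq_hz = care_freq_hz, care_amp_g = care_amp_g,
            noise_sd_g = noise_sd_g, gravity_g = gravity_g,
            attenuation = attenuation, threshold_g = threshold_g,
            jitter = jitter)
  ranges <- p[c("shake_freq_hz", "light_freq_hz", "amp_g", "light_amp_g",
                "care_freq_hz", "care_amp_g")]
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(r < 0) || r[2] < r[1]) {
      stop("`", nm, "` must be a nondecreasing nonnegative range", call. = FALSE)
    }
  }
  if (noise_sd_g < 0 || gravity_g < 0 || threshold_g <= 0 ||
      attenuation <= 0 || attenuation > 1 || jitter < 0 || jitter >= 1) {
    stop("invalid motion parameter magnitudes", call. = FALSE)
  }
  # separation by construction (at unit attenuation)
  agg_min_peak <- sqrt(gravity_g^2 + (amp_g[1] * (1 - jitter))^2)
  light_max_peak <- gravity_g + light_amp_g[2] * (1 + jitter)
  if (agg_min_peak <= threshold_g) {
    stop("aggressive amplitude range cannot guarantee peak norm above ",
         "threshold_g", call. = FALSE)
  }
  if (light_max_peak >= threshold_g) {
    stop("light amplitude range cannot guarantee peak norm below ",
         "threshold_g", call. = FALSE)
  }
  class(p) <- "motion_params"
  p
}

#' Random proper rotation
#'
#' Draws a uniformly random 3x3 rotation matrix (orthonormal, determinant
#' +1) used to give each simulated recording an arbitrary fixed sensor
#' orientation. With `seed = NULL` the identity is returned.
#'
#' @param seed Integer seed, or `NULL` for the identity rotation.
#' @return A 3x3 rotation matrix.
#' @export
random_orientation <- function(seed = NULL) {
  if (is.null(seed)) return(diag(3))
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  d <- sign(diag(qr.R(qr_out)))
  d[d == 0] <- 1
  q <- q %*% diag(d)   # make the decomposition unique
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Rotate the acceleration axes of a recording
#'
#' Applies a fixed rotation to the (ax, ay, az) channels; the acceleration
#' norm is invariant under this operation.
#'
#' @param rec An `imu_recording`.
#' @param rot A 3x3 rotation matrix.
#' @return The rotated `imu_recording`.
#' @export
rotate_recording <- function(rec, rot) {
  stopifnot(inherits(rec, "imu_recording"), all(dim(rot) == c(3, 3)))
  a <- rot %*% rbind(rec$ax, rec$ay, rec$az)
  rec$ax <- a[1, ]
  rec$ay <- a[2, ]
  rec$az <- a[3, ]
  rec
}

axis_direction <- function(shake_axis, rng_dir = NULL) {
  switch(shake_axis,
         vertical = c(0, 0, 1),
         fore_aft = c(1, 0, 0),
         lateral  = c(0, 1, 0),
         mixed    = {
           v <- rng_dir
           v / sqrt(sum(v^2))
         },
         stop("unknown shake axis: ", shake_axis, call. = FALSE))
}

# Oscillation with per-cycle amplitude/frequency jitter: each cycle draws its
# own frequency and amplitude multiplier in [1 - jitter, 1 + jitter].
jittered_oscillation <- function(t, base_freq, base_amp, jitter) {
  n <- length(t)
  s <- numeric(n)
  if (base_amp <= 0 || base_freq <= 0 || n == 0L) return(s)
  t0 <- t[1]
  t_end <- t[n]
  while (t0 <= t_end) {
    f <- base_freq * stats::runif(1, 1 - jitter, 1 + jitter)
    a <- base_amp * stats::runif(1, 1 - jitter, 1 + jitter)
    period <- 1 / f
    idx <- which(t >= t0 & t < t0 + period)
    s[idx] <- a * sin(2 * pi * f * (t[idx] - t0))
    t0 <- t0 + period
  }
  s
}

# Half-sine impulse of given width centred at tc, added along a direction.
impulse <- function(t, tc, width, amp) {
  u <- (t - (tc - width / 2)) / width
  ifelse(u >= 0 & u <= 1, amp * sin(pi * u), 0)
}

#' Simulate one task recording
#'
#' Generates the triaxial acceleration time series and its single
#' ground-truth annotation event for one (task, sensor position) pair.
#' High-risk tasks oscillate at 3-5 Hz with 3-6 g amplitude, light shaking
#' at 1-2 Hz with 0.3-1 g, and daily-care tasks at 0.3-1 Hz below 0.5 g.
#' The throw-and-catch task contains a free-fall dip (norm near zero)
#' followed by a catch impulse; the burping task adds brief patting
#' impulses. Deterministic for a fixed seed.
#'
#' @param task One row of a protocol's `tasks` data.frame, as a list.
#' @param position Sensor position.
#' @param params A `motion_params` object.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @param base_amp,base_freq Optional participant-level oscillation values;
#'   drawn from the class's range when `NULL`.
#' @param participant_id,recording_id Identifier strings.
#' @return A list with elements `recording` (an `imu_recording`) and
#'   `events` (an `annotation_events` data.frame with one row).
#' @export
simulate_task <- function(task, position, params = motion_params(),
                          seed = 1L, fs = 100,
                          base_amp = NULL, base_freq = NULL,
                          participant_id = "p1",
                          recording_id = NULL) {
  stopifnot(inherits(params, "motion_params"))
  assert_position(position)
  task <- as.list(task)
  set.seed(seed)
  n <- round(task$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs

  label <- task_label(task)
  ranges <- switch(label,
    aggressive = list(freq = params$shake_freq_hz, amp = params$amp_g),
    light      = list(freq = params$light_freq_hz, amp = params$light_amp_g),
    daily_care = list(freq = params$care_freq_hz, amp = params$care_amp_g))
  freq <- base_freq %||% stats::runif(1, ranges$freq[1], ranges$freq[2])
  amp <- (base_amp %||% stats::runif(1, ranges$amp[1], ranges$amp[2])) *
    params$attenuation

  rot <- random_orientation(derive_seed(seed, 7L))
  set.seed(derive_seed(seed, 11L))
  gvec <- params$gravity_g * as.vector(rot %*% c(0, 0, 1))
  axis <- if (is.na(task$shake_axis %||% NA)) "mixed" else task$shake_axis
  dvec <- as.vector(rot %*% axis_direction(axis, stats::rnorm(3)))

  osc <- jittered_oscillation(t, freq, amp, params$jitter)
  if (task$task_id == 11L) {
    # the hold oscillation pauses around each throw
    for (tc in seq(2.5, task$duration_s - 2, by = 4)) {
      osc[t >= tc - 0.1 & t < tc + 0.8] <- 0
    }
  }
  acc <- outer(gvec, rep(1, n)) + outer(dvec, osc)

  if (task$task_id == 11L) {
    # throw-and-catch: gentle hold, ~0.4 s free fall (specific force -> 0),
    # then a catch impulse; repeated a few times across the 15 s
    for (tc in seq(2.5, task$duration_s - 2, by = 4)) {
      fall <- t >= tc & t < tc + 0.4
      acc[, fall] <- 0
      catch <- impulse(t, tc + 0.5, 0.15, 1.0 * params$attenuation)
      acc <- acc + outer(gvec / params$gravity_g, catch)
    }
  }
  if (task$task_id == 17L) {
    # burping: brief pats on the back at ~1.2 s spacing
    for (tc in seq(1, task$duration_s - 0.5, by = 1.2)) {
      acc <- acc + outer(dvec, impulse(t, tc, 0.08,
                                       0.6 * params$attenuation))
    }
  }

  acc <- acc + matrix(stats::rnorm(3 * n, sd = params$noise_sd_g), 3, n)

  rec <- imu_recording(
    t = t, ax = acc[1, ], ay = acc[2, ], az = acc[3, ],
    position = position, fs = fs,
    recording_id = recording_id %||%
      sprintf("%s_t%02d_%s", participant_id, task$task_id, position),
    participant_id = participant_id, task_id = task$task_id
  )
  events <- annotation_events(label, 0, task$duration_s)
  list(recording = rec, events = events)
}

# Position-dependent transmissibility of the oscillation. Trunk-driven
# shaking reaches the limbs attenuated; arm-swing tasks (9, 10) drive the
# arms directly and reach the trunk and legs weakly. Daily-care tasks are
# gentle whole-body handling, unattenuated.
position_attenuation <- function(task_id, position) {
  arm_swing <- task_id %in% c(9L, 10L)
  if (task_id >= 14L) return(1.0)
  if (arm_swing) {
    if (position %in% c("left_arm", "right_arm")) 1.0 else 0.6
  } else {
    switch(position,
           head = 1.0, chest = 1.0,
           left_arm = 0.9, right_arm = 0.9,
           left_leg = 0.8, right_leg = 0.8)
  }
}

#' Simulate a full data-collection session
#'
#' Runs every (participant, task, position) combination of the protocol
#' through [simulate_task()]. Participants get their own base oscillation
#' amplitude and frequency drawn from the parameter ranges; sensor positions
#' attenuate the transmitted oscillation. With the default protocol this
#' produces 8 x 18 = 144 tasks and 864 recordings. When `dir` is given, the
#' recordings, annotation files and a JSON manifest are written there;
#' otherwise the session stays in memory. Fully reproducible per seed.
#'
#' @param protocol A `protocol` object from [default_protocol()].
#' @param params A `motion_params` object.
#' @param seed Integer seed.
#' @param dir Optional output directory for CSV files and the manifest.
#' @param fs Sampling rate in Hz.
#' @return An `imu_session`; when `dir` is given it carries a
#'   `manifest` attribute with the manifest path.
#' @export
simulate_session <- function(protocol = default_protocol(),
                             params = motion_params(), seed = 1L,
                             dir = NULL, fs = 100) {
  stopifnot(inherits(protocol, "protocol"))
  tasks <- protocol$tasks
  write_out <- !is.null(dir)
  if (write_out && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }

  entries <- list()
  manifest_rows <- list()
  k <- 0L
  for (pi in seq_len(protocol$n_participants)) {
    pid <- sprintf("p%02d", pi)
    # participant-level base motion per task class
    set.seed(derive_seed(seed, pi))
    base <- list(
      aggressive = c(stats::runif(1, params$amp_g[1], params$amp_g[2]),
                     stats::runif(1, params$shake_freq_hz[1],
                                  params$shake_freq_hz[2])),
      light = c(stats::runif(1, params$light_amp_g[1], params$light_amp_g[2]),
                stats::runif(1, params$light_freq_hz[1],
                             params$light_freq_hz[2])),
      daily_care = c(stats::runif(1, params$care_amp_g[1], params$care_amp_g[2]),
                     stats::runif(1, params$care_freq_hz[1],
                                  params$care_freq_hz[2]))
    )
    for (ti in seq_len(nrow(tasks))) {
      task <- as.list(tasks[ti, ])
      b <- base[[task_label(task)]]
      ann_path <- NULL
      for (pos_i in seq_along(protocol$positions)) {
        pos <- protocol$positions[pos_i]
        p_pos <- params
        p_pos$attenuation <- params$attenuation *
          position_attenuation(task$task_id, pos)
        sim <- simulate_task(
          task, pos, p_pos,
          seed = derive_seed(seed, pi, task$task_id, pos_i),
          fs = fs, base_amp = b[1], base_freq = b[2],
          participant_id = pid
        )
        k <- k + 1L
        entries[[k]] <- sim
        if (write_out) {
          rec_file <- sprintf("%s_t%02d_%s.csv", pid, task$task_id, pos)
          write_recording(sim$recording, file.path(dir, rec_file))
          if (is.null(ann_path)) {
            ann_path <- sprintf("%s_t%02d_events.csv", pid, task$task_id)
            write_annotations(sim$events, file.path(dir, ann_path))
          }
          manifest_rows[[k]] <- data.frame(
            recording = rec_file, annotations = ann_path,
            participant_id = pid, task_id = task$task_id, position = pos,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  session <- structure(
    list(session_id = sprintf("sim_seed%d", seed), seed = seed,
         entries = entries),
    class = "imu_session")
  if (write_out) {
    manifest <- do.call(rbind, manifest_rows)
    mpath <- file.path(dir, "manifest.json")
    write_manifest(manifest, mpath, session_id = session$session_id,
                   seed = seed)
    attr(session, "manifest") <- mpath
  }
  session
}

#' Session bookkeeping counts
#'
#' Tallies the session the way a study log would: number of performed tasks
#' (participant x task pairs), how many were aggressive vs non-aggressive,
#' and the total recording count across sensor positions.
#'
#' @param session An `imu_session`.
#' @return A list with `n_tasks`, `n_aggressive`, `n_non_aggressive`,
#'   `n_recordings`.
#' @export
session_counts <- function(session) {
  key <- vapply(session$entries, function(e)
    paste(e$recording$participant_id, e$recording$task_id), character(1))
  lab <- vapply(session$entries, function(e) e$events$label[1], character(1))
  first <- !duplicated(key)
  list(
    n_tasks = sum(first),
    n_aggressive = sum(lab[first] == "aggressive"),
    n_non_aggressive = sum(lab[first] != "aggressive"),
    n_recordings = length(session$entries)
  )
}
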