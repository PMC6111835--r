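# Deterministic synthetic skeletal-motion generator. Emulates a 30 Hz
# depth-camera body-tracking stream for each supported exercise and
# returns the planted ground truth alongside, so every detector can be
# tested against sessions whose correct answer is known by construction.

#' Describe a synthetic exercise session
#'
#' A motion plan fixes everything about a generated session: the exercise,
#' how many repetitions (or, for balance, the per-direction compliance
#' fractions), movement amplitude and cadence, sensor-like imperfections
#' (additive position noise, angle noise, tracking dropouts) and the RNG
#' seed. The same plan and seed always produce a bit-identical stream.
#'
#' Noise is applied to *positions* (angle noise is realized geometrically
#' by perturbing the planned rotation before moving the distal joints), so
#' detectors only ever see joint positions, exactly as with a real sensor.
#'
#' @param exercise One of `"elbow"`, `"squat"`, `"step"`, `"balance"`.
#' @param repetitions Planted repetitions (flexion sessions) or climbs
#'   (step sessions). Ignored for balance.
#' @param amplitude Peak deviation angle in degrees reached by each
#'   repetition (elbow default 150, i.e. the elbow closes to a 30 degree
#'   interior angle; squat and step knee default 85 and 80).
#' @param cadence Repetitions per minute for flexion sessions (default 12,
#'   a deliberate rehabilitation pace).
#' @param side Stepping foot for step sessions, `"right"` or `"left"`.
#' @param step_height Hip elevation per climb in meters (default 0.15).
#' @param compliance Numeric vector of 8 fractions in \[0, 1\]: the share
#'   of each direction's window the subject holds the COM on target.
#' @param level Balance difficulty level (1-3).
#' @param noise_pos Standard deviation (m) of isotropic Gaussian jitter
#'   added to every joint coordinate (default 0).
#' @param noise_angle Standard deviation (degrees) of per-frame jitter on
#'   the planned joint rotation (default 0).
#' @param dropout_rate Per-joint, per-frame probability of a `NotTracked`
#'   flag (default 0).
#' @param dropout_joints Joints subject to dropout (default: all 25).
#' @param seed Integer RNG seed (default 1).
#' @param sample_rate Stream sampling rate in Hz (default 30).
#' @param height Subject height in meters (default 1.72, the study
#'   controls' mean).
#' @param mass_kg Subject mass in kg (default 67, the controls' mean).
#' @return A `motion_plan` object.
#' @export
motion_plan <- function(exercise = c("elbow", "squat", "step", "balance"),
                        repetitions = 5, amplitude = NULL, cadence = 12,
                        side = c("right", "left"), step_height = 0.15,
                        compliance = rep(1, 8), level = 1,
                        noise_pos = 0, noise_angle = 0,
                        dropout_rate = 0, dropout_joints = NULL,
                        seed = 1, sample_rate = 30,
                        height = 1.72, mass_kg = 67) {
  exercise <- match.arg(exercise)
  side <- match.arg(side)
  if (is.null(amplitude))
    amplitude <- switch(exercise, elbow = 150, squat = 85, step = 80, balance = NA_real_)
  stopifnot(repetitions >= 0, cadence > 0, step_height > 0,
            length(compliance) == 8, all(compliance >= 0 & compliance <= 1),
            noise_pos >= 0, noise_angle >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            sample_rate > 0, height > 0, mass_kg > 0)
  if (!is.null(dropout_joints))
    stopifnot(all(dropout_joints %in% kinect_joint_names()))
  structure(list(exercise = exercise, repetitions = as.integer(repetitions),
                 amplitude = amplitude, cadence = cadence, side = side,
                 step_height = step_height, compliance = compliance,
                 level = as.integer(level),
                 noise_pos = noise_pos, noise_angle = noise_angle,
                 dropout_rate = dropout_rate, dropout_joints = dropout_joints,
                 seed = as.integer(seed), sample_rate = sample_rate,
                 height = height, mass_kg = mass_kg),
            class = "motion_plan")
}

# Internal: rest-pose joint coordinates for a standing subject of the
# given height, facing the sensor at z = 2.5 m, feet near the floor.
# Proportions are fixed fractions of stature; arms hang straight so the
# elbow deviation angle is exactly 0, and legs are straight so the knee
# deviation is 0. Right-side joints sit at +x (the subject's right).
base_pose <- function(height) {
  h <- height
  z0 <- 2.5
  sh <- 0.18 * h   # shoulder half-width
  hp <- 0.09 * h   # hip half-width
  m <- rbind(
    SpineBase     = c(0,  0.580 * h, z0),
    SpineMid      = c(0,  0.690 * h, z0),
    Neck          = c(0,  0.840 * h, z0),
    Head          = c(0,  0.930 * h, z0),
    SpineShoulder = c(0,  0.800 * h, z0),
    ShoulderLeft  = c(-sh, 0.800 * h, z0),
    ElbowLeft     = c(-sh, 0.614 * h, z0),
    WristLeft     = c(-sh, 0.468 * h, z0),
    HandLeft      = c(-sh, 0.438 * h, z0),
    HandTipLeft   = c(-sh, 0.393 * h, z0),
    ThumbLeft     = c(-sh + 0.02 * h, 0.450 * h, z0 - 0.01 * h),
    ShoulderRight = c(sh, 0.800 * h, z0),
    ElbowRight    = c(sh, 0.614 * h, z0),
    WristRight    = c(sh, 0.468 * h, z0),
    HandRight     = c(sh, 0.438 * h, z0),
    HandTipRight  = c(sh, 0.393 * h, z0),
    ThumbRight    = c(sh - 0.02 * h, 0.450 * h, z0 - 0.01 * h),
    HipLeft       = c(-hp, 0.530 * h, z0),
    KneeLeft      = c(-hp, 0.285 * h, z0),
    AnkleLeft     = c(-hp, 0.050 * h, z0),
    FootLeft      = c(-hp, 0.020 * h, z0 - 0.06 * h),
    HipRight      = c(hp, 0.530 * h, z0),
    KneeRight     = c(hp, 0.285 * h, z0),
    AnkleRight    = c(hp, 0.050 * h, z0),
    FootRight     = c(hp, 0.020 * h, z0 - 0.06 * h))
  colnames(m) <- c("x", "y", "z")
  m[kinect_joint_names(), , drop = FALSE]
}

#' Neutral standing pose as a one-frame skeleton
#'
#' Builds a single `Tracked` frame of all 25 joints for a subject of the
#' given height standing 2.5 m from the sensor, feet near the floor and
#' the hip center near y = 1.0 m for a typical adult. Proportions scale
#' linearly with height.
#'
#' @param height Standing height in meters.
#' @return Data frame of 25 joint rows (canonical stream columns) at
#'   `time_s = 0`.
#' @export
make_base_skeleton <- function(height = 1.72) {
  stopifnot(height > 0)
  m <- base_pose(height)
  data.frame(time_s = 0, body_id = 0L, joint = rownames(m),
             x_m = m[, "x"], y_m = m[, "y"], z_m = m[, "z"],
             state = "Tracked", row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: run `expr` under a seed without disturbing the caller's RNG.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Internal: assemble per-joint coordinate matrices (n_frames x 25, columns
# in kinect_joint_names() order) into a skeleton_stream, applying position
# noise and dropouts from the plan. Row order: frame-major, joints in
# canonical order within each frame.
assemble_stream <- function(tms, X, Y, Z, plan) {
  joints <- kinect_joint_names()
  n <- length(tms)
  J <- length(joints)
  state <- matrix("Tracked", n, J)
  if (plan$noise_pos > 0 || plan$dropout_rate > 0) {
    with_rng(plan$seed, {
      if (plan$noise_pos > 0) {
        X <- X + matrix(stats::rnorm(n * J, 0, plan$noise_pos), n, J)
        Y <- Y + matrix(stats::rnorm(n * J, 0, plan$noise_pos), n, J)
        Z <- Z + matrix(stats::rnorm(n * J, 0, plan$noise_pos), n, J)
      }
      if (plan$dropout_rate > 0) {
        cols <- if (is.null(plan$dropout_joints)) seq_len(J)
                else match(plan$dropout_joints, joints)
        drop_mask <- matrix(stats::runif(n * length(cols)) < plan$dropout_rate,
                            n, length(cols))
        state[, cols][drop_mask] <- "NotTracked"
      }
    })
  }
  frames <- data.frame(
    time_s = rep(tms, each = J),
    body_id = 0L,
    joint = rep(joints, times = n),
    x_m = as.vector(t(X)), y_m = as.vector(t(Y)), z_m = as.vector(t(Z)),
    state = as.vector(t(state)), stringsAsFactors = FALSE)
  skeleton_stream(frames, sample_rate = plan$sample_rate,
                  subject = subject_profile("synthetic", plan$mass_kg, plan$height),
                  validate = FALSE)
}

# Internal: rotate the listed joints about a pivot joint by per-frame
# angles `theta` (radians) around the x axis (sagittal flexion). X/Y/Z are
# n x 25 matrices modified in place and returned as a list.
rotate_about <- function(X, Y, Z, pivot, moving, theta) {
  joints <- kinect_joint_names()
  pv <- match(pivot, joints)
  ct <- cos(theta)
  st <- sin(theta)
  for (j in match(moving, joints)) {
    oy <- Y[, j] - Y[, pv]
    oz <- Z[, j] - Z[, pv]
    Y[, j] <- Y[, pv] + oy * ct - oz * st
    Z[, j] <- Z[, pv] + oy * st + oz * ct
  }
  list(X = X, Y = Y, Z = Z)
}

# Internal: per-frame planned deviation angle (degrees) for a session of
# `reps` half-sine repetitions at `cadence` per minute, with `lead`
# seconds of rest before and `tail` after.
flexion_profile <- function(tms, reps, amplitude, cadence, lead, tail) {
  period <- 60 / cadence
  t_act <- tms - lead
  delta <- numeric(length(tms))
  act <- t_act >= 0 & t_act < reps * period
  delta[act] <- amplitude * sin(pi * (t_act[act] %% period) / period)
  delta
}

# Internal: cubic smoothstep ramp 0 -> 1 over [t0, t1].
smoothstep <- function(t, t0, t1) {
  s <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  s * s * (3 - 2 * s)
}

distal_arm <- function(side) paste0(c("Wrist", "Hand", "HandTip", "Thumb"), side)
distal_leg <- function(side) paste0(c("Ankle", "Foot"), side)

#' Generate a synthetic flexion/extension session
#'
#' Produces a stream in which both elbows (exercise `"elbow"`) or both
#' knees (exercise `"squat"`) perform `repetitions` half-sine
#' flexion-extension cycles of the planned amplitude, realized by rigidly
#' rotating the distal segments about the apex joint, with 1 s of quiet
#' standing before and after. Angle noise perturbs the planned rotation
#' per frame before the geometry is built; position noise and dropouts are
#' applied afterwards per [motion_plan()].
#'
#' The ground truth reports the planted repetitions as reachable only if
#' the amplitude actually crosses the default detector band for that
#' joint (elbow interior 50/100, knee deviation 70/30); otherwise the
#' session is generated as asked but `reps` is 0 and `reachable` is
#' `FALSE`.
#'
#' @param plan A [motion_plan()] with exercise `"elbow"` or `"squat"`.
#' @return List with `stream` (a [skeleton_stream()]) and `truth` (list:
#'   `exercise`, `reps`, `reps_planned`, `reachable`, `per_side`).
#' @export
gen_flexion_session <- function(plan) {
  stopifnot(inherits(plan, "motion_plan"), plan$exercise %in% c("elbow", "squat"))
  rate <- plan$sample_rate
  lead <- 1
  tail <- 1
  period <- 60 / plan$cadence
  dur <- lead + plan$repetitions * period + tail
  n <- floor(dur * rate) + 1L
  tms <- (seq_len(n) - 1L) / rate
  delta <- flexion_profile(tms, plan$repetitions, plan$amplitude,
                           plan$cadence, lead, tail)
  if (plan$noise_angle > 0)
    delta <- with_rng(plan$seed + 1L, {
      pmin(pmax(delta + stats::rnorm(n, 0, plan$noise_angle), 0), 179)
    })
  pose <- base_pose(plan$height)
  joints <- kinect_joint_names()
  X <- matrix(pose[, "x"], n, 25, byrow = TRUE)
  Y <- matrix(pose[, "y"], n, 25, byrow = TRUE)
  Z <- matrix(pose[, "z"], n, 25, byrow = TRUE)
  colnames(X) <- colnames(Y) <- colnames(Z) <- joints
  theta <- delta * pi / 180
  for (side in c("Left", "Right")) {
    if (plan$exercise == "elbow") {
      r <- rotate_about(X, Y, Z, paste0("Elbow", side), distal_arm(side), theta)
    } else {
      r <- rotate_about(X, Y, Z, paste0("Knee", side), distal_leg(side), theta)
    }
    X <- r$X; Y <- r$Y; Z <- r$Z
  }
  stream <- assemble_stream(tms, X, Y, Z, plan)
  band <- if (plan$exercise == "elbow") deviation_band(flexion_config("elbow"))
          else deviation_band(flexion_config("knee"))
  reachable <- plan$amplitude >= band["flex"]  # rest deviation 0 <= ext band
  reps <- if (reachable) plan$repetitions else 0L
  truth <- list(exercise = plan$exercise, reps = reps,
                reps_planned = plan$repetitions, reachable = reachable,
                per_side = c(left = reps, right = reps))
  list(stream = stream, truth = truth)
}

#' Generate a synthetic step-climb session
#'
#' Each planted climb is a 6 s block: the stepping knee flexes to the
#' planned amplitude and re-extends while the whole body rises by
#' `step_height` (smoothstep ramps), dwells on the block, and descends
#' back to baseline. 2.5 s of quiet standing precede the first block
#' (covering the detector's baseline window) and 1 s follows the last.
#'
#' Ground truth counts the planted climbs as detectable only if the knee
#' amplitude crosses the 70/30 deviation band *and* the step height
#' exceeds the default 0.09 m hip-rise threshold; a hip rise with straight
#' knees (tip-toe artifact) or knee cycles without body rise plant 0.
#'
#' @param plan A [motion_plan()] with exercise `"step"`.
#' @return List with `stream` and `truth` (`climbs`/`descents` per foot).
#' @export
gen_step_session <- function(plan) {
  stopifnot(inherits(plan, "motion_plan"), plan$exercise == "step")
  rate <- plan$sample_rate
  lead <- 2.5
  block <- 6
  dur <- lead + plan$repetitions * block + 1
  n <- floor(dur * rate) + 1L
  tms <- (seq_len(n) - 1L) / rate
  delta <- numeric(n)
  rise <- numeric(n)
  for (k in seq_len(plan$repetitions)) {
    t0 <- lead + (k - 1) * block
    tb <- tms - t0
    delta <- delta + plan$amplitude *
      (smoothstep(tb, 0.3, 1.2) - smoothstep(tb, 1.8, 2.8))
    rise <- rise + plan$step_height *
      (smoothstep(tb, 0.8, 2.2) - smoothstep(tb, 4.0, 5.2))
  }
  if (plan$noise_angle > 0)
    delta <- with_rng(plan$seed + 1L, {
      pmin(pmax(delta + stats::rnorm(n, 0, plan$noise_angle), 0), 179)
    })
  pose <- base_pose(plan$height)
  joints <- kinect_joint_names()
  X <- matrix(pose[, "x"], n, 25, byrow = TRUE)
  Y <- matrix(pose[, "y"], n, 25, byrow = TRUE)
  Z <- matrix(pose[, "z"], n, 25, byrow = TRUE)
  colnames(X) <- colnames(Y) <- colnames(Z) <- joints
  sfx <- if (plan$side == "left") "Left" else "Right"
  r <- rotate_about(X, Y, Z, paste0("Knee", sfx), distal_leg(sfx), delta * pi / 180)
  X <- r$X; Y <- r$Y; Z <- r$Z
  Y <- Y + rise  # whole-body elevation
  stream <- assemble_stream(tms, X, Y, Z, plan)
  cfg <- step_config()
  detectable <- plan$amplitude >= cfg$knee_right$flexion_threshold &&
    plan$step_height >= cfg$hip_rise_threshold
  k <- if (detectable) plan$repetitions else 0L
  climbs <- c(left = 0L, right = 0L)
  climbs[plan$side] <- k
  truth <- list(exercise = "step", side = plan$side, climbs = climbs,
                descents = climbs, planned = plan$repetitions,
                reachable = detectable)
  list(stream = stream, truth = truth)
}

#' Generate a synthetic balance session
#'
#' Builds a whole-body lean trajectory realized as a rigid XZ translation
#' of the skeleton (so the body COM follows it exactly): 2 s of quiet
#' standing for calibration, then for each direction in N..NW order a
#' single frame back at the starting position (which opens the scoring
#' window at the next frame), `round(compliance_d * T * rate)` frames held
#' exactly on the target, and the remainder of the window parked halfway
#' between start and target (off target, off idle). A 1 s idle tail closes
#' the stream.
#'
#' With zero noise and dropout, [score_balance()] under the same
#' [balance_config()] level recovers the planted on-target times exactly.
#'
#' @param plan A [motion_plan()] with exercise `"balance"`; `compliance`
#'   gives the 8 per-direction dwell fractions.
#' @param cfg The [balance_config()] describing the protocol geometry
#'   (defaults to the plan's level with standard geometry).
#' @return List with `stream`, `truth` (`on_target_s`, `scores` per
#'   direction) and `cfg`.
#' @export
gen_balance_session <- function(plan, cfg = balance_config(level = plan$level)) {
  stopifnot(inherits(plan, "motion_plan"), plan$exercise == "balance",
            inherits(cfg, "balance_config"))
  rate <- plan$sample_rate
  Tw <- cfg$time_per_target
  wlen <- round(Tw * rate)              # frames per scoring window
  ncal <- round(cfg$calibration_window * rate)
  dirs <- cfg$directions
  n_on <- round(plan$compliance * wlen)
  n <- ncal + 8L * (wlen + 1L) + round(rate) + 1L
  tms <- (seq_len(n) - 1L) / rate
  offx <- numeric(n)
  offz <- numeric(n)
  for (d in seq_len(8L)) {
    b <- ncal + (d - 1L) * (wlen + 1L) + 1L   # idle trigger frame (1-based)
    tx <- cfg$excursion * dirs$ux[d]
    tz <- cfg$excursion * dirs$uz[d]
    if (n_on[d] > 0) {
      idx_on <- (b + 1L):(b + n_on[d])
      offx[idx_on] <- tx
      offz[idx_on] <- tz
    }
    if (n_on[d] < wlen) {
      idx_off <- (b + n_on[d] + 1L):(b + wlen)
      offx[idx_off] <- tx / 2
      offz[idx_off] <- tz / 2
    }
  }
  pose <- base_pose(plan$height)
  joints <- kinect_joint_names()
  X <- matrix(pose[, "x"], n, 25, byrow = TRUE) + offx
  Y <- matrix(pose[, "y"], n, 25, byrow = TRUE)
  Z <- matrix(pose[, "z"], n, 25, byrow = TRUE) + offz
  colnames(X) <- colnames(Y) <- colnames(Z) <- joints
  stream <- assemble_stream(tms, X, Y, Z, plan)
  on_s <- n_on / rate
  names(on_s) <- dirs$direction
  truth <- list(exercise = "balance", level = cfg$level,
                on_target_s = on_s, scores = 100 * on_s / Tw,
                compliance = plan$compliance)
  list(stream = stream, truth = truth, cfg = cfg)
}

#' Generate a session from a motion plan
#'
#' Dispatches on `plan$exercise` to the matching generator.
#'
#' @param plan A [motion_plan()].
#' @param ... Passed on (e.g. `cfg` for balance).
#' @return List with `stream` and `truth`.
#' @export
gen_session <- function(plan, ...) {
  switch(plan$exercise,
         elbow = gen_flexion_session(plan),
         squat = gen_flexion_session(plan),
         step = gen_step_session(plan),
         balance = gen_balance_session(plan, ...))
}
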