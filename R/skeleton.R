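# Skeleton data model: joint vocabulary, tracking states, subject profile,
# the skeleton_stream container and frame validation.

#' The 25 joints of a depth-camera body-tracking skeleton
#'
#' Returns the fixed vocabulary of joint names used throughout the package,
#' in the sensor SDK's canonical order. Bilateral joints come in Left/Right
#' pairs; the remaining five lie on the body midline.
#'
#' @return Character vector of 25 distinct joint names.
#' @examples
#' kinect_joint_names()
#' @export
kinect_joint_names <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder",
    "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight")
}

#' Valid joint tracking states
#'
#' A joint sample is `Tracked` (directly observed), `Inferred` (position
#' estimated by the sensor, e.g. under partial occlusion) or `NotTracked`
#' (no usable position). Only `NotTracked` excludes a joint from analysis;
#' `Inferred` samples are kept.
#'
#' @return Character vector of the three states.
#' @export
tracking_states <- function() c("Tracked", "Inferred", "NotTracked")

#' Subject profile
#'
#' Minimal anthropometric record attached to a session: an identifier, the
#' total body mass (used to scale segment masses for center-of-mass
#' estimation) and an optional standing height.
#'
#' @param id Opaque subject identifier (coerced to character).
#' @param mass_kg Total body mass in kilograms; must be positive.
#' @param height_m Optional standing height in meters.
#' @return An object of class `subject_profile`.
#' @examples
#' subject_profile("S01", mass_kg = 67, height_m = 1.72)
#' @export
subject_profile <- function(id, mass_kg, height_m = NULL) {
  stopifnot(length(mass_kg) == 1, is.finite(mass_kg), mass_kg > 0)
  if (!is.null(height_m)) stopifnot(length(height_m) == 1, is.finite(height_m), height_m > 0)
  structure(list(id = as.character(id), mass_kg = as.numeric(mass_kg),
                 height_m = if (is.null(height_m)) NULL else as.numeric(height_m)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> id=%s mass=%.1f kg%s\n", x$id, x$mass_kg,
              if (is.null(x$height_m)) "" else sprintf(" height=%.2f m", x$height_m)))
  invisible(x)
}

#' Construct a skeleton stream
#'
#' A skeleton stream is a long-format data frame with one row per joint per
#' frame: columns `time_s`, `body_id`, `joint`, `x_m`, `y_m`, `z_m`,
#' `state`. Positions are in meters, camera space: `y` vertical (up), `z`
#' along the sensor-subject axis, `x` transverse. Frame timestamps must be
#' strictly increasing within each body.
#'
#' @param frames Data frame with the seven canonical columns.
#' @param sample_rate Nominal sampling rate in Hz (default 30).
#' @param subject Optional [subject_profile()].
#' @param validate Check column types, joint names, states and timestamp
#'   monotonicity (default `TRUE`).
#' @return A data frame of class `skeleton_stream` with `sample_rate` and
#'   `subject` attributes.
#' @seealso [read_stream()], [split_bodies()], [validate_frame()]
#' @export
skeleton_stream <- function(frames, sample_rate = 30, subject = NULL, validate = TRUE) {
  stopifnot(is.data.frame(frames), sample_rate > 0)
  needed <- c("time_s", "body_id", "joint", "x_m", "y_m", "z_m", "state")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols) > 0)
    stop("skeleton stream is missing columns: ", paste(missing_cols, collapse = ", "))
  frames <- as.data.frame(frames)[needed]
  frames$joint <- as.character(frames$joint)
  frames$state <- as.character(frames$state)
  frames$body_id <- as.integer(frames$body_id)
  if (validate) {
    bad_joint <- !(frames$joint %in% kinect_joint_names())
    if (any(bad_joint))
      stop("unknown joint name(s): ", paste(unique(frames$joint[bad_joint]), collapse = ", "))
    bad_state <- !(frames$state %in% tracking_states())
    if (any(bad_state))
      stop("unknown tracking state(s): ", paste(unique(frames$state[bad_state]), collapse = ", "))
    for (b in unique(frames$body_id)) {
      tb <- frames$time_s[frames$body_id == b]
      ut <- unique(tb)
      if (is.unsorted(ut, strictly = TRUE))
        stop("timestamps not strictly increasing for body_id ", b)
    }
    if (length(unique(frames$body_id)) > 6)
      stop("a stream carries at most 6 bodies")
  }
  structure(frames, class = c("skeleton_stream", "data.frame"),
            sample_rate = as.numeric(sample_rate), subject = subject)
}

#' @export
print.skeleton_stream <- function(x, ...) {
  ts <- unique(x$time_s)
  cat(sprintf("<skeleton_stream> %d frames, %d bodies, %.1f Hz, %.2f s\n",
              length(ts), length(unique(x$body_id)), attr(x, "sample_rate"),
              if (length(ts) > 0) max(ts) - min(ts) else 0))
  invisible(x)
}

#' Split a multi-body stream into one stream per body
#'
#' Depth cameras can track several bodies at once (two-player sessions);
#' each body is analyzed independently.
#'
#' @param stream A [skeleton_stream()].
#' @return Named list of single-body `skeleton_stream` objects, one per
#'   `body_id`.
#' @export
split_bodies <- function(stream) {
  stopifnot(inherits(stream, "skeleton_stream"))
  ids <- sort(unique(stream$body_id))
  out <- lapply(ids, function(b)
    skeleton_stream(stream[stream$body_id == b, , drop = FALSE],
                    sample_rate = attr(stream, "sample_rate"),
                    subject = attr(stream, "subject"), validate = FALSE))
  names(out) <- as.character(ids)
  out
}

# Internal: require a single-body stream.
single_body <- function(stream) {
  ids <- unique(stream$body_id)
  if (length(ids) > 1)
    stop("stream contains ", length(ids), " bodies; use split_bodies() first")
  stream
}

#' Validate a single skeleton frame
#'
#' Implements the frame-acceptance rule used throughout: a frame is
#' rejected if it contains no joints at all ("no body detected") or if any
#' joint of interest is absent or flagged `NotTracked`. Accepted frames
#' pass through unmodified -- there is no filtering or interpolation;
#' rejection is a normal outcome, not an error. `Inferred` joints are
#' accepted.
#'
#' @param frame Data frame of joint rows sharing one timestamp (canonical
#'   stream columns).
#' @param required Character vector of joints of interest.
#' @return A list with `accepted` (logical) and `reason` (`NULL` if
#'   accepted, otherwise a short message naming the offending joint).
#' @examples
#' fr <- make_base_skeleton(1.72)
#' validate_frame(fr, c("KneeLeft", "HipLeft", "AnkleLeft"))
#' @export
validate_frame <- function(frame, required = character()) {
  stopifnot(all(required %in% kinect_joint_names()))
  if (nrow(frame) == 0)
    return(list(accepted = FALSE, reason = "no body"))
  required <- unique(required)
  absent <- setdiff(required, frame$joint)
  if (length(absent) > 0)
    return(list(accepted = FALSE,
                reason = paste0("missing joint: ", paste(sort(absent), collapse = ", "))))
  idx <- match(required, frame$joint)
  nt <- required[frame$state[idx] == "NotTracked"]
  if (length(nt) > 0)
    return(list(accepted = FALSE,
                reason = paste0("NotTracked joint: ", paste(sort(nt), collapse = ", "))))
  bad <- required[!is.finite(frame$x_m[idx]) | !is.finite(frame$y_m[idx]) |
                    !is.finite(frame$z_m[idx])]
  if (length(bad) > 0)
    return(list(accepted = FALSE,
                reason = paste0("non-finite position: ", paste(sort(bad), collapse = ", "))))
  list(accepted = TRUE, reason = NULL)
}

# Internal: wide view of a single-body stream restricted to `joints`.
# Returns list(time, x, y, z, state) where x/y/z are n_frames x n_joints
# matrices (columns in the order of `joints`) and state a character matrix.
stream_wide <- function(stream, joints) {
  stream <- single_body(stream)
  times <- unique(stream$time_s)        # strictly increasing by construction
  n <- length(times)
  J <- length(joints)
  x <- y <- z <- matrix(NA_real_, n, J)
  st <- matrix(NA_character_, n, J)
  keep <- stream$joint %in% joints
  ti <- match(stream$time_s[keep], times)
  ji <- match(stream$joint[keep], joints)
  idx <- cbind(ti, ji)
  x[idx] <- stream$x_m[keep]
  y[idx] <- stream$y_m[keep]
  z[idx] <- stream$z_m[keep]
  st[idx] <- stream$state[keep]
  list(time = times, x = x, y = y, z = z, state = st, joints = joints)
}

# Internal: logical vector over frames -- TRUE where every listed joint is
# present, not NotTracked, and has finite coordinates (the vectorized form
# of validate_frame over a stream).
valid_frame_mask <- function(wide) {
  ok <- !is.na(wide$state) & wide$state != "NotTracked" &
    is.finite(wide$x) & is.finite(wide$y) & is.finite(wide$z)
  rowSums(ok) == length(wide$joints)
}
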