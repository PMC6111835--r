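# Joint-angle and center-of-mass kinematics on validated frames.

#' Angle between two segment vectors
#'
#' The geometric angle between vectors `u` and `v` in degrees, computed as
#' `atan2(|u x v|, u . v) * 180 / pi`. The two-argument arctangent extends
#' the naive `arctan(|u x v| / (u . v))` continuously through 90 degrees
#' and keeps obtuse configurations in (90, 180]. The result is symmetric
#' in its arguments, invariant to positive rescaling of either vector, and
#' always in [0, 180].
#'
#' @param u,v Numeric 3-vectors, or n x 3 matrices for a vectorized call.
#' @return Angle(s) in degrees in \[0, 180\].
#' @examples
#' joint_angle(c(1, 0, 0), c(0, 1, 0))   # 90
#' joint_angle(c(1, 0, 0), c(-1, 0, 0))  # 180
#' @export
joint_angle <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  stopifnot(ncol(u) == 3, ncol(v) == 3, nrow(u) == nrow(v))
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu == 0 | nv == 0, na.rm = TRUE))
    stop("joint_angle: zero-length vector")
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  cross_norm <- sqrt(cx^2 + cy^2 + cz^2)
  dot <- rowSums(u * v)
  ang <- atan2(cross_norm, dot) * 180 / pi
  if (length(ang) == 1) as.numeric(ang) else ang
}

#' Define the joint triple for an angle measurement
#'
#' An angle is measured at an apex joint between the two adjacent body
#' segments: `u` runs proximal -> apex and `v` apex -> distal. With this
#' orientation the reported angle is the *deviation* angle: 0 degrees for
#' a straight limb, growing with flexion. The anatomical (interior) angle
#' is `180 - deviation`.
#'
#' @param proximal,apex,distal Three distinct joint names.
#' @return A `joint_triple` object.
#' @seealso [exercise_triple()] for the standard elbow/knee/ankle triples.
#' @export
joint_triple <- function(proximal, apex, distal) {
  js <- c(proximal, apex, distal)
  stopifnot(all(js %in% kinect_joint_names()), length(unique(js)) == 3)
  structure(list(proximal = proximal, apex = apex, distal = distal),
            class = "joint_triple")
}

#' Standard joint triples for the supported exercises
#'
#' Elbow: Shoulder-Elbow-Wrist; knee: Hip-Knee-Ankle; ankle:
#' Knee-Ankle-Foot.
#'
#' @param joint One of `"elbow"`, `"knee"`, `"ankle"`.
#' @param side `"left"` or `"right"`.
#' @return A [joint_triple()].
#' @export
exercise_triple <- function(joint = c("elbow", "knee", "ankle"),
                            side = c("right", "left")) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  sfx <- if (side == "left") "Left" else "Right"
  switch(joint,
         elbow = joint_triple(paste0("Shoulder", sfx), paste0("Elbow", sfx),
                              paste0("Wrist", sfx)),
         knee = joint_triple(paste0("Hip", sfx), paste0("Knee", sfx),
                             paste0("Ankle", sfx)),
         ankle = joint_triple(paste0("Knee", sfx), paste0("Ankle", sfx),
                              paste0("Foot", sfx)))
}

#' Joint-angle time series over a stream
#'
#' Computes the deviation angle at `triple$apex` for every frame in which
#' all three joints of the triple pass [validate_frame()] (present, not
#' `NotTracked`, finite). Rejected frames are skipped, never interpolated:
#' the series is exactly as long as the number of valid frames.
#'
#' @param stream Single-body [skeleton_stream()].
#' @param triple A [joint_triple()].
#' @param warn Warn when no frame passes validation (default `TRUE`).
#' @return Data frame `time_s`, `joint` (apex), `angle_deg` (deviation, 0 =
#'   straight limb).
#' @export
angle_series <- function(stream, triple, warn = TRUE) {
  stopifnot(inherits(triple, "joint_triple"))
  js <- c(triple$proximal, triple$apex, triple$distal)
  w <- stream_wide(stream, js)
  ok <- valid_frame_mask(w)
  if (!any(ok)) {
    if (warn) warning("angle_series: no frame passes validation for apex ", triple$apex)
    return(data.frame(time_s = numeric(0), joint = character(0),
                      angle_deg = numeric(0)))
  }
  u <- cbind(w$x[ok, 2] - w$x[ok, 1], w$y[ok, 2] - w$y[ok, 1], w$z[ok, 2] - w$z[ok, 1])
  v <- cbind(w$x[ok, 3] - w$x[ok, 2], w$y[ok, 3] - w$y[ok, 2], w$z[ok, 3] - w$z[ok, 2])
  data.frame(time_s = w$time[ok], joint = triple$apex,
             angle_deg = as.numeric(joint_angle(u, v)))
}

#' Center of mass of one body segment
#'
#' A segment's mass is assumed concentrated at its midpoint:
#' `sCOM = s1 + (s2 - s1) / 2`.
#'
#' @param s1,s2 Segment endpoint positions (3-vectors, meters).
#' @return The midpoint 3-vector.
#' @examples
#' segment_com(c(0, 0, 0), c(2, 0, 0))  # c(1, 0, 0)
#' @export
segment_com <- function(s1, s2) {
  stopifnot(length(s1) == 3, length(s2) == 3)
  as.numeric(s1) + (as.numeric(s2) - as.numeric(s1)) / 2
}

#' Whole-body center of mass for one frame
#'
#' Mass-weighted average of the 16 segment midpoints:
#' `bCOM = sum(Mi * sCOMi) / sum(Mi)` with `Mi = fraction_i * M`. Because
#' the weights are relative, the result does not depend on `M`;
#' normalizing by `sum(Mi)` rather than `M` absorbs the 0.02 percent
#' deficit of the printed mass table. Every endpoint joint must be present
#' and not `NotTracked`, otherwise the frame is rejected.
#'
#' @param frame Single-timestamp data frame of joint rows.
#' @param table Segment table (default [default_segment_table()]).
#' @param mass_kg Total body mass in kg (must be positive; does not affect
#'   the position, only the physical interpretation of segment masses).
#' @return Named numeric 3-vector `c(x, y, z)` in meters.
#' @export
body_com <- function(frame, table = default_segment_table(), mass_kg = 70) {
  table <- check_segment_table(table)
  stopifnot(mass_kg > 0)
  needed <- unique(c(table$proximal, table$distal))
  chk <- validate_frame(frame, needed)
  if (!chk$accepted)
    stop("body_com: frame rejected (", chk$reason, ")")
  idx <- match(frame$joint, frame$joint)  # identity; positions by name below
  pos <- as.matrix(frame[, c("x_m", "y_m", "z_m")])
  rownames(pos) <- frame$joint
  p <- pos[table$proximal, , drop = FALSE]
  d <- pos[table$distal, , drop = FALSE]
  mid <- (p + d) / 2
  w <- table$fraction
  out <- colSums(mid * w) / sum(w)
  names(out) <- c("x", "y", "z")
  out
}

#' Center-of-mass time series over a stream
#'
#' Vectorized [body_com()] across frames: frames in which any segment
#' endpoint joint is missing or `NotTracked` are skipped (no
#' interpolation).
#'
#' @inheritParams body_com
#' @param stream Single-body [skeleton_stream()].
#' @param warn Warn when no frame is valid.
#' @return Data frame `time_s`, `x_m`, `y_m`, `z_m`.
#' @export
com_series <- function(stream, table = default_segment_table(), mass_kg = 70,
                       warn = TRUE) {
  table <- check_segment_table(table)
  stopifnot(mass_kg > 0)
  joints <- unique(c(table$proximal, table$distal))
  w <- stream_wide(stream, joints)
  ok <- valid_frame_mask(w)
  if (!any(ok)) {
    if (warn) warning("com_series: no frame has all segment endpoints tracked")
    return(data.frame(time_s = numeric(0), x_m = numeric(0),
                      y_m = numeric(0), z_m = numeric(0)))
  }
  pi_ <- match(table$proximal, joints)
  di <- match(table$distal, joints)
  fr <- table$fraction / sum(table$fraction)
  mid_axis <- function(m) ((m[ok, pi_, drop = FALSE] + m[ok, di, drop = FALSE]) / 2) %*% fr
  data.frame(time_s = w$time[ok],
             x_m = as.numeric(mid_axis(w$x)),
             y_m = as.numeric(mid_axis(w$y)),
             z_m = as.numeric(mid_axis(w$z)))
}

#' Transverse-plane displacement of the center of mass
#'
#' Displacement of a COM position from a reference point in the
#' floor-parallel XZ plane: `dx` transverse, `dz` longitudinal. The
#' vertical component is ignored.
#'
#' @param com Either a 3-vector or a [com_series()] data frame.
#' @param reference Finite 3-vector (or `c(x, z)` pair) reference point.
#' @return For a 3-vector, named `c(dx, dz)`; for a series, the data frame
#'   with `dx_m`, `dz_m` columns appended.
#' @export
com_displacement <- function(com, reference) {
  if (length(reference) == 3) reference <- reference[c(1, 3)]
  stopifnot(length(reference) == 2, all(is.finite(reference)))
  if (is.data.frame(com)) {
    com$dx_m <- com$x_m - reference[1]
    com$dz_m <- com$z_m - reference[2]
    return(com)
  }
  stopifnot(length(com) == 3)
  c(dx = as.numeric(com[1]) - reference[1], dz = as.numeric(com[3]) - reference[2])
}
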