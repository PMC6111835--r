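# Anthropometric segment-mass model.

#' Default anthropometric segment table (male mass fractions)
#'
#' The body is modeled as 16 rigid segments, each spanning two skeleton
#' joints and carrying a fixed fraction of total body mass (percent),
#' following standard male anthropometric tables: Head 8.26, Thorax 20.10,
#' Abdomen 13.06, Pelvis 13.66, and per side Upper Arm 3.25, Forearm 1.87,
#' Hand 0.65, Thigh 10.50, Leg 4.75, Foot 1.43. Bilateral segments appear
#' twice with equal fraction; the fractions sum to 99.98 (the 0.02 percent
#' deficit is absorbed by normalization in [body_com()]).
#'
#' The endpoint-joint mapping is a documented modeling choice (the source
#' tables name anatomical segments, not sensor joints): Head = Head-Neck,
#' Thorax = Neck-SpineMid, Abdomen = SpineMid-SpineBase, Pelvis =
#' HipLeft-HipRight, Upper Arm = Shoulder-Elbow, Forearm = Elbow-Wrist,
#' Hand = Wrist-HandTip, Thigh = Hip-Knee, Leg = Knee-Ankle, Foot =
#' Ankle-Foot. The table is plain data and can be edited or replaced.
#'
#' The male table is applied to all subjects regardless of sex.
#'
#' @return Data frame of class `segment_table` with columns `segment`,
#'   `proximal`, `distal`, `fraction` (percent of body mass), 16 rows.
#' @examples
#' tab <- default_segment_table()
#' sum(tab$fraction)  # 99.98
#' @export
default_segment_table <- function() {
  axial <- data.frame(
    segment = c("Head", "Thorax", "Abdomen", "Pelvis"),
    proximal = c("Head", "Neck", "SpineMid", "HipLeft"),
    distal = c("Neck", "SpineMid", "SpineBase", "HipRight"),
    fraction = c(8.26, 20.10, 13.06, 13.66),
    stringsAsFactors = FALSE)
  lateral <- data.frame(
    segment = c("Upper Arm", "Forearm", "Hand", "Thigh", "Leg", "Foot"),
    proximal = c("Shoulder", "Elbow", "Wrist", "Hip", "Knee", "Ankle"),
    distal = c("Elbow", "Wrist", "HandTip", "Knee", "Ankle", "Foot"),
    fraction = c(3.25, 1.87, 0.65, 10.50, 4.75, 1.43),
    stringsAsFactors = FALSE)
  sides <- do.call(rbind, lapply(c("left", "right"), function(s) {
    suffix <- if (s == "left") "Left" else "Right"
    data.frame(segment = paste0(lateral$segment, " (", s, ")"),
               proximal = paste0(lateral$proximal, suffix),
               distal = paste0(lateral$distal, suffix),
               fraction = lateral$fraction, stringsAsFactors = FALSE)
  }))
  tab <- rbind(axial, sides)
  stopifnot(all(tab$proximal %in% kinect_joint_names()),
            all(tab$distal %in% kinect_joint_names()))
  structure(tab, class = c("segment_table", "data.frame"))
}

# Internal: sanity-check a (possibly user-supplied) segment table.
check_segment_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("segment", "proximal", "distal", "fraction") %in% names(table)))
  if (!all(table$proximal %in% kinect_joint_names()) ||
      !all(table$distal %in% kinect_joint_names()))
    stop("segment table references unknown joint names")
  if (any(!is.finite(table$fraction) | table$fraction <= 0))
    stop("segment mass fractions must be positive")
  table
}
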