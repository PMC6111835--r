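# Flexion/extension repetition counting: two-threshold hysteresis automaton.

#' Configuration for flexion/extension counting
#'
#' The counter is a two-state hysteresis automaton over a joint-angle
#' trace. The threshold pair is interpreted on either the *deviation*
#' angle (0 = straight limb) or the *interior* anatomical angle
#' (180 = straight); the two conventions are complementary
#' (`interior = 180 - deviation`). Defaults follow clinical settings for
#' arthropathic joints: elbow (50, 100) on the interior angle -- flexed
#' once the elbow closes to 50 degrees or less, extension complete once it
#' reopens to 100 degrees or more; knee (70, 30) on the deviation angle --
#' flexed at 70 degrees or more of knee bend, extension complete back at
#' 30 degrees or less.
#'
#' @param joint `"elbow"` or `"knee"` (selects the defaults).
#' @param side `"right"` or `"left"` (metadata; selects the triple when a
#'   stream is analyzed).
#' @param flexion_threshold Angle (degrees) whose crossing marks the
#'   flexed state.
#' @param extension_threshold Angle (degrees) whose crossing completes the
#'   repetition.
#' @param convention `"interior"` or `"deviation"`: the scale on which the
#'   thresholds are expressed.
#' @return A `flexion_config` object.
#' @export
flexion_config <- function(joint = c("knee", "elbow"), side = c("right", "left"),
                           flexion_threshold = NULL, extension_threshold = NULL,
                           convention = NULL) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  if (is.null(flexion_threshold))
    flexion_threshold <- if (joint == "elbow") 50 else 70
  if (is.null(extension_threshold))
    extension_threshold <- if (joint == "elbow") 100 else 30
  if (is.null(convention))
    convention <- if (joint == "elbow") "interior" else "deviation"
  convention <- match.arg(convention, c("deviation", "interior"))
  stopifnot(flexion_threshold > 0, flexion_threshold < 180,
            extension_threshold > 0, extension_threshold < 180,
            flexion_threshold != extension_threshold)
  # For a consistent hysteresis band the flexed-side threshold must lie on
  # the flexed side of the extended-side threshold.
  if (convention == "deviation" && flexion_threshold < extension_threshold)
    stop("deviation convention requires flexion_threshold > extension_threshold")
  if (convention == "interior" && flexion_threshold > extension_threshold)
    stop("interior convention requires flexion_threshold < extension_threshold")
  structure(list(joint = joint, side = side,
                 flexion_threshold = flexion_threshold,
                 extension_threshold = extension_threshold,
                 convention = convention),
            class = "flexion_config")
}

# Internal: express the hysteresis band on the deviation scale.
# Returns c(flex, ext) with flex > ext: flexed when deviation >= flex,
# repetition completes when deviation <= ext.
deviation_band <- function(cfg) {
  if (cfg$convention == "deviation")
    c(flex = cfg$flexion_threshold, ext = cfg$extension_threshold)
  else
    c(flex = 180 - cfg$flexion_threshold, ext = 180 - cfg$extension_threshold)
}

#' Count flexion/extension repetitions in an angle trace
#'
#' Two-step detection: the automaton starts *extended*; it moves to
#' *flexed* when the angle crosses the flexed-side threshold, and on a
#' subsequent crossing of the extended-side threshold the repetition is
#' counted and the automaton returns to *extended*. Samples between the
#' two thresholds change nothing, so noise smaller than the hysteresis gap
#' cannot double-count. Threshold comparisons are inclusive on both sides,
#' so a trace sitting exactly on a threshold cannot oscillate the
#' automaton.
#'
#' @param angles Data frame with `time_s` and `angle_deg` columns holding
#'   the *deviation* angle as produced by [angle_series()] (the config's
#'   `convention` says how its thresholds map onto it), time-ordered.
#' @param cfg A [flexion_config()].
#' @return A `flexion_result`: list with `flex_count`, `events` (data
#'   frame `t_flexed`, `t_extended`, one row per completed repetition),
#'   `angles` (the input trace) and `config`.
#' @examples
#' tr <- data.frame(time_s = 0:4, angle_deg = c(10, 80, 50, 80, 10))
#' count_flexions(tr, flexion_config("knee"))$flex_count  # 1
#' @export
count_flexions <- function(angles, cfg = flexion_config()) {
  stopifnot(inherits(cfg, "flexion_config"),
            is.data.frame(angles), all(c("time_s", "angle_deg") %in% names(angles)))
  if (nrow(angles) == 0) {
    warning("count_flexions: empty angle series")
    return(structure(list(flex_count = 0L,
                          events = data.frame(t_flexed = numeric(0),
                                              t_extended = numeric(0)),
                          angles = angles, config = cfg),
                     class = "flexion_result"))
  }
  if (is.unsorted(angles$time_s)) stop("count_flexions: series not time-ordered")
  band <- deviation_band(cfg)
  x <- angles$angle_deg
  tms <- angles$time_s
  sym <- integer(length(x))
  sym[x >= band["flex"]] <- 1L
  sym[x <= band["ext"]] <- -1L
  nz <- which(sym != 0L)
  t_flexed <- t_extended <- numeric(0)
  state <- -1L  # extended
  pending_flex_time <- NA_real_
  if (length(nz) > 0) {
    runs <- rle(sym[nz])
    pos <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
    for (k in seq_along(runs$values)) {
      v <- runs$values[k]
      t_first <- tms[nz[pos[k]]]
      if (v == 1L && state == -1L) {
        state <- 1L
        pending_flex_time <- t_first
      } else if (v == -1L && state == 1L) {
        state <- -1L
        t_flexed <- c(t_flexed, pending_flex_time)
        t_extended <- c(t_extended, t_first)
      }
    }
  }
  structure(list(flex_count = length(t_extended),
                 events = data.frame(t_flexed = t_flexed, t_extended = t_extended),
                 angles = angles, config = cfg),
            class = "flexion_result")
}

#' @export
print.flexion_result <- function(x, ...) {
  cat(sprintf("<flexion_result> %s (%s): %d repetition(s), %d samples\n",
              x$config$joint, x$config$side, x$flex_count, nrow(x$angles)))
  invisible(x)
}

#' Count flexions directly from a skeleton stream
#'
#' Convenience wrapper: builds the angle series for the configured joint
#' and side via [exercise_triple()] and runs [count_flexions()].
#'
#' @param stream Single-body [skeleton_stream()].
#' @param cfg A [flexion_config()].
#' @return A `flexion_result`.
#' @export
count_flexions_stream <- function(stream, cfg = flexion_config()) {
  ang <- angle_series(stream, exercise_triple(cfg$joint, cfg$side), warn = FALSE)
  count_flexions(ang, cfg)
}
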