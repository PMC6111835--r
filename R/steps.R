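# Step-climb detection from hip elevation combined with knee cycles.

#' Configuration for step-climb detection
#'
#' A step climb is detected from two conditions that must overlap in time:
#' (a) a general rise of the body, measured as the hip center (SpineBase)
#' climbing at least `hip_rise_threshold` above its standing baseline, and
#' (b) a flexion-then-extension cycle of the stepping knee under the usual
#' hysteresis semantics. The ankle angle is recorded throughout for
#' clinical review but is deliberately never used for detection -- foot
#' and ankle joints are the least reliably tracked by depth cameras.
#'
#' @param hip_rise_threshold Minimum hip-center elevation above baseline
#'   (m) to call the body "raised"; default 0.09, about 60 percent of a
#'   0.15 m step block.
#' @param step_height Physical step-block height in meters (metadata;
#'   default 0.15).
#' @param flexion_threshold,extension_threshold Knee hysteresis band in
#'   degrees on the `convention` scale (defaults 70/30, deviation).
#' @param convention Angle convention for the knee band.
#' @param baseline_window Seconds of standing at the start (and after each
#'   descent) over which the hip baseline is averaged; default 2.
#' @return A `step_config` object.
#' @export
step_config <- function(hip_rise_threshold = 0.09, step_height = 0.15,
                        flexion_threshold = 70, extension_threshold = 30,
                        convention = "deviation", baseline_window = 2) {
  stopifnot(hip_rise_threshold > 0, step_height > 0, baseline_window > 0)
  knee_left <- flexion_config("knee", "left", flexion_threshold,
                              extension_threshold, convention)
  knee_right <- flexion_config("knee", "right", flexion_threshold,
                               extension_threshold, convention)
  structure(list(hip_rise_threshold = hip_rise_threshold,
                 step_height = step_height,
                 knee_left = knee_left, knee_right = knee_right,
                 baseline_window = baseline_window),
            class = "step_config")
}

#' Count step climbs and descents
#'
#' Scans the hip-center (SpineBase) vertical trajectory for raised
#' intervals: the body becomes *raised* when the hip exceeds
#' `baseline + hip_rise_threshold`, and a *descent* is recorded when it
#' returns within `hip_rise_threshold / 2` of baseline. The baseline is
#' the mean hip height over the initial `baseline_window` seconds and is
#' re-anchored over the window following each completed descent (the next
#' rise is searched only after that window), which makes the detector
#' robust to slow postural drift. A climb is credited to foot F when a
#' knee-F flexion-extension cycle (per [count_flexions()]) overlaps a
#' raised interval in time; each interval credits at most one climb per
#' foot, and its descent is credited to the same foot/feet.
#'
#' Frames where the needed joints are `NotTracked` are skipped;
#' if the hip center is never tracked the stream cannot be analyzed and
#' an error is raised.
#'
#' @param stream Single-body [skeleton_stream()].
#' @param cfg A [step_config()].
#' @return A `step_result`: list with `climbs` and `descents` (named
#'   integer vectors, `left`/`right`), `ankle_angles` (list of recorded
#'   left/right ankle deviation-angle series, never consulted by the
#'   detector), `knee_events`, `hip` (data frame `time_s`, `y_m`,
#'   `baseline_m`) and `config`.
#' @export
count_steps <- function(stream, cfg = step_config()) {
  stopifnot(inherits(cfg, "step_config"))
  w <- stream_wide(stream, "SpineBase")
  ok <- valid_frame_mask(w)
  if (!any(ok))
    stop("count_steps: hip center (SpineBase) never tracked in stream")
  ht <- w$time[ok]
  hy <- w$y[ok, 1]

  knees <- list(
    left = count_flexions(angle_series(stream, exercise_triple("knee", "left"),
                                       warn = FALSE), cfg$knee_left),
    right = count_flexions(angle_series(stream, exercise_triple("knee", "right"),
                                        warn = FALSE), cfg$knee_right))
  if (nrow(knees$left$angles) == 0 && nrow(knees$right$angles) == 0)
    warning("count_steps: no valid knee frames on either side")

  ankle_angles <- list(
    left = angle_series(stream, exercise_triple("ankle", "left"), warn = FALSE),
    right = angle_series(stream, exercise_triple("ankle", "right"), warn = FALSE))

  thr <- cfg$hip_rise_threshold
  win <- cfg$baseline_window
  n <- length(ht)
  baseline_of <- function(from_t) {
    sel <- ht >= from_t & ht < from_t + win
    if (!any(sel)) sel <- seq_len(min(2L, n))  # degenerate: too few frames
    mean(hy[sel])
  }
  baseline <- baseline_of(ht[1])
  baseline_trace <- rep(baseline, n)
  intervals <- list()
  # scan cursor: first frame after the initial baseline window
  i <- match(TRUE, ht >= ht[1] + win, nomatch = n + 1L)
  while (i <= n) {
    up <- which(hy[i:n] >= baseline + thr)
    if (length(up) == 0) break
    i_rise <- i + up[1] - 1L
    down <- which(hy[i_rise:n] <= baseline + thr / 2)
    if (length(down) == 0) {
      intervals[[length(intervals) + 1L]] <- c(t_rise = ht[i_rise], t_desc = NA_real_)
      break
    }
    i_desc <- i_rise + down[1] - 1L
    intervals[[length(intervals) + 1L]] <- c(t_rise = ht[i_rise], t_desc = ht[i_desc])
    baseline <- baseline_of(ht[i_desc])
    i_next <- match(TRUE, ht >= ht[i_desc] + win, nomatch = n + 1L)
    if (i_next <= n) baseline_trace[i_next:n] <- baseline
    i <- max(i_desc + 1L, i_next)
  }

  t_end <- ht[n]
  climbs <- c(left = 0L, right = 0L)
  descents <- c(left = 0L, right = 0L)
  for (side in c("left", "right")) {
    ev <- knees[[side]]$events
    if (length(intervals) == 0 || nrow(ev) == 0) next
    used <- rep(FALSE, nrow(ev))
    for (iv in intervals) {
      t_hi <- if (is.na(iv["t_desc"])) t_end else iv["t_desc"]
      hit <- which(!used & ev$t_flexed <= t_hi & ev$t_extended >= iv["t_rise"])
      if (length(hit) > 0) {
        used[hit[1]] <- TRUE
        climbs[side] <- climbs[side] + 1L
        if (!is.na(iv["t_desc"])) descents[side] <- descents[side] + 1L
      }
    }
  }

  structure(list(climbs = climbs, descents = descents,
                 ankle_angles = ankle_angles,
                 knee_events = list(left = knees$left$events,
                                    right = knees$right$events),
                 hip = data.frame(time_s = ht, y_m = hy, baseline_m = baseline_trace),
                 intervals = intervals, config = cfg),
            class = "step_result")
}

#' @export
print.step_result <- function(x, ...) {
  cat(sprintf("<step_result> climbs L=%d R=%d, descents L=%d R=%d\n",
              x$climbs["left"], x$climbs["right"],
              x$descents["left"], x$descents["right"]))
  invisible(x)
}
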