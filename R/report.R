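# Session records, report bundles and progress-style plots.

#' Bundle a session's results into a record
#'
#' A session record holds everything needed to reproduce and report one
#' analyzed session: the subject, the exercise, the effective
#' configuration snapshot, the detector result and a caller-supplied
#' timestamp (kept as data so regenerating a report from the same record
#' is byte-identical).
#'
#' @param subject A [subject_profile()].
#' @param exercise One of `"elbow"`, `"squat"`, `"step"`, `"balance"`.
#' @param config The detector config used (flexion/step/balance config,
#'   or a plain list for provenance).
#' @param result A `flexion_result` (possibly a list of them, one per
#'   side), `step_result` or `balance_result`.
#' @param timestamp Character timestamp recorded with the session.
#' @return A `session_record`.
#' @export
session_record <- function(subject, exercise, config, result,
                           timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(inherits(subject, "subject_profile"),
            exercise %in% c("elbow", "squat", "step", "balance"))
  structure(list(subject = subject, exercise = exercise, config = config,
                 result = result, timestamp = as.character(timestamp)),
            class = "session_record")
}

# Internal: reduce a detector result to plain serializable lists.
result_payload <- function(result) {
  if (inherits(result, "flexion_result")) {
    return(list(type = "flexion", joint = result$config$joint,
                side = result$config$side, flex_count = result$flex_count,
                events = result$events))
  }
  if (is.list(result) && all(vapply(result, inherits, TRUE, "flexion_result"))) {
    return(list(type = "flexion_bilateral",
                sides = lapply(result, result_payload)))
  }
  if (inherits(result, "step_result")) {
    return(list(type = "step",
                climbs = as.list(result$climbs),
                descents = as.list(result$descents),
                knee_events = result$knee_events))
  }
  if (inherits(result, "balance_result")) {
    return(list(type = "balance", level = result$config$level,
                scores = as.list(result$scores),
                on_target_s = as.list(result$on_target_s),
                idle_pos = as.list(result$idle_pos),
                incomplete = as.list(result$incomplete)))
  }
  stop("unknown result type")
}

# Internal: strip classes so configs serialize as plain JSON objects.
config_payload <- function(config) {
  if (is.null(config)) return(NULL)
  x <- unclass(config)
  if (!is.null(x$directions)) x$directions <- NULL
  lapply(x, function(v) if (is.list(v) || inherits(v, "flexion_config"))
    config_payload(v) else v)
}

#' Plot a joint-angle trace
#'
#' Angle (degrees) against time (seconds), the standard progress graph
#' for flexion-type exercises.
#'
#' @param series Data frame from [angle_series()] (or the `angles` element
#'   of a `flexion_result`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_angle_series <- function(series, title = "Joint angle over time") {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_s, y = .data$angle_deg)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "angle (°)", title = title) +
    ggplot2::theme_minimal()
}

#' Plot a COM trajectory in the transverse plane
#'
#' The center-of-mass path in the XZ (floor) plane, optionally with the
#' balance targets and idle position overlaid.
#'
#' @param com Data frame from [com_series()].
#' @param result Optional `balance_result` whose idle position and target
#'   geometry are drawn.
#' @return A ggplot object.
#' @export
plot_com_trajectory <- function(com, result = NULL) {
  p <- ggplot2::ggplot(com, ggplot2::aes(x = .data$x_m, y = .data$z_m)) +
    ggplot2::geom_path(alpha = 0.6, color = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m, transverse)", y = "z (m, longitudinal)",
                  title = "COM trajectory (XZ plane)") +
    ggplot2::theme_minimal()
  if (!is.null(result) && inherits(result, "balance_result")) {
    cfg <- result$config
    tg <- cfg$directions
    tg$x <- result$idle_pos["x"] + cfg$excursion * tg$ux
    tg$z <- result$idle_pos["z"] + cfg$excursion * tg$uz
    p <- p +
      ggplot2::geom_point(data = tg, ggplot2::aes(x = .data$x, y = .data$z),
                          shape = 1, size = 4, color = "darkgreen") +
      ggplot2::annotate("point", x = result$idle_pos["x"],
                        y = result$idle_pos["z"], shape = 3, color = "red")
  }
  p
}

#' Write a report bundle for a session record
#'
#' Writes into `outdir`: `report.json` (machine-readable results plus the
#' effective configuration for provenance; byte-identical when
#' regenerated from the same record), `summary.txt` (human-readable), and
#' PDF plots -- the angle trace for flexion/step sessions, the COM
#' trajectory with targets for balance sessions.
#'
#' @param record A [session_record()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_report <- function(record, outdir) {
  stopifnot(inherits(record, "session_record"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  files <- character(0)

  json_path <- file.path(outdir, "report.json")
  payload <- list(format = "rehabmotion-report/1",
                  timestamp = record$timestamp,
                  subject = unclass(record$subject),
                  exercise = record$exercise,
                  config = config_payload(record$config),
                  result = result_payload(record$result))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  files <- c(files, json_path)

  txt_path <- file.path(outdir, "summary.txt")
  writeLines(summary_lines(record), txt_path)
  files <- c(files, txt_path)

  res <- record$result
  if (inherits(res, "balance_result")) {
    plot_path <- file.path(outdir, "com_trajectory.pdf")
    grDevices::pdf(plot_path, width = 6, height = 6)
    print(plot_com_trajectory(res$com, res))
    grDevices::dev.off()
    files <- c(files, plot_path)
  } else {
    traces <- if (inherits(res, "flexion_result")) list(res)
      else if (inherits(res, "step_result"))
        list(structure(list(angles = res$ankle_angles$left,
                            config = list(joint = "ankle", side = "left")),
                       class = "flexion_trace"),
             structure(list(angles = res$ankle_angles$right,
                            config = list(joint = "ankle", side = "right")),
                       class = "flexion_trace"))
      else res
    plot_path <- file.path(outdir, "angle_trace.pdf")
    grDevices::pdf(plot_path, width = 8, height = 4)
    for (tr in traces) {
      if (nrow(tr$angles) > 0)
        print(plot_angle_series(tr$angles,
                                title = paste(tr$config$joint, tr$config$side)))
    }
    grDevices::dev.off()
    files <- c(files, plot_path)
  }
  invisible(files)
}

# Internal: human-readable summary of a record.
summary_lines <- function(record) {
  res <- record$result
  head_lines <- c(
    sprintf("Exercise session report (%s)", record$exercise),
    sprintf("Subject: %s  mass %.1f kg", record$subject$id, record$subject$mass_kg),
    sprintf("Recorded: %s", record$timestamp), "")
  body_lines <- if (inherits(res, "balance_result")) {
    c(sprintf("Balance level %d; scores (%% of %g s on target):", res$config$level,
              res$config$time_per_target),
      vapply(names(res$scores), function(d)
        sprintf("  %-2s %s", d,
                if (is.na(res$scores[d])) "incomplete"
                else sprintf("%5.1f", res$scores[d])), ""))
  } else if (inherits(res, "step_result")) {
    c(sprintf("Step climbs: left %d, right %d", res$climbs["left"], res$climbs["right"]),
      sprintf("Step descents: left %d, right %d",
              res$descents["left"], res$descents["right"]))
  } else if (inherits(res, "flexion_result")) {
    sprintf("Repetitions (%s %s): %d", res$config$joint, res$config$side,
            res$flex_count)
  } else if (is.list(res)) {
    vapply(res, function(r)
      sprintf("Repetitions (%s %s): %d", r$config$joint, r$config$side,
              r$flex_count), "")
  } else "unknown result"
  c(head_lines, body_lines)
}
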