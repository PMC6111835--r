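# Canonical stream formats and achievement-rate aggregation.

canonical_columns <- c("time_s", "body_id", "joint", "x_m", "y_m", "z_m", "state")

# Internal: full-precision number formatting so write/read round-trips
# doubles bit-identically.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a skeleton stream to the canonical CSV format
#'
#' One row per joint per frame, header
#' `time_s,body_id,joint,x_m,y_m,z_m,state`. Numbers are written with 17
#' significant digits so that a write/read round trip reproduces
#' positions bit-identically.
#'
#' @param stream A [skeleton_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "skeleton_stream"))
  lines <- c(paste(canonical_columns, collapse = ","),
             paste(fmt_num(stream$time_s), stream$body_id, stream$joint,
                   fmt_num(stream$x_m), fmt_num(stream$y_m), fmt_num(stream$z_m),
                   stream$state, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a skeleton stream
#'
#' Parses the canonical CSV dialect (or a JSON session envelope, see
#' [write_session()]). Malformed records -- unknown joint names or
#' tracking states, non-numeric positions, timestamps that are not
#' strictly increasing per body -- raise an error naming the offending
#' line numbers.
#'
#' @param path Input file.
#' @param dialect `"canonical-csv"` or `"session-json"`.
#' @param sample_rate Nominal rate attached to the stream (CSV dialect;
#'   default 30).
#' @return A [skeleton_stream()] (possibly multi-body; see
#'   [split_bodies()]).
#' @export
read_stream <- function(path, dialect = c("canonical-csv", "session-json"),
                        sample_rate = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "session-json") return(read_session(path)$stream)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(time_s = "numeric", body_id = "integer",
                                       joint = "character", x_m = "numeric",
                                       y_m = "numeric", z_m = "numeric",
                                       state = "character"))
  if (!identical(names(df), canonical_columns))
    stop("unexpected columns in ", path, ": ", paste(names(df), collapse = ","))
  line_no <- seq_len(nrow(df)) + 1L  # +1 for the header line
  bad <- !(df$joint %in% kinect_joint_names())
  if (any(bad))
    stop("unknown joint name(s) at line(s) ",
         paste(utils::head(line_no[bad], 10), collapse = ", "),
         ": ", paste(utils::head(unique(df$joint[bad]), 5), collapse = ", "))
  bad <- !(df$state %in% tracking_states())
  if (any(bad))
    stop("unknown tracking state(s) at line(s) ",
         paste(utils::head(line_no[bad], 10), collapse = ", "))
  for (b in unique(df$body_id)) {
    idx_b <- which(df$body_id == b)
    tb <- df$time_s[idx_b]
    newt <- c(TRUE, tb[-1] != tb[-length(tb)])
    ft <- tb[newt]  # frame times in file order
    if (is.unsorted(ft, strictly = TRUE)) {
      k <- which(diff(ft) <= 0)[1] + 1L
      stop("non-monotone timestamps for body_id ", b,
           " near line ", line_no[idx_b[newt][k]])
    }
  }
  skeleton_stream(df, sample_rate = sample_rate, validate = FALSE)
}

#' Write / read a JSON session envelope
#'
#' The session envelope bundles the stream with the subject profile and
#' exercise metadata in one self-describing JSON document.
#'
#' @param stream A [skeleton_stream()].
#' @param path File path.
#' @param exercise Optional exercise label.
#' @param config Optional configuration snapshot (any serializable list).
#' @return `write_session()` returns `path` invisibly; `read_session()` a
#'   list with `stream`, `exercise`, `config`.
#' @export
write_session <- function(stream, path, exercise = NULL, config = NULL) {
  stopifnot(inherits(stream, "skeleton_stream"))
  subject <- attr(stream, "subject")
  payload <- list(
    format = "rehabmotion-session/1",
    subject = if (is.null(subject)) NULL else unclass(subject),
    exercise = exercise,
    config = config,
    sample_rate_hz = attr(stream, "sample_rate"),
    frames = as.data.frame(stream))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject <- if (is.null(p$subject)) NULL
    else subject_profile(p$subject$id, p$subject$mass_kg, p$subject$height_m)
  stream <- skeleton_stream(p$frames, sample_rate = p$sample_rate_hz,
                            subject = subject)
  list(stream = stream, exercise = p$exercise, config = p$config)
}

#' Export an angle or COM series as tidy CSV
#'
#' @param series A data frame from [angle_series()] or [com_series()]
#'   (optionally with displacement columns from [com_displacement()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Achievement rate of one exercise series
#'
#' The percentage of prescribed repetitions correctly detected, capped at
#' 100 (extra detections do not overshoot).
#'
#' @param detected Detected repetition count(s).
#' @param prescribed Prescribed repetitions per series (default 5).
#' @return Percent value(s) in \[0, 100\].
#' @examples
#' achievement_rate(4)      # 80
#' achievement_rate(7, 5)   # capped at 100
#' @export
achievement_rate <- function(detected, prescribed = 5) {
  stopifnot(all(detected >= 0), all(prescribed > 0))
  pmin(100, 100 * detected / prescribed)
}

# Display rounding: half away from zero to integer percent.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Aggregate achievement rates across series
#'
#' Arithmetic mean and sample standard deviation of per-series achievement
#' rates, with display values rounded half-away-from-zero to integer
#' percent (as in clinical summary tables of "mean +/- sd over 5 series of
#' 5 repetitions").
#'
#' @param rates Non-empty numeric vector of percentages in \[0, 100\].
#' @return An `achievement_summary`: list with `rates`, `mean`, `sd`
#'   (exact values) and `mean_display`, `sd_display` (integers; `sd` is
#'   `NA` for a single series).
#' @examples
#' aggregate_achievement(c(80, 88, 84, 76, 80, 72, 72, 80, 68, 80))
#' @export
aggregate_achievement <- function(rates) {
  if (length(rates) == 0) stop("aggregate_achievement: empty series")
  stopifnot(all(is.finite(rates)), all(rates >= 0 & rates <= 100))
  m <- mean(rates)
  s <- if (length(rates) > 1) stats::sd(rates) else NA_real_
  structure(list(rates = rates, mean = m, sd = s,
                 mean_display = as.integer(round_half_away(m)),
                 sd_display = if (is.na(s)) NA_integer_
                              else as.integer(round_half_away(s))),
            class = "achievement_summary")
}

#' @export
print.achievement_summary <- function(x, ...) {
  cat(sprintf("<achievement_summary> %d series: %d +/- %s %%\n",
              length(x$rates), x$mean_display,
              if (is.na(x$sd_display)) "NA" else x$sd_display))
  invisible(x)
}
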