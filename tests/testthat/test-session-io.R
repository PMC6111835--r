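# Stream formats, achievement aggregation, reports and the CLI.

test_that("canonical CSV read/write is a lossless round trip with validation", {
  sess <- gen_flexion_session(motion_plan("squat", repetitions = 2,
                                          noise_pos = 0.003, seed = 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(sess$stream, path)
  back <- read_stream(path)
  expect_identical(as.data.frame(back)[c("time_s", "x_m", "y_m", "z_m")],
                   as.data.frame(sess$stream)[c("time_s", "x_m", "y_m", "z_m")])

  # a misspelled joint is reported with its line number
  lines <- readLines(path)
  lines[3] <- sub("^([^,]*,[^,]*,)[A-Za-z]+", "\\1Kneee", lines[3])
  bad_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad_path)
  expect_error(read_stream(bad_path), "Kneee")
  expect_error(read_stream(bad_path), "line.*3")

  # non-monotone frame times are rejected
  fr <- make_base_skeleton(1.72)
  tw <- rbind(transform(fr, time_s = 1), transform(fr, time_s = 0.5))
  s <- skeleton_stream(tw, validate = FALSE)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_stream(s, p2)
  expect_error(read_stream(p2), "non-monotone")
})

test_that("multi-body streams split into independent per-body streams", {
  fr <- make_base_skeleton(1.72)
  f2 <- transform(fr, body_id = 1L, x_m = x_m + 0.6)
  both <- rbind(rbind(fr, transform(fr, time_s = 1 / 30)),
                rbind(f2, transform(f2, time_s = 1 / 30)))
  stream <- skeleton_stream(both)
  parts <- split_bodies(stream)
  expect_length(parts, 2)
  expect_setequal(names(parts), c("0", "1"))
  expect_equal(parts[["1"]]$x_m - parts[["0"]]$x_m, rep(0.6, nrow(parts[["0"]])))
  # each part analyzes independently
  expect_s3_class(parts[["0"]], "skeleton_stream")
})

test_that("the JSON session envelope round-trips stream and subject", {
  sess <- gen_flexion_session(motion_plan("elbow", repetitions = 2, seed = 16))
  path <- withr::local_tempfile(fileext = ".json")
  write_session(sess$stream, path, exercise = "elbow",
                config = list(prescribed = 5))
  back <- read_session(path)
  expect_equal(back$exercise, "elbow")
  expect_equal(back$config$prescribed, 5)
  expect_equal(attr(back$stream, "subject")$mass_kg, 67)
  expect_equal(back$stream$x_m, sess$stream$x_m)
  expect_equal(read_stream(path, dialect = "session-json")$y_m, sess$stream$y_m)
})

test_that("achievement rates aggregate like the clinical summary tables", {
  # per-subject means of the published step/squat tables
  controls <- utils::read.csv(system.file("extdata", "controls_step_achievement.csv",
                                          package = "rehabmotion"))
  patients <- utils::read.csv(system.file("extdata", "patients_achievement.csv",
                                          package = "rehabmotion"))
  expect_equal(aggregate_achievement(controls$right_step)$mean_display, 78L)
  expect_equal(aggregate_achievement(patients$right_knee)$mean_display, 86L)
  expect_equal(aggregate_achievement(patients$right_step)$mean_display, 66L)

  const <- aggregate_achievement(c(100, 100, 100))
  expect_equal(const$mean_display, 100L)
  expect_equal(const$sd, 0)

  s <- aggregate_achievement(c(80, 88, 84, 76, 80, 72, 72, 80, 68, 80))
  expect_gte(s$mean, min(s$rates))
  expect_lte(s$mean, max(s$rates))
  expect_error(aggregate_achievement(numeric(0)), "empty")

  expect_equal(achievement_rate(4), 80)
  expect_equal(achievement_rate(7, 5), 100)  # capped
  expect_equal(achievement_rate(0), 0)
})

test_that("reports carry the results and regenerate byte-identically", {
  sq <- gen_flexion_session(motion_plan("squat", repetitions = 3, seed = 17))
  res <- lapply(c("left", "right"), function(s)
    count_flexions_stream(sq$stream, flexion_config("knee", s)))
  names(res) <- c("left", "right")
  rec <- session_record(subject_profile("T01", 67), "squat",
                        res$right$config, res)
  dir1 <- withr::local_tempdir()
  files <- make_report(rec, dir1)
  expect_true(file.exists(file.path(dir1, "report.json")))
  expect_true(file.exists(file.path(dir1, "angle_trace.pdf")))
  rep_json <- jsonlite::read_json(file.path(dir1, "report.json"),
                                  simplifyVector = TRUE)
  expect_equal(rep_json$result$sides$right$flex_count, 3)
  expect_equal(rep_json$result$sides$left$flex_count, 3)

  dir2 <- withr::local_tempdir()
  make_report(rec, dir2)
  expect_identical(readBin(file.path(dir1, "report.json"), "raw", 1e6),
                   readBin(file.path(dir2, "report.json"), "raw", 1e6))

  # balance report lists the 8 scores in protocol order
  ba <- gen_balance_session(motion_plan("balance", compliance = rep(0.5, 8),
                                        seed = 18))
  rb <- score_balance(ba$stream, ba$cfg, mass_kg = 67)
  rec_b <- session_record(subject_profile("T02", 80), "balance", rb$config, rb)
  dir3 <- withr::local_tempdir()
  make_report(rec_b, dir3)
  summ <- readLines(file.path(dir3, "summary.txt"))
  dir_lines <- grep("^  (N|NE|E|SE|S|SW|W|NW) ", summ)
  got_order <- sub("^  (\\S+).*", "\\1", summ[dir_lines])
  expect_equal(got_order, c("N", "NE", "E", "SE", "S", "SW", "W", "NW"))
  expect_true(file.exists(file.path(dir3, "com_trajectory.pdf")))
})

test_that("configuration files override defaults and are echoed to reports", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("step:",
               "  hip_rise_threshold: 0.12",
               "balance:",
               "  level: 2",
               "  time_per_target: 5"), path)
  cfg <- load_config(path)
  expect_equal(cfg$step$hip_rise_threshold, 0.12)
  expect_equal(cfg$step$baseline_window, 2)          # untouched default
  expect_equal(cfg$balance$time_per_target, 5)
  expect_equal(cfg$balance$excursion, 0.06)          # level 2 geometry
  defaults <- load_config(NULL)
  expect_equal(defaults$step$hip_rise_threshold, 0.09)
})

test_that("the CLI wires simulate, analyze and summarize together", {
  td <- withr::local_tempdir()
  stream_path <- file.path(td, "squat.csv")
  status <- run_cli(c("simulate", "--exercise", "squat", "--reps", "4",
                      "--seed", "12", "--out", stream_path))
  expect_equal(status, 0L)
  expect_true(file.exists(stream_path))
  truth <- jsonlite::read_json(paste0(stream_path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$reps, 4)

  outdir <- file.path(td, "report")
  status <- suppressMessages(
    run_cli(c("analyze", "--exercise", "squat", "--input", stream_path,
              "--mass", "67", "--out", outdir)))
  expect_equal(status, 0L)
  rep_json <- jsonlite::read_json(file.path(outdir, "report.json"),
                                  simplifyVector = TRUE)
  expect_equal(rep_json$result$sides$right$flex_count, 4)

  sumdir <- file.path(td, "summary")
  status <- suppressMessages(
    run_cli(c("summarize", "--inputs", file.path(td, "report", "report.json"),
              "--prescribed", "5", "--out", sumdir)))
  expect_equal(status, 0L)
  ach <- jsonlite::read_json(file.path(sumdir, "achievement.json"),
                             simplifyVector = TRUE)
  expect_equal(ach$mean, 80)  # 4 of 5 on both sides

  # validation failures exit with status 2
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("analyze", "--exercise", "squat"))), 2L)
})
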