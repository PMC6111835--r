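# Detectors: hysteresis repetition counting, step climbs, balance scoring.

knee_trace <- function(x) data.frame(time_s = seq_along(x) - 1, angle_deg = x)

test_that("hysteresis automaton counts flexed-then-extended cycles", {
  knee <- flexion_config("knee")
  expect_equal(count_flexions(knee_trace(c(10, 80, 10)), knee)$flex_count, 1)
  expect_equal(count_flexions(knee_trace(c(10, 60, 10)), knee)$flex_count, 0)
  # partial extension between thresholds does not complete a repetition
  expect_equal(count_flexions(knee_trace(c(10, 80, 50, 80, 10)), knee)$flex_count, 1)
  # sitting exactly on a threshold cannot oscillate the automaton
  expect_equal(count_flexions(knee_trace(c(70, 70, 70, 30)), knee)$flex_count, 1)
  # elbow thresholds live on the interior scale (series stays deviation)
  elbow <- flexion_config("elbow")
  dev <- c(0, 140, 0, 135, 60, 0)  # interior: 180, 40, 180, 45, 120, 180
  expect_equal(count_flexions(knee_trace(dev), elbow)$flex_count, 2)
  # event times bracket each repetition
  r <- count_flexions(knee_trace(c(10, 80, 10, 80, 10)), knee)
  expect_equal(r$flex_count, 2)
  expect_equal(r$events$t_flexed, c(1, 3))
  expect_equal(r$events$t_extended, c(2, 4))
  expect_warning(r0 <- count_flexions(knee_trace(numeric(0)), knee), "empty")
  expect_equal(r0$flex_count, 0)
})

test_that("counting agrees with a per-sample brute-force oracle on random traces", {
  set.seed(99)
  cfg <- flexion_config("knee")
  for (i in 1:1000) {
    x <- random_trace(sample(5:60, 1))
    expect_identical(count_flexions(knee_trace(x), cfg)$flex_count,
                     flexion_oracle(x, 70, 30))
  }
})

test_that("counting is monotone and bounded by flexed-threshold crossings", {
  set.seed(7)
  cfg <- flexion_config("knee")
  for (i in 1:50) {
    x <- random_trace(sample(10:40, 1))
    n0 <- count_flexions(knee_trace(x), cfg)$flex_count
    # appending one full cycle adds exactly one repetition
    x_ext <- c(x, 80, 10)
    n1 <- count_flexions(knee_trace(x_ext), cfg)$flex_count
    expect_identical(n1, n0 + 1L)
    # flexCount never decreases as the trace extends
    for (cut in sample(seq_along(x), 3))
      expect_lte(count_flexions(knee_trace(x[1:cut]), cfg)$flex_count, n0 + 0L)
    # bounded by the number of upward flexed-threshold crossings
    above <- x >= 70
    crossings <- sum(diff(c(FALSE, above)) == 1)
    expect_lte(n0, crossings)
  }
})

test_that("step climbs need the hip rise and the knee cycle to overlap", {
  # planted session: 4 right-foot climbs
  sess <- gen_step_session(motion_plan("step", repetitions = 4, side = "right",
                                       seed = 21))
  res <- count_steps(sess$stream)
  expect_equal(unname(res$climbs), c(0L, 4L))
  expect_equal(unname(res$descents), c(0L, 4L))
  expect_lte(res$descents[["right"]], res$climbs[["right"]] + 1L)

  # quiet standing counts nothing
  still <- gen_step_session(motion_plan("step", repetitions = 0, seed = 22))
  expect_equal(unname(count_steps(still$stream)$climbs), c(0L, 0L))

  # hip rise with straight knees (tip-toe artifact): condition (b) unmet
  tiptoe <- gen_step_session(motion_plan("step", repetitions = 3, seed = 23,
                                         amplitude = 0.001, step_height = 0.12))
  expect_equal(unname(count_steps(tiptoe$stream)$climbs), c(0L, 0L))
  expect_equal(tiptoe$truth$climbs[["right"]], 0L)

  # knee cycles without body rise: condition (a) unmet
  lowrise <- gen_step_session(motion_plan("step", repetitions = 3, seed = 24,
                                          step_height = 0.03))
  expect_equal(unname(count_steps(lowrise$stream)$climbs), c(0L, 0L))

  # left-foot sessions credit the left foot
  left <- gen_step_session(motion_plan("step", repetitions = 2, side = "left",
                                       seed = 25))
  expect_equal(unname(count_steps(left$stream)$climbs), c(2L, 0L))
})

test_that("ankle angles are recorded but never consulted by the step detector", {
  plan <- motion_plan("step", repetitions = 4, side = "right", seed = 31)
  clean <- count_steps(gen_step_session(plan)$stream)
  expect_equal(nrow(clean$ankle_angles$right),
               length(unique(gen_step_session(plan)$stream$time_s)))
  # heavy dropout on the ankles leaves the counts untouched
  plan_d <- motion_plan("step", repetitions = 4, side = "right", seed = 31,
                        dropout_rate = 0.3,
                        dropout_joints = c("FootLeft", "FootRight"))
  noisy <- count_steps(gen_step_session(plan_d)$stream)
  expect_equal(noisy$climbs, clean$climbs)
  expect_lt(nrow(noisy$ankle_angles$right), nrow(clean$ankle_angles$right))
})

test_that("count_steps fails without a hip center and warns without knees", {
  sess <- gen_step_session(motion_plan("step", repetitions = 1, seed = 41))
  no_hip <- sess$stream
  no_hip$state[no_hip$joint == "SpineBase"] <- "NotTracked"
  no_hip <- skeleton_stream(as.data.frame(no_hip), validate = FALSE)
  expect_error(count_steps(no_hip), "SpineBase")
})

test_that("balance scores are the planted percentage of time on target", {
  # full compliance: 100 everywhere
  full <- gen_balance_session(motion_plan("balance", compliance = rep(1, 8),
                                          seed = 51))
  r <- score_balance(full$stream, full$cfg, mass_kg = 67)
  expect_equal(unname(r$scores), rep(100, 8))
  expect_false(any(r$incomplete))
  expect_equal(names(r$scores), c("N", "NE", "E", "SE", "S", "SW", "W", "NW"))

  # never leaving the start: 0 everywhere
  idle <- gen_balance_session(motion_plan("balance", compliance = rep(0, 8),
                                          seed = 52))
  r0 <- score_balance(idle$stream, idle$cfg, mass_kg = 67)
  expect_equal(unname(r0$scores), rep(0, 8))

  # half-time on the east target only
  east <- gen_balance_session(motion_plan("balance",
                                          compliance = c(0, 0, 0.5, 0, 0, 0, 0, 0),
                                          seed = 53))
  re <- score_balance(east$stream, east$cfg, mass_kg = 67)
  expect_equal(unname(re$scores[["E"]]), 50)
  expect_equal(unname(re$scores[c("N", "NE", "SE", "S", "SW", "W", "NW")]),
               rep(0, 7))

  # alternating plan
  alt <- gen_balance_session(motion_plan("balance",
                                         compliance = c(1, 0, 1, 0, 1, 0, 1, 0),
                                         seed = 54))
  ra <- score_balance(alt$stream, alt$cfg, mass_kg = 67)
  expect_equal(unname(ra$scores), rep(c(100, 0), 4))
})

test_that("balance scoring is invariant to rigid XZ translation of the session", {
  sess <- gen_balance_session(motion_plan("balance",
                                          compliance = c(0.2, 0.9, 0.5, 0, 1, 0.4, 0.7, 0.3),
                                          seed = 61, level = 2))
  r1 <- score_balance(sess$stream, sess$cfg, mass_kg = 67)
  shifted <- as.data.frame(sess$stream)
  shifted$x_m <- shifted$x_m + 0.8
  shifted$z_m <- shifted$z_m - 0.35
  r2 <- score_balance(skeleton_stream(shifted), sess$cfg, mass_kg = 67)
  expect_equal(r2$scores, r1$scores, tolerance = 1e-9)
  expect_equal(unname(r2$idle_pos[c("x", "z")] - r1$idle_pos[c("x", "z")]),
               c(0.8, -0.35), tolerance = 1e-9)
  expect_true(all(r1$scores >= 0 & r1$scores <= 100))
  # the completed protocol spans at least 8 windows
  expect_gte(max(sess$stream$time_s) - min(sess$stream$time_s),
             8 * sess$cfg$time_per_target)
})

test_that("a truncated balance stream flags the unvisited directions incomplete", {
  sess <- gen_balance_session(motion_plan("balance", compliance = rep(0.6, 8),
                                          seed = 71))
  cut_t <- sort(unique(sess$stream$time_s))
  cut_at <- cut_t[floor(length(cut_t) * 0.45)]  # ~3.5 directions in
  short <- skeleton_stream(as.data.frame(sess$stream)[sess$stream$time_s <= cut_at, ],
                           validate = FALSE)
  r <- score_balance(short, sess$cfg, mass_kg = 67)
  expect_true(any(r$incomplete))
  done <- !r$incomplete
  expect_true(any(done))
  expect_equal(unname(r$scores[done]), rep(60, sum(done)), tolerance = 0.5)
  expect_true(all(is.na(r$scores[r$incomplete])))
})
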