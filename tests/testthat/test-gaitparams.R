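test_that("step geometry formulas match hand calculations", {
  # length: hypotenuse of AP and VT separations, ML excluded
  expect_equal(step_length_cm(c(0, 0.60, 0), c(0, 0, 0)), 60)
  expect_equal(step_length_cm(c(0.2, 0.60, 0.03), c(-0.1, 0, 0)),
               100 * sqrt(0.36 + 0.0009))
  expect_equal(step_length_cm(c(0, 0, 0), c(0, 0, 0)), 0)
  # width: |ML| difference
  expect_equal(step_width_cm(c(0.10, 1, 0), c(-0.10, 0.4, 0)), 20)
  expect_equal(step_width_cm(c(0.07, 1, 0), c(0.07, 0.4, 0)), 0)
})

test_that("speed averages the belt channel over the step", {
  expect_equal(step_speed(rep(1.33, 100), 1, 101), 1.33)
  expect_equal(step_speed(seq(1.0, 1.2, length.out = 101), 1, 101), 1.1,
               tolerance = 1e-3)
  expect_equal(step_speed(rep(0, 50), 10, 20), 0)
  expect_error(step_speed(rep(1, 50), 10, 10), "interval")
})

test_that("pendulum model follows omega = sqrt(g / l)", {
  expect_equal(pendulum_model(9.81)$omega, 1)
  expect_equal(pendulum_model(0.981)$omega, sqrt(10), tolerance = 1e-9)
  expect_error(pendulum_model(0), "positive")
  # omega strictly decreasing in l
  l <- seq(0.5, 1.5, by = 0.05)
  om <- vapply(l, function(x) pendulum_model(x)$omega, numeric(1))
  expect_true(all(diff(om) < 0))
})

test_that("extrapolated CoM and the margin of stability match closed forms", {
  m <- pendulum_model(0.981)
  expect_equal(extrapolated_com(0.10, 0.20, m), 0.10 + 0.20 / sqrt(10),
               tolerance = 1e-9)
  expect_equal(extrapolated_com(0.10, 0.20, m), 0.16325, tolerance = 1e-4)
  expect_equal(extrapolated_com(0.25, 0, m), 0.25)        # static reduction
  expect_lt(extrapolated_com(0, -0.3, m), 0)

  expect_equal(ml_margin_of_stability(0.15, 0.163, "R"), -1.3,
               tolerance = 1e-9)
  expect_equal(ml_margin_of_stability(0.15, 0.15, "R"), 0)
  expect_equal(ml_margin_of_stability(-0.15, -0.10, "L"), 5, tolerance = 1e-9)
  expect_error(ml_margin_of_stability(0, 0, "M"), "side")

  # chain consistency: zero velocity reduces MoS to side-signed heel - CoM
  set.seed(8)
  for (r in 1:50) {
    heel <- runif(1, -0.3, 0.3)
    p <- runif(1, -0.2, 0.2)
    l <- runif(1, 0.5, 1.5)
    mm <- pendulum_model(l)
    expect_equal(ml_margin_of_stability(heel, extrapolated_com(p, 0, mm), "R"),
                 100 * (heel - p), tolerance = 1e-12)
    expect_equal(ml_margin_of_stability(heel, extrapolated_com(p, 0, mm), "L"),
                 100 * (p - heel), tolerance = 1e-12)
  }
})

test_that("trunk angle follows atan2 of the AP/VT offsets", {
  expect_equal(trunk_angle(c(0, 0, 0), c(0, 0, 0.5)), 0)
  expect_equal(trunk_angle(c(0, 0, 0), c(0, 0.1, 0.5)), atan(0.2) * 180 / pi)
  expect_equal(trunk_angle(c(0, 0, 0), c(0, -0.1, 0.5)),
               -atan(0.2) * 180 / pi)
  expect_error(trunk_angle(c(0, 0, 1), c(0, 0, 0.5)), "above")
})

test_that("CoV matches hand values and is scale invariant", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(4, 6)), 100 * sqrt(2) / 5,
               tolerance = 1e-9)
  expect_equal(coefficient_of_variation(c(4, 6)), 28.28, tolerance = 1e-2)
  set.seed(2)
  x <- rnorm(20, 10, 2)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  # time-reversal invariance
  expect_equal(coefficient_of_variation(rev(x)), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("trunk RMS reduces to known closed forms", {
  iv <- cbind(c(1, 101), c(101, 201))
  expect_equal(trunk_rms(rep(2.5, 210), iv), 2.5)
  expect_equal(trunk_rms(rep(c(1, -1), 105), iv), 1)
  a <- 3 * sin(2 * pi * (0:209) / 100)  # full periods per 100-sample step
  expect_equal(trunk_rms(a, iv), 3 / sqrt(2), tolerance = 1e-3)
  expect_true(is.na(trunk_rms(a, iv[0, , drop = FALSE])))
})

test_that("step skeleton and timing agree with hand-built event sets", {
  fs <- 100
  ev <- structure(list(hs = list(L = c(1L, 101L, 201L), R = c(51L, 151L)),
                       to = list(L = c(66L, 166L), R = c(16L, 116L, 216L)),
                       sample_rate_hz = fs), class = "gait_events")
  # alternating strikes 0.5 s apart -> 4 steps of 0.5 s
  st <- steps_from_events(ev)
  expect_equal(nrow(st), 4)
  expect_equal(st$side, c("R", "L", "R", "L"))
  expect_equal((st$end - st$start) / fs, rep(0.5, 4))

  # DST: toe-offs 0.15 s after each opposite heel strike -> 30% of stride
  td <- slopegait:::step_time_dst_at(
    data.frame(side = c("L", "R", "L", "R", "L"),
               idx = c(1L, 51L, 101L, 151L, 201L)),
    ev$to, k = 2, fs)
  expect_equal(td$time_s, 0.5)
  expect_equal(td$dst_pct, 30)

  # toe-off simultaneous with the contralateral strike -> 0% double support
  ev0 <- list(L = c(101L, 201L), R = c(51L, 151L))
  td0 <- slopegait:::step_time_dst_at(
    data.frame(side = c("L", "R", "L", "R", "L"),
               idx = c(1L, 51L, 101L, 151L, 201L)),
    list(L = c(51L, 151L), R = c(1L, 101L, 201L)), k = 2, fs)
  expect_equal(td0$dst_pct, 0)

  # single heel strike -> empty step table
  ev1 <- structure(list(hs = list(L = 10L, R = integer(0)),
                        to = list(L = integer(0), R = integer(0)),
                        sample_rate_hz = fs), class = "gait_events")
  expect_equal(nrow(steps_from_events(ev1)), 0)
})

test_that("refusing to build steps from a corrupted event set", {
  ev <- structure(list(hs = list(L = c(100L, 200L, 300L), R = c(150L, 350L)),
                       to = list(L = c(170L, 370L), R = c(120L, 220L)),
                       sample_rate_hz = 100), class = "gait_events")
  expect_error(steps_from_events(ev), "integrity")
})

test_that("level-step selection applies the distance window", {
  # constant 1.25 m/s: distance window [10, 30) maps to t in [8, 24) s
  fs <- 100
  n <- 30 * fs
  df <- data.frame(time_s = (0:(n - 1)) / fs)
  for (ch in setdiff(slopegait:::trial_channels(), "time_s")) df[[ch]] <- 0
  df$LPSIS_Z <- df$RPSIS_Z <- df$COM_Z <- 0.9
  df$C7_Z <- 1.4
  df$belt_speed_mps <- 1.25
  rec <- trial_recording(df, fs)
  steps <- data.frame(step = 1:3, side = "L",
                      start = c(700L, 801L, 2500L),
                      end = c(800L, 901L, 2600L))
  sel <- select_level_steps(rec, steps)
  # heel strikes at 8.0 s (= 10 m exactly, included), 9.0 s, 26 s (excluded)
  expect_equal(sel, c(TRUE, TRUE, FALSE))
  late <- data.frame(step = 1, side = "L", start = 2900L, end = 2999L)
  expect_warning(sel2 <- select_level_steps(rec, late), "no level steps")
  expect_false(any(sel2))
})

test_that("full-chain recovery matches generator ground truth", {
  sim <- quick_trial(step_time_s = 0.5, n_steps = 40, seed = 3)
  st <- compute_step_table(sim$recording)
  tr <- sim$truth
  m <- min(nrow(st), nrow(tr))
  expect_equal(nrow(st), nrow(tr))
  expect_lt(max(abs(st$length_cm[1:m] - tr$length_cm[1:m]) / tr$length_cm[1:m]),
            0.01)
  expect_lt(max(abs(st$width_cm[1:m] - tr$width_cm[1:m]) / tr$width_cm[1:m]),
            0.01)
  expect_lte(max(abs(st$time_s[1:m] - tr$time_s[1:m])) * 100, 1)
  ok <- !is.na(st$dst_pct[1:m]) & !is.na(tr$dst_pct[1:m])
  expect_lt(max(abs(st$dst_pct[1:m][ok] - tr$dst_pct[1:m][ok])), 1)
  expect_true(all(st$mos_cm > 0))
  expect_equal(mean(st$trunk_angle_deg), attr(tr, "trunk_angle_deg"),
               tolerance = 0.01)
})

test_that("condition summaries aggregate per slope class", {
  sim <- quick_trial(step_time_s = 0.5, n_steps = 30, noise_sd_m = 0.003,
                     jitter_frac = 0.03, seed = 6)
  st <- compute_step_table(sim$recording)
  st$slope_class <- rep(c("uphill", "downhill", "level"),
                        length.out = nrow(st))
  sm <- summarize_conditions(st)
  expect_equal(sort(sm$slope_class), sort(c("uphill", "downhill", "level")))
  expect_true(all(sm[, grep("_cov$", names(sm))] >= 0))
  expect_true(all(sm$n_steps >= 3))
  # below the floor nothing is reported
  st2 <- st[1:4, ]
  st2$slope_class <- c("uphill", "uphill", "downhill", "downhill")
  sm2 <- summarize_conditions(st2, min_steps = 3)
  expect_null(sm2)
})
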