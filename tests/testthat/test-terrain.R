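test_that("terrain config validates its invariants", {
  expect_error(terrain_config(frequencies_hz = numeric(0)), "frequency")
  expect_error(terrain_config(frequencies_hz = c(0.2, -0.1),
                              amplitudes = c(1, 1), phases_rad = c(0, 0)),
               "positive")
  expect_error(terrain_config(frequencies_hz = c(0.2, 0.2),
                              amplitudes = c(1, 1), phases_rad = c(0, 0)),
               "distinct")
  expect_error(terrain_config(peak_deg = 0), "peak_deg")
  expect_error(terrain_config(duration_s = -1), "duration")
  expect_error(terrain_config(sample_rate_hz = 0.5), "twice")
})

test_that("pitch generator matches the closed form and normalizes the peak", {
  cfg <- terrain_config(duration_s = 600)
  pitch <- generate_platform_pitch(cfg)
  expect_length(pitch, 600 * 100)
  expect_equal(pitch[1], 0)                      # all phases 0 at t = 0
  expect_equal(max(abs(pitch)), 3, tolerance = 1e-9)

  # single component: 3 * sin(2 pi 0.25 t) evaluated at t = 1 s
  c1 <- terrain_config(frequencies_hz = 0.25, amplitudes = 1, phases_rad = 0,
                       peak_deg = 3, duration_s = 8)
  p1 <- generate_platform_pitch(c1)
  expect_equal(p1[101], 3 * sin(pi / 2), tolerance = 1e-9)

  # normalization holds for arbitrary configs
  set.seed(4)
  for (r in 1:5) {
    cfgr <- terrain_config(frequencies_hz = sort(runif(3, 0.05, 0.6)),
                           amplitudes = runif(3, 0.2, 2),
                           peak_deg = runif(1, 1, 5),
                           duration_s = 120,
                           phase_seed = r)
    pr <- generate_platform_pitch(cfgr)
    expect_equal(max(abs(pr)), cfgr$peak_deg, tolerance = 1e-9)
  }
})

test_that("random phases are reproducible and leave the global RNG alone", {
  set.seed(99)
  before <- .Random.seed
  c1 <- terrain_config(phase_seed = 7)
  c2 <- terrain_config(phase_seed = 7)
  expect_identical(c1$phases_rad, c2$phases_rad)
  expect_false(all(c1$phases_rad == 0))
  expect_identical(before, .Random.seed)
})

test_that("extremum locator agrees with a brute-force scan", {
  expect_identical(locate_extrema(1:50), integer(0))        # monotone ramp
  expect_identical(locate_extrema(rep(2, 30)), integer(0))  # constant
  expect_error(locate_extrema(c(1, 2)), "3 samples")

  # sampled sine: extrema near quarter-period samples
  x <- sin(2 * pi * (0:199) / 100)
  found <- locate_extrema(x)
  expect_equal(length(found), 4)
  expect_true(all(abs(found - c(26, 76, 126, 176)) <= 1))

  # brute-force oracle on random smooth signals
  set.seed(11)
  for (r in 1:20) {
    t <- seq(0, 10, by = 0.01)
    y <- rowSums(sapply(1:3, function(k)
      runif(1, 0.5, 2) * sin(2 * pi * runif(1, 0.1, 0.8) * t + runif(1, 0, 2 * pi))))
    brute <- which(vapply(2:(length(y) - 1), function(i) {
      (y[i - 1] < y[i] && y[i] > y[i + 1]) ||
        (y[i - 1] > y[i] && y[i] < y[i + 1])
    }, logical(1))) + 1L
    expect_identical(locate_extrema(y), brute)
  }

  # plateau flanked by lower values reports its first sample
  expect_identical(locate_extrema(c(0, 1, 2, 2, 2, 1, 0)), 3L)
})

test_that("step slope classifier applies band and extremum rules", {
  pitch <- rep(2, 100)
  cls <- classify_step_slope(10, 40, pitch, extrema = integer(0))
  expect_equal(cls$class_label, "uphill")
  expect_equal(cls$mean_pitch_deg, 2)
  expect_false(cls$spans_extremum)

  # shaded band |mean| < 1 is excluded
  expect_equal(classify_step_slope(10, 40, rep(0.5, 100), integer(0))$class_label,
               "excluded")
  # an extremum strictly inside excludes regardless of the mean
  cls2 <- classify_step_slope(10, 40, pitch, extrema = 25L)
  expect_equal(cls2$class_label, "excluded")
  expect_true(cls2$spans_extremum)
  # extrema exactly at the boundaries do not exclude
  expect_equal(classify_step_slope(10, 40, pitch, extrema = c(10L, 40L))$class_label,
               "uphill")
  # band edges are inclusive
  expect_equal(classify_step_slope(1, 11, rep(1, 20), integer(0))$class_label,
               "uphill")
  expect_equal(classify_step_slope(1, 11, rep(3, 20), integer(0))$class_label,
               "uphill")
  expect_equal(classify_step_slope(1, 11, rep(-1, 20), integer(0))$class_label,
               "downhill")
  expect_equal(classify_step_slope(1, 11, rep(-3.01, 20), integer(0))$class_label,
               "excluded")
  expect_error(classify_step_slope(5, 5, pitch), "start")
})

test_that("classifier agrees with a brute-force oracle on random intervals", {
  set.seed(21)
  for (r in 1:200) {
    t <- seq(0, 30, by = 0.01)
    y <- 3 * sin(2 * pi * runif(1, 0.1, 0.4) * t + runif(1, 0, 2 * pi)) +
      1.5 * sin(2 * pi * runif(1, 0.02, 0.1) * t)
    ext <- locate_extrema(y)
    s <- sample(length(y) - 20, 1)
    e <- s + sample(10:100, 1)
    e <- min(e, length(y))
    got <- classify_step_slope(s, e, y, ext)
    # direct re-derivation
    mp <- sum(y[s:(e - 1)]) / (e - s)
    sp <- FALSE
    for (i in (s + 1):(e - 1)) {
      if (i >= 2 && i < length(y) &&
          ((y[i - 1] < y[i] && y[i] > y[i + 1]) ||
           (y[i - 1] > y[i] && y[i] < y[i + 1]))) sp <- TRUE
    }
    lab <- if (!sp && mp >= 1 && mp <= 3) "uphill"
           else if (!sp && mp <= -1 && mp >= -3) "downhill" else "excluded"
    expect_equal(got$class_label, lab)
    expect_equal(got$mean_pitch_deg, mp, tolerance = 1e-12)
  }
})

test_that("default spectrum shows the four configured components", {
  cfg <- terrain_config(duration_s = 600)
  pitch <- as.numeric(generate_platform_pitch(cfg))
  n <- length(pitch)
  spec <- Mod(stats::fft(pitch))[1:(n / 2)]^2
  freq <- (seq_len(n / 2) - 1) * cfg$sample_rate_hz / n
  keep <- freq <= 1
  spec <- spec[keep]; freq <- freq[keep]
  pk <- locate_extrema(spec)
  pk <- pk[spec[pk] > 0.1 * max(spec)]
  pk <- pk[spec[pk] > spec[pmax(1, pk - 1)]]  # maxima only
  expect_equal(length(pk), 4)
  expect_equal(sort(freq[pk]), cfg$frequencies_hz,
               tolerance = (freq[2] - freq[1]) / min(cfg$frequencies_hz))
})
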