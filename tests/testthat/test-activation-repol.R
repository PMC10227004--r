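test_that("activation lands at the center of a symmetric upstroke", {
  tt <- seq(0, 198, by = 2)
  tr <- 1 / (1 + exp(-(tt - 50) / 2))          # sigmoid centered at 50 ms
  w <- list(start = 20, end = 180, stimulus_time = 30)
  expect_lt(abs(activation_time(tr, w) - 50), 0.5)
})

test_that("a flat trace yields a missing activation, not an error", {
  tr <- rep(0.2, 100)
  w <- list(start = 20, end = 180, stimulus_time = 30)
  expect_true(is.na(activation_time(tr, w)))
})

test_that("plane-wave activation differences match distance over velocity", {
  pw <- quick_wave(cv = 50, apd80 = 75, n = 48)
  mv <- normalize_movie(pw$movie)
  w <- segment_beats(mv)[2, ]
  t1 <- activation_time(mv$frames[, 24, 4], w)
  t2 <- activation_time(mv$frames[, 24, 44], w)
  expect_lt(abs((t2 - t1) - 40 * 30 / 128 / 0.5), 0.5)
})

test_that("triangular action potential gives the closed-form APD80", {
  # instant upstroke at 10 ms from 0 to 1, linear decay hitting 0 at 110 ms:
  # the 0.2 level is crossed at 90 ms, so APD80 = 80 ms
  tt <- seq(0, 298, by = 2)
  tr <- ifelse(tt < 10, 0, pmax(1 - (tt - 10) / 100, 0))
  w <- list(start = 0, end = 290, stimulus_time = 8)
  apd <- apd80(tr, t_act = 10, w)
  expect_equal(apd, 80, tolerance = 1e-6)
})

test_that("a pulse that never repolarizes inside the window is missing", {
  tt <- seq(0, 298, by = 2)
  tr <- ifelse(tt < 50, 0, 1)
  w <- list(start = 20, end = 290, stimulus_time = 40)
  expect_true(is.na(apd80(tr, t_act = 50, w)))
})

test_that("plane-wave APD80 is recovered at every valid pixel", {
  pw <- quick_wave(cv = 60, apd80 = 75, n = 48)
  maps <- build_maps(pw$movie)
  v <- maps[["400"]]$apd$values
  expect_gt(mean(is.finite(v)), 0.95)
  expect_lt(max(abs(v - 75), na.rm = TRUE), 1)
})

test_that("beat averaging tolerates missing beats and records the count", {
  expect_equal(as.numeric(beat_average(c(70, 72, 74))), 72)
  m <- beat_average(c(70, NA, 74))
  expect_equal(as.numeric(m), 72)
  expect_equal(attr(m, "n"), 2L)
  none <- beat_average(c(NA_real_, NA_real_))
  expect_true(is.na(none))
  expect_equal(attr(none, "n"), 0L)
  # no more than n_beats values contribute
  expect_equal(as.numeric(beat_average(c(1, 2, 3, 100), n_beats = 3)), 2)
})

test_that("steady pacing makes the 3-beat mean close to any single beat", {
  sim <- sim_control_400()
  maps <- build_maps(sim$movie)
  roi <- default_roi(sim$movie)
  gt <- sim$ground_truth
  sel <- which(!vapply(gt$beats, `[[`, TRUE, "transient"))
  per_beat <- vapply(gt$beats[sel], function(b)
    mean(b$apd80[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]], na.rm = TRUE), 0)
  expect_lt(max(abs(per_beat - mean(per_beat))), 1)
})

test_that("diastolic interval is CL minus APD80, defined only when positive", {
  expect_equal(diastolic_interval(400, 108.362), 291.638)
  expect_equal(diastolic_interval(300, 66.672), 233.328)
  expect_error(diastolic_interval(200, 200), "shorter")
  expect_error(diastolic_interval(200, 260), "shorter")
})

test_that("maps respect window ordering for every valid pixel", {
  pw <- quick_wave(cv = 45, apd80 = 90, n = 32)
  mv <- normalize_movie(pw$movie)
  w <- segment_beats(mv)
  sel <- w[w$selected, ][1, ]
  tt <- frame_times(mv)
  for (px in list(c(5, 5), c(16, 20), c(30, 28))) {
    tr <- mv$frames[, px[1], px[2]]
    ta <- activation_time(tr, sel)
    ap <- apd80(tr, ta, sel)
    expect_gt(ta, sel$start)
    expect_lt(ta + ap, sel$end)
  }
})

test_that("sub-sample refinement stays within one frame of the argmax", {
  set.seed(44)
  tt <- seq(0, 398, by = 2)
  w <- list(start = 20, end = 380, stimulus_time = 30)
  for (i in 1:25) {
    ta_true <- runif(1, 60, 200)
    tr <- 1 / (1 + exp(-(tt - ta_true) / runif(1, 0.5, 3))) +
      rnorm(length(tt), 0, 0.02)
    ta <- activation_time(tr, w)
    if (is.na(ta)) next
    d <- diff(tr) / 2
    discrete <- tt[which.max(d) ] + 1     # argmax of forward difference
    expect_lt(abs(ta - discrete), 2.5)
  }
})

test_that("homogeneous plane wave yields a spatially uniform APD map", {
  pw <- quick_wave(cv = 55, apd80 = 85, n = 32)
  maps <- build_maps(pw$movie)
  expect_lt(maps[["400"]]$summary$sd_apd80, 1)
  expect_false(maps[["400"]]$summary$low_quality)
})

test_that("a fully masked movie is flagged rather than crashing", {
  pw <- quick_wave(n = 24, beats = 2)
  noise_only <- add_acquisition_noise(
    voltage_movie(array(0.5, dim(pw$movie$frames)) + pw$movie$frames * 1e-4,
                  polarity = "fluorescence_down",
                  protocol = pw$movie$protocol,
                  stimulus_times = pw$movie$stimulus_times,
                  stimulus_cls = pw$movie$stimulus_cls),
    snr = 0.5, seed = 2)
  maps <- tryCatch(build_maps(noise_only), error = function(e) e)
  if (inherits(maps, "error")) {
    expect_match(conditionMessage(maps), "analyzable|dynamic")
  } else {
    expect_true(maps[[1]]$summary$low_quality ||
                  maps[[1]]$summary$frac_valid < 0.5)
  }
})
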