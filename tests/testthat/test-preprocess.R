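test_that("normalization flips dye polarity and is idempotent", {
  pw <- quick_wave(n = 32, polarity = "fluorescence_down")
  mv <- normalize_movie(pw$movie)
  expect_equal(mv$polarity, "voltage_up")
  # upstroke is positive-going at an active pixel: value rises at activation
  tr <- mv$frames[, 16, 20]
  tt <- frame_times(mv)
  ta <- pw$ground_truth$beats[[1]]$activation[16, 20] + 20
  i <- which.min(abs(tt - ta))
  expect_gt(tr[i + 2] - tr[i - 2], 0.5)
  # idempotence
  again <- normalize_movie(mv)
  expect_lt(max(abs(again$frames - mv$frames)), 1e-6)
})

test_that("flat pixels are flagged but untouched; all-flat movies refuse", {
  pw <- quick_wave(n = 24, beats = 2)
  fr <- pw$movie$frames
  fr[, 3, 4] <- 0.5
  mv <- voltage_movie(fr, polarity = "fluorescence_down",
                      protocol = pw$movie$protocol,
                      stimulus_times = pw$movie$stimulus_times,
                      stimulus_cls = pw$movie$stimulus_cls)
  norm <- normalize_movie(mv)
  expect_true(norm$mask$flat[3, 4])
  expect_false(norm$mask$analyzable[3, 4])
  expect_true(all(norm$frames[, 3, 4] == -0.5))  # sign-flipped, not rescaled
  flat <- voltage_movie(array(0.3, c(50, 16, 16)), stimulus_times = 10,
                        stimulus_cls = 400)
  expect_error(normalize_movie(flat), "no dynamic signal")
})

test_that("robust rescale keeps nearly all samples in [-0.05, 1.05]", {
  pw <- quick_wave(n = 32)
  noisy <- add_acquisition_noise(pw$movie, snr = 10, drift_amplitude = 0.05,
                                 seed = 3)
  mv <- normalize_movie(noisy)
  ok <- as.vector(mv$mask$analyzable)
  m <- mv$frames
  dim(m) <- c(dim(m)[1], prod(dim(m)[2:3]))
  frac <- mean(m[, ok] >= -0.05 & m[, ok] <= 1.05)
  expect_gt(frac, 0.97)
})

test_that("identity filter settings return the movie bit-for-bit", {
  pw <- quick_wave(n = 24, beats = 2)
  out <- filter_movie(pw$movie, spatial_sigma = 0, temporal_window = 1)
  expect_identical(out$frames, pw$movie$frames)
  expect_error(filter_movie(pw$movie, temporal_window = 4), "odd")
  expect_error(filter_movie(pw$movie, temporal_window = 10001), "longer")
})

test_that("temporal smoothing barely moves a clean activation estimate", {
  pw <- quick_wave(cv = 45, apd80 = 80, n = 32)
  raw <- normalize_movie(pw$movie)
  sm <- filter_movie(raw, spatial_sigma = 0, temporal_window = 5)
  w <- segment_beats(raw)[2, ]
  t_raw <- activation_time(raw$frames[, 16, 16], w)
  t_sm <- activation_time(sm$frames[, 16, 16], w)
  expect_lt(abs(t_raw - t_sm), 2)        # under one frame interval
})

test_that("filtering a noisy movie improves CV recovery", {
  pw <- quick_wave(cv = 60, apd80 = 80, n = 48)
  noisy <- add_acquisition_noise(pw$movie, snr = 5, seed = 21)
  norm <- normalize_movie(noisy)
  act_f <- build_maps(filter_movie(norm, 1, 5))[["400"]]$activation
  act_r <- build_maps(norm)[["400"]]$activation
  # same probe for both: endpoints valid in both maps along the mid row
  ok <- which(is.finite(act_f$values[24, ]) & is.finite(act_r$values[24, ]))
  probe <- vector_probe(c(24, min(ok[ok >= 5]) - 1), c(24, max(ok[ok <= 44]) - 1),
                        pixel_pitch = 30 / 128)
  err <- function(a) abs(as.numeric(single_vector_cv(a, probe)) - 60)
  e_filtered <- err(act_f)
  e_raw <- err(act_r)
  expect_lt(e_filtered, e_raw + 1e-9)
  expect_lt(e_filtered / 60, 0.05)
})

test_that("beat segmentation tiles each train and selects three beats", {
  pw <- quick_wave(n = 24, cl = 300, beats = 4)
  w <- segment_beats(pw$movie)
  expect_equal(nrow(w), 4)
  expect_true(all(diff(w$start) == 300))
  # windows tile without overlap
  expect_equal(w$start[-1], w$end[-nrow(w)])
  expect_equal(w$beat_index, 0:3)
  expect_equal(which(w$selected), 2:4)
  expect_true(w$transient[1])
  expect_true(all(w$end - w$start <= 300))
})

test_that("a single-stimulus cycle length is flagged unanalyzable", {
  pw <- quick_wave(n = 24, cl = 300, beats = 4)
  mv <- pw$movie
  mv$stimulus_times <- c(mv$stimulus_times[1:4], 1300)
  mv$stimulus_cls <- c(mv$stimulus_cls[1:4], 150)
  w <- segment_beats(mv)
  expect_false(w$analyzable[5])
  expect_equal(attr(w, "unanalyzable_cls"), 150)
  expect_true(all(w$analyzable[1:4]))
})

test_that("default protocol selects exactly three beats per cycle length", {
  pr <- pacing_protocol(cycle_lengths = c(400, 300), beats_per_cl = 4)
  pw <- plane_wave_movie(60, 80, params = small_params(24), protocol = pr)
  w <- segment_beats(pw$movie)
  for (cl in c(400, 300))
    expect_equal(sum(w$selected[w$cl == cl]), 3)
})
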