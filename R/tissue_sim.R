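#' Tissue model parameters
#'
#' Parameters of the synthetic excitable sheet: grid geometry plus the
#' reaction-diffusion constants that set conduction velocity and action
#' potential duration. The default grid reproduces a 128 x 128 sensor over
#' a 30 x 30 mm field (pitch 30/128 = 0.234375 mm/pixel).
#'
#' `diffusivity` (mm^2/ms) sets conduction velocity (CV scales with the
#' square root of diffusivity in a monodomain sheet); `repol_rate`
#' multiplies the recovery rate of the two-variable reaction term, so
#' smaller values give longer action potentials; `excitability` is the
#' dimensionless excitation threshold of the cubic reaction term (smaller
#' is more excitable).
#'
#' @param grid_rows,grid_cols Grid size in pixels (>= 16).
#' @param pixel_pitch Pixel pitch, mm/pixel.
#' @param diffusivity Isotropic diffusivity, mm^2/ms.
#' @param excitability Dimensionless excitation threshold.
#' @param repol_rate Dimensionless recovery-rate multiplier (> 0).
#' @param phenotype_label `"control"` or `"hf"`.
#' @return A `tissue_params` object.
#' @seealso [phenotype_presets()]
#' @export
tissue_params <- function(grid_rows = 128L, grid_cols = 128L,
                          pixel_pitch = 30 / 128,
                          diffusivity = 0.5,
                          excitability = 0.08,
                          repol_rate = 1,
                          phenotype_label = c("control", "hf")) {
  phenotype_label <- match.arg(phenotype_label)
  if (grid_rows < 16 || grid_cols < 16) stop("grid dims must be >= 16")
  if (!is.finite(pixel_pitch) || pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (!is.finite(diffusivity) || diffusivity <= 0) stop("diffusivity must be > 0")
  if (!is.finite(repol_rate) || repol_rate <= 0) stop("repol_rate must be > 0")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pixel_pitch = pixel_pitch,
                 diffusivity = diffusivity,
                 excitability = excitability,
                 repol_rate = repol_rate,
                 phenotype_label = phenotype_label),
            class = "tissue_params")
}

#' Phenotype parameter presets
#'
#' Two presets are shipped as an editable configuration rather than being
#' baked into the simulator: `control` (healthy myocardium: fast
#' conduction, short action potentials) and `hf` (failing myocardium:
#' diffusivity scaled by 0.4 and recovery rate by 0.6 relative to control,
#' giving slower conduction and longer action potentials). The control
#' constants were calibrated once so that the measured plane-wave CV and
#' APD80 at a 400-ms cycle length fall in the physiological ranges reported
#' for healthy rabbit ventricle (CV roughly 80-110 cm/s, APD80 70-80 ms).
#'
#' @return Named list of parameter lists, one per phenotype.
#' @export
phenotype_presets <- function() {
  control <- list(diffusivity = 0.5, excitability = 0.08, repol_rate = 1)
  hf <- control
  hf$diffusivity <- control$diffusivity * 0.4
  hf$repol_rate <- control$repol_rate * 0.6
  list(control = control, hf = hf)
}

#' Tissue parameters for a named phenotype
#'
#' @param phenotype `"control"` or `"hf"`.
#' @param ... Overrides passed on to [tissue_params()] (e.g. `grid_rows`).
#' @return A `tissue_params` object.
#' @export
phenotype_params <- function(phenotype = c("control", "hf"), ...) {
  phenotype <- match.arg(phenotype)
  p <- phenotype_presets()[[phenotype]]
  args <- list(...)
  for (nm in names(p)) if (is.null(args[[nm]])) args[[nm]] <- p[[nm]]
  args$phenotype_label <- phenotype
  do.call(tissue_params, args)
}

# fixed reaction-term constants (Aliev-Panfilov class); t_scale maps the
# dimensionless model clock to ms and was calibrated together with the
# control preset
.ap_constants <- list(k = 8, eps0 = 0.002, mu1 = 0.2, mu2 = 0.3,
                      t_scale = 2.0, stim_strength = 4)

# 0-based column-major indices of the line-electrode cells
.stim_indices <- function(nr, nc, site, width = 3L) {
  w <- min(width, nr, nc)
  idx <- switch(site,
    left   = outer(seq_len(nr) - 1L, seq_len(w) - 1L, function(r, c) r + nr * c),
    right  = outer(seq_len(nr) - 1L, nc - seq_len(w), function(r, c) r + nr * c),
    top    = outer(seq_len(w) - 1L, seq_len(nc) - 1L, function(r, c) r + nr * c),
    bottom = outer(nr - seq_len(w), seq_len(nc) - 1L, function(r, c) r + nr * c))
  as.integer(idx)
}

# smooth multiplicative heterogeneity field for the excitation threshold:
# white noise blurred with a wide separable Gaussian, scaled to sd `amount`
.heterogeneity_field <- function(nr, nc, amount, seed) {
  if (amount <= 0) return(matrix(1, nr, nc))
  z <- .with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  k <- .gauss_smoother(nr, 8) ; z <- k %*% z
  k <- .gauss_smoother(nc, 8) ; z <- z %*% t(k)
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  1 + amount * z
}

# row-normalized banded Gaussian smoothing matrix (replicate-style edges)
.gauss_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > half] <- 0
  k / rowSums(k)
}

#' Simulate a paced excitable sheet and record a voltage movie
#'
#' Integrates a two-variable phenomenological excitable-medium model
#' (cubic excitation + slow recovery, isotropic diffusion, no-flux
#' boundaries) with an explicit time step well below the frame interval,
#' paces it with a line electrode following `protocol`, and resamples the
#' transmembrane variable to movie frames. Ground-truth activation and
#' APD80 fields are measured from the noise-free transmembrane signal with
#' the same definitions the analysis side uses (maximum upstroke
#' derivative; first 80% recovery), so simulator and pipeline can be
#' compared like for like.
#'
#' The run is deterministic given `(params, protocol, seed)`; the seed
#' drives only the smooth spatial heterogeneity of the excitation
#' threshold (set `heterogeneity = 0` for perfectly uniform tissue).
#'
#' @param params A [tissue_params()].
#' @param protocol A [pacing_protocol()].
#' @param duration Recording duration (ms). Default: long enough for every
#'   train plus one trailing cycle length.
#' @param seed Integer seed for the heterogeneity field.
#' @param frame_interval Frame interval (ms).
#' @param polarity Polarity of the recorded movie; the dye-like default
#'   inverts the transmembrane signal.
#' @param heterogeneity Relative sd of the smooth excitability
#'   heterogeneity field.
#' @param lead_in Delay before the first stimulus (ms).
#' @param stimulus_strength Stimulus source amplitude (1/ms) at the
#'   electrode cells; `NULL` uses the calibrated supra-threshold default.
#'   Sub-threshold values fail to capture, which is flagged in the ground
#'   truth rather than raising an error.
#' @return A list with elements `movie` (a [voltage_movie()]) and
#'   `ground_truth` (see [ground_truth_fields()]; includes per-stimulus
#'   capture flags).
#' @export
simulate_tissue <- function(params, protocol, duration = NULL, seed = 1L,
                            frame_interval = 2, polarity = "fluorescence_down",
                            heterogeneity = 0.02, lead_in = 20,
                            stimulus_strength = NULL) {
  stopifnot(inherits(params, "tissue_params"), inherits(protocol, "pacing_protocol"))
  sched <- stimulus_schedule(protocol, lead_in = lead_in)
  need <- max(sched$time) + max(sched$cl)
  if (is.null(duration)) duration <- need
  if (duration < need)
    stop(sprintf("duration %.0f ms does not cover the protocol (needs >= %.0f ms)",
                 duration, need))
  nr <- params$grid_rows; nc <- params$grid_cols
  h <- params$pixel_pitch
  cst <- .ap_constants

  # explicit-Euler stability: dt comfortably below h^2 / (4 D), and below
  # 0.1 ms so the upstroke is resolved well under the frame interval
  dt_max <- min(0.05, 0.2 * h^2 / params$diffusivity)
  steps_per_frame <- ceiling(frame_interval / dt_max)
  dt <- frame_interval / steps_per_frame
  n_frames <- as.integer(ceiling(duration / frame_interval))

  a_field <- params$excitability *
    .heterogeneity_field(nr, nc, heterogeneity, seed)
  stim_idx <- .stim_indices(nr, nc, protocol$stimulus_site)

  res <- ap_integrate(a_field,
                      D = params$diffusivity, k = cst$k, eps0 = cst$eps0,
                      mu1 = cst$mu1, mu2 = cst$mu2, t_scale = cst$t_scale,
                      repol_rate = params$repol_rate,
                      h = h, dt = dt,
                      n_frames = n_frames, steps_per_frame = steps_per_frame,
                      stim_times = sched$time,
                      stim_dur = protocol$stimulus_duration,
                      stim_strength = if (is.null(stimulus_strength)) cst$stim_strength
                                      else stimulus_strength,
                      stim_idx = stim_idx,
                      u0 = matrix(0, nr, nc), v0 = matrix(0, nr, nc))

  u <- aperm(res$frames, c(3, 1, 2))          # -> time x row x col
  clean <- voltage_movie(u, frame_interval = frame_interval,
                         pixel_pitch = h, polarity = "voltage_up",
                         protocol = protocol,
                         stimulus_times = sched$time, stimulus_cls = sched$cl)
  gt <- ground_truth_fields(clean)

  frames <- if (polarity == "fluorescence_down") 1 - u else u
  movie <- voltage_movie(frames, frame_interval = frame_interval,
                         pixel_pitch = h, polarity = polarity,
                         protocol = protocol,
                         stimulus_times = sched$time, stimulus_cls = sched$cl)
  list(movie = movie, ground_truth = gt)
}

#' Ground-truth activation/APD fields from a clean movie
#'
#' Measures per-beat, per-pixel activation time and APD80 from a noise-free
#' upstroke-positive movie using the same detectors as the analysis
#' pipeline, and flags whether each stimulus captured (i.e. the wave
#' propagated to the half of the sheet far from the electrode). A
#' ground-truth plane CV per beat is estimated by regressing activation
#' time on distance along the propagation axis over the central rows.
#'
#' @param clean A `voltage_movie` with `polarity = "voltage_up"` and no
#'   added noise.
#' @return A `ground_truth` object: per-beat activation and APD80 fields
#'   (ms), capture flags, and per-beat `cv` estimates (cm/s).
#' @export
ground_truth_fields <- function(clean) {
  stopifnot(inherits(clean, "voltage_movie"), clean$polarity == "voltage_up")
  norm <- tryCatch(normalize_movie(clean), error = function(e) NULL)
  if (is.null(norm)) {
    # nothing ever activated: every stimulus failed to capture
    wins <- segment_beats(clean)
    d <- dim(clean$frames)
    beats <- lapply(seq_len(nrow(wins)), function(i)
      list(cl = wins$cl[i], stimulus_time = wins$stimulus_time[i],
           beat_index = wins$beat_index[i], transient = wins$transient[i],
           activation = matrix(NA_real_, d[2], d[3]),
           apd80 = matrix(NA_real_, d[2], d[3]),
           captured = FALSE, cv = NA_real_))
    return(structure(list(beats = beats, windows = wins),
                     class = "ground_truth"))
  }
  wins <- segment_beats(norm)
  d <- dim(norm$frames)
  m <- .as_pixel_matrix(norm$frames)
  tt <- frame_times(norm)
  beats <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    act <- .act_core(m, tt, w$start, w$end, w$stimulus_time,
                     norm$frame_interval)
    apd <- .apd_core(m, tt, act$t_act, w$start, w$end, w$stimulus_time,
                     norm$frame_interval)
    act_f <- matrix(act$t_act - w$stimulus_time, d[2], d[3])
    apd_f <- matrix(apd$apd, d[2], d[3])
    # captured if the far half of the sheet activated
    far <- .far_half(d[2], d[3], clean$protocol$stimulus_site)
    captured <- mean(is.finite(act_f[far])) > 0.5
    cv <- .plane_cv_from_field(act_f, clean$pixel_pitch,
                               clean$protocol$stimulus_site)
    beats[[i]] <- list(cl = w$cl, stimulus_time = w$stimulus_time,
                       beat_index = w$beat_index, transient = w$transient,
                       activation = act_f, apd80 = apd_f,
                       captured = captured, cv = cv)
  }
  structure(list(beats = beats, windows = wins), class = "ground_truth")
}

.far_half <- function(nr, nc, site) {
  switch(site,
    left   = cbind(rep(seq_len(nr), nc %/% 2),
                   rep(seq(nc - nc %/% 2 + 1, nc), each = nr)),
    right  = cbind(rep(seq_len(nr), nc %/% 2), rep(seq_len(nc %/% 2), each = nr)),
    top    = cbind(rep(seq(nr - nr %/% 2 + 1, nr), nc), rep(seq_len(nc), each = nr %/% 2))[
               seq_len((nr %/% 2) * nc), , drop = FALSE],
    bottom = cbind(rep(seq_len(nr %/% 2), nc), rep(seq_len(nc), each = nr %/% 2))[
               seq_len((nr %/% 2) * nc), , drop = FALSE])
}

# plane CV (cm/s) from an activation field: slope of distance vs time along
# the propagation axis, central band only (avoids boundary effects)
.plane_cv_from_field <- function(act, pitch, site) {
  nr <- nrow(act); nc <- ncol(act)
  horiz <- site %in% c("left", "right")
  n_axis <- if (horiz) nc else nr
  band <- if (horiz) seq(max(1, nr %/% 4), min(nr, nr - nr %/% 4)) else
                     seq(max(1, nc %/% 4), min(nc, nc - nc %/% 4))
  axis_keep <- seq(max(1, round(0.15 * n_axis)), round(0.85 * n_axis))
  prof <- if (horiz) colMeans(act[band, , drop = FALSE], na.rm = TRUE)
          else rowMeans(act[, band, drop = FALSE], na.rm = TRUE)
  prof <- prof[axis_keep]
  x <- (axis_keep - 1) * pitch
  ok <- is.finite(prof)
  if (sum(ok) < 5) return(NA_real_)
  b <- coef(lm(prof[ok] ~ x[ok]))[2]
  if (!is.finite(b) || abs(b) < 1e-9) return(NA_real_)
  abs(1 / b) * 100          # mm/ms -> cm/s
}

#' Analytic plane-wave movie with closed-form ground truth
#'
#' Generates a movie of a stereotyped plane wave sweeping the sheet from
#' the stimulus edge at constant velocity: a pixel at distance x from the
#' electrode activates exactly `x / cv` after each stimulus, with a 2-ms
#' raised-cosine upstroke (maximum slope exactly at the activation time)
#' followed by a monotone linear repolarization that crosses 80% recovery
#' exactly `apd80` ms after activation. Because every timing is closed
#' form, this generator is the analytic oracle against which the
#' measurement chain is validated.
#'
#' @param cv Conduction velocity, cm/s (> 0).
#' @param apd80 Action potential duration at 80% repolarization, ms; must
#'   be shorter than the shortest cycle length (otherwise beats would
#'   fuse and the generator refuses).
#' @param params A [tissue_params()] (grid geometry; reaction constants
#'   are ignored).
#' @param protocol A [pacing_protocol()].
#' @param frame_interval Frame interval, ms.
#' @param polarity Output polarity (dye-like by default).
#' @param lead_in Delay before the first stimulus, ms.
#' @return A list with `movie` and `ground_truth` (per-beat closed-form
#'   activation/APD fields plus `plane_cv = cv`).
#' @export
plane_wave_movie <- function(cv, apd80, params = tissue_params(),
                             protocol = pacing_protocol(cycle_lengths = 400),
                             frame_interval = 2,
                             polarity = "fluorescence_down", lead_in = 20) {
  stopifnot(inherits(params, "tissue_params"), inherits(protocol, "pacing_protocol"))
  if (!is.finite(cv) || cv <= 0) stop("cv must be > 0")
  if (apd80 >= min(protocol$cycle_lengths))
    stop("apd80 must be shorter than the shortest cycle length (beats would fuse)")
  if (apd80 <= 2) stop("apd80 must exceed the 2-ms upstroke")

  sched <- stimulus_schedule(protocol, lead_in = lead_in)
  duration <- max(sched$time) + max(sched$cl)
  n_frames <- as.integer(ceiling(duration / frame_interval))
  tt <- (seq_len(n_frames) - 1) * frame_interval
  nr <- params$grid_rows; nc <- params$grid_cols
  v <- cv / 100                                 # cm/s -> mm/ms

  horiz <- protocol$stimulus_site %in% c("left", "right")
  n_axis <- if (horiz) nc else nr
  x <- (seq_len(n_axis) - 1) * params$pixel_pitch
  if (protocol$stimulus_site %in% c("right", "bottom")) x <- rev(x)

  u_axis <- matrix(0, n_frames, n_axis)
  for (i in seq_len(nrow(sched))) {
    ta <- sched$time[i] + x / v                 # activation time per axis pos
    s <- outer(tt, ta, "-")                     # time since activation
    u_axis <- pmax(u_axis, .ap_waveform(s, apd80))
  }
  frames <- array(0, c(n_frames, nr, nc))
  if (horiz) for (r in seq_len(nr)) frames[, r, ] <- u_axis
  else       for (cc in seq_len(nc)) frames[, , cc] <- u_axis

  beats <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    af <- if (horiz) matrix(x / v, nr, n_axis, byrow = TRUE)
          else       matrix(x / v, n_axis, nc)
    beats[[i]] <- list(cl = sched$cl[i], stimulus_time = sched$time[i],
                       beat_index = sched$beat_index[i],
                       transient = sched$beat_index[i] == 0,
                       activation = af,
                       apd80 = matrix(apd80, nr, nc),
                       captured = TRUE, cv = cv)
  }
  if (polarity == "fluorescence_down") frames <- 1 - frames
  movie <- voltage_movie(frames, frame_interval = frame_interval,
                         pixel_pitch = params$pixel_pitch, polarity = polarity,
                         protocol = protocol,
                         stimulus_times = sched$time, stimulus_cls = sched$cl)
  gt <- structure(list(beats = beats, plane_cv = cv, apd80 = apd80),
                  class = "ground_truth")
  list(movie = movie, ground_truth = gt)
}

# stereotyped action potential as a function of time-since-activation s:
# raised-cosine upstroke on [-1, 1] (max slope at s = 0), linear decay
# reaching the 20% level exactly at s = apd80, continued to 5% and then a
# short linear tail to baseline
.ap_waveform <- function(s, apd80) {
  u <- matrix(0, nrow(s), ncol(s))
  ris <- s >= -1 & s <= 1
  u[ris] <- (1 - cos(pi * (s[ris] + 1) / 2)) / 2
  slope <- 0.8 / (apd80 - 1)                   # hits 0.2 at s = apd80
  s05 <- 1 + 0.95 / slope                      # reaches 0.05 here
  dec <- s > 1 & s <= s05
  u[dec] <- 1 - slope * (s[dec] - 1)
  tail <- s > s05 & s <= s05 + 5
  u[tail] <- 0.05 * (1 - (s[tail] - s05) / 5)
  u
}

#' Add acquisition noise to a movie
#'
#' Emulates dye/camera noise: white noise scaled to each pixel's signal
#' amplitude divided by `snr`, plus an optional slow sinusoidal baseline
#' drift (random period 1-3 s and phase per pixel). Optionally flips the
#' polarity to dye-like. Reproducible by seed; the caller's RNG state is
#' left untouched.
#'
#' @param movie A `voltage_movie`.
#' @param snr Amplitude signal-to-noise ratio (> 0).
#' @param drift_amplitude Baseline drift amplitude as a fraction of the
#'   per-pixel signal amplitude.
#' @param seed Integer seed.
#' @param flip_to_fluorescence If `TRUE` and the movie is upstroke-positive,
#'   invert it to dye-like polarity after adding noise.
#' @return A new `voltage_movie`.
#' @export
add_acquisition_noise <- function(movie, snr, drift_amplitude = 0, seed = 1L,
                                  flip_to_fluorescence = FALSE) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (!is.finite(snr) || snr <= 0) stop("snr must be > 0")
  d <- dim(movie$frames)
  m <- .as_pixel_matrix(movie$frames)
  q <- apply(m, 2, quantile, probs = c(0.01, 0.99), names = FALSE)
  amp <- pmax(q[2, ] - q[1, ], 1e-12)
  tt <- (seq_len(d[1]) - 1) * movie$frame_interval
  m <- .with_seed(seed, {
    noise <- matrix(stats::rnorm(length(m)), nrow(m)) *
      rep(amp / snr, each = nrow(m))
    out <- m + noise
    if (drift_amplitude > 0) {
      period <- stats::runif(ncol(m), 1000, 3000)
      phase <- stats::runif(ncol(m), 0, 2 * pi)
      drift <- sin(outer(tt, 2 * pi / period) +
                   rep(phase, each = length(tt))) *
        rep(drift_amplitude * amp, each = length(tt))
      out <- out + drift
    }
    out
  })
  polarity <- movie$polarity
  if (flip_to_fluorescence && polarity == "voltage_up") {
    m <- -m
    polarity <- "fluorescence_down"
  }
  voltage_movie(.from_pixel_matrix(m, d[2], d[3]),
                frame_interval = movie$frame_interval,
                pixel_pitch = movie$pixel_pitch, polarity = polarity,
                protocol = movie$protocol,
                stimulus_times = movie$stimulus_times,
                stimulus_cls = movie$stimulus_cls)
}
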