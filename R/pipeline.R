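#' Measure conduction velocity and APD80 from one recording
#'
#' The full measurement chain for a single paced recording: polarity
#' correction and robust per-pixel normalization, spatiotemporal filtering
#' when the median pixel SNR is below `filter_snr`, beat segmentation,
#' per-pixel activation/APD80 maps averaged over three consecutive
#' non-transient beats, an automatically placed two-point probe along the
#' apparent propagation axis, and the single-vector CV.
#'
#' APD80 is reported only for cycle lengths in `apd_cls` (by default 400,
#' 300, 250 and 200 ms; short cycle lengths are conventionally excluded
#' because beat fusion and alternans make the APD ill-defined there); CV
#' is reported for every analyzable cycle length.
#'
#' @param movie A `voltage_movie`.
#' @param roi Summary ROI (half-open 0-based rectangle); default: centered
#'   third of the field.
#' @param probe_roi ROI used for probe placement; default: central 80% of
#'   the field, so the probe can span enough tissue for a stable velocity.
#' @param apd_cls Cycle lengths (ms) for which APD80 is reported.
#' @param filter_snr Apply the default filter (sigma = 1 px, window = 5
#'   frames) when the median pixel SNR is below this; `Inf` always
#'   filters, `0` never does.
#' @param verbose Log stage progress to stderr.
#' @return Data frame with one row per analyzable cycle length: `cl_ms`,
#'   `cv_cm_s`, `apd80_ms`, `apd80_sd_ms`, `frac_valid`, `low_quality`.
#' @export
measure_recording <- function(movie, roi = NULL, probe_roi = NULL,
                              apd_cls = c(400, 300, 250, 200),
                              filter_snr = 20, verbose = FALSE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  movie <- normalize_movie(movie)
  d <- dim(movie$frames)
  log_("movie loaded: %d frames, %d x %d px", d[1], d[2], d[3])
  med_snr <- median(movie$mask$snr[is.finite(movie$mask$snr)])
  if (med_snr < filter_snr) {
    log_("median SNR %.1f < %.0f: filtering (sigma 1 px, window 5)",
         med_snr, filter_snr)
    movie <- filter_movie(movie, spatial_sigma = 1, temporal_window = 5)
  }
  windows <- segment_beats(movie)
  log_("beats found: %d (%d selected)", nrow(windows), sum(windows$selected))
  if (is.null(roi)) roi <- default_roi(movie)
  if (is.null(probe_roi)) {
    m10 <- round(c(d[2], d[3]) * 0.1)
    probe_roi <- c(m10[1], d[2] - m10[1], m10[2], d[3] - m10[2])
  }
  maps <- build_maps(movie, windows, roi = roi)
  rows <- lapply(maps, function(mc) {
    cv <- tryCatch({
      probe <- auto_probe(mc$activation, roi = probe_roi)
      as.numeric(single_vector_cv(mc$activation, probe))
    }, error = function(e) {
      log_("CL %g: CV not measurable (%s)", mc$cl, conditionMessage(e))
      NA_real_
    })
    s <- mc$summary
    data.frame(cl_ms = mc$cl, cv_cm_s = cv,
               apd80_ms = if (mc$cl %in% apd_cls) s$mean_apd80 else NA_real_,
               apd80_sd_ms = if (mc$cl %in% apd_cls) s$sd_apd80 else NA_real_,
               frac_valid = s$frac_valid, low_quality = s$low_quality)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$cl_ms), ]
}

#' Simulate and measure one synthetic subject
#'
#' Emulates one heart going through the pacing protocol: for each cycle
#' length a separate recording is simulated (as on a real rig, where each
#' pacing run is acquired separately), acquisition noise is added, and
#' [measure_recording()] extracts CV and APD80. Subject-to-subject
#' variability comes from lognormal jitter of diffusivity and recovery
#' rate around the phenotype preset plus a subject-specific spatial
#' heterogeneity field, all driven by `seed`.
#'
#' @param phenotype `"control"` or `"hf"`.
#' @param seed Integer seed for this subject.
#' @param cls Cycle lengths to pace (ms).
#' @param beats_per_cl Stimuli per run (first is a transient).
#' @param grid_rows,grid_cols Simulated grid (smaller grids run faster and
#'   behave identically up to discretization).
#' @param snr Acquisition signal-to-noise ratio.
#' @param drift Baseline drift fraction.
#' @param cv_jitter,apd_jitter Lognormal sd of the diffusivity and
#'   recovery-rate jitter.
#' @param diffusivity_scale,repol_scale Extra multiplicative scalings of
#'   the preset, letting a study design place groups between the two
#'   phenotype presets (e.g. partial remodeling).
#' @param apd_cls Passed to [measure_recording()].
#' @return Data frame: one row per cycle length with measured `cv_cm_s`,
#'   `apd80_ms`, plus ground-truth `gt_cv_cm_s`, `gt_apd80_ms`.
#' @export
simulate_subject <- function(phenotype, seed, cls = c(400, 300, 250, 200),
                             beats_per_cl = 4, grid_rows = 48, grid_cols = 48,
                             snr = 20, drift = 0.05,
                             cv_jitter = 0.1, apd_jitter = 0.05,
                             diffusivity_scale = 1, repol_scale = 1,
                             apd_cls = c(400, 300, 250, 200)) {
  jit <- .with_seed(seed * 7 + 1, stats::rnorm(2))
  base <- phenotype_presets()[[phenotype]]
  params <- phenotype_params(phenotype,
                             grid_rows = grid_rows, grid_cols = grid_cols,
                             diffusivity = base$diffusivity * diffusivity_scale *
                               exp(cv_jitter * jit[1]),
                             repol_rate = base$repol_rate * repol_scale *
                               exp(apd_jitter * jit[2]))
  rows <- lapply(seq_along(cls), function(i) {
    pr <- pacing_protocol(cycle_lengths = cls[i], beats_per_cl = beats_per_cl)
    sim <- simulate_tissue(params, pr, seed = seed)
    noisy <- add_acquisition_noise(sim$movie, snr = snr,
                                   drift_amplitude = drift,
                                   seed = seed * 131 + i)
    meas <- measure_recording(noisy, apd_cls = apd_cls)
    sel <- !vapply(sim$ground_truth$beats, `[[`, TRUE, "transient")
    gt_cv <- mean(vapply(sim$ground_truth$beats[sel], `[[`, 0, "cv"),
                  na.rm = TRUE)
    roi <- default_roi(sim$movie)
    gt_apd <- mean(vapply(sim$ground_truth$beats[sel], function(b)
      mean(b$apd80[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]], na.rm = TRUE), 0),
      na.rm = TRUE)
    cbind(meas, gt_cv_cm_s = gt_cv,
          gt_apd80_ms = if (cls[i] %in% apd_cls) gt_apd else NA_real_)
  })
  do.call(rbind, rows)
}

#' Simulate and measure a multi-subject cohort
#'
#' `groups` is either a named integer vector (label -> n, labels being
#' phenotype names) or a data frame with columns `label`, `phenotype`,
#' `n` and optionally `diffusivity_scale` / `repol_scale`, which lets a
#' study design include groups lying between the two phenotype presets
#' (partial remodeling).
#'
#' @param groups Group specification (see above).
#' @param seed Base seed; subject s of group g gets a distinct derived seed.
#' @param ... Passed to [simulate_subject()].
#' @return Data frame with `subject_id`, `group` and the per-CL
#'   measurements of every subject.
#' @export
simulate_cohort <- function(groups = c(control = 5, hf = 4), seed = 1, ...) {
  if (!is.data.frame(groups))
    groups <- data.frame(label = names(groups), phenotype = names(groups),
                         n = as.integer(groups))
  if (is.null(groups$diffusivity_scale)) groups$diffusivity_scale <- 1
  if (is.null(groups$repol_scale)) groups$repol_scale <- 1
  out <- list()
  sid <- 0L
  for (g in seq_len(nrow(groups))) for (s in seq_len(groups$n[g])) {
    sid <- sid + 1L
    sub <- simulate_subject(groups$phenotype[g], seed = seed * 1000L + sid,
                            diffusivity_scale = groups$diffusivity_scale[g],
                            repol_scale = groups$repol_scale[g], ...)
    out[[sid]] <- cbind(subject_id = sprintf("s%02d", sid),
                        group = groups$label[g], sub)
  }
  do.call(rbind, out)
}
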