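# Vectorized measurement cores. Both operate on a (time x pixel) matrix of
# normalized upstroke-positive traces and return per-pixel results; the
# public single-trace functions and build_maps() share this single code
# path.

# activation time = time of maximum first derivative (central differences)
# within the beat window, refined below the frame interval by parabolic
# interpolation of the discrete derivative peak (refinement clamped to
# +/- 1 frame). A pixel is invalid when its in-window amplitude is below
# `amp_thresh` of its normalized range or its peak derivative does not
# exceed `deriv_snr` times the baseline derivative noise.
.act_core <- function(m, tt, start, end, stim, dt,
                      amp_thresh = 0.3, deriv_snr = 5) {
  win <- which(tt >= start & tt < end)
  if (length(win) < 5) stop("beat window too short for activation detection")
  V <- m[win, , drop = FALSE]
  tw <- tt[win]
  P <- ncol(V); Tw <- nrow(V)

  base_rows <- which(tw < stim)
  if (length(base_rows) < 2) base_rows <- 1:2
  baseline <- colMeans(V[base_rows, , drop = FALSE])
  ipkv <- max.col(t(V), ties.method = "first")
  vmax <- V[cbind(ipkv, seq_len(P))]
  amp <- vmax - baseline

  D <- (V[-(1:2), , drop = FALSE] - V[seq_len(Tw - 2), , drop = FALSE]) / (2 * dt)
  nd <- nrow(D)
  imax <- max.col(t(D), ties.method = "first")
  dmax <- D[cbind(imax, seq_len(P))]

  dbase_rows <- which(tw[1 + seq_len(nd)] < stim)
  dnoise <- if (length(dbase_rows) >= 3)
    apply(D[dbase_rows, , drop = FALSE], 2, sd) else rep(0, P)
  dnoise <- pmax(dnoise, 1e-9)

  ic <- pmin(pmax(imax, 2L), nd - 1L)
  y0 <- D[cbind(ic, seq_len(P))]
  ym <- D[cbind(ic - 1L, seq_len(P))]
  yp <- D[cbind(ic + 1L, seq_len(P))]
  den <- ym - 2 * y0 + yp
  off <- ifelse(abs(den) > 1e-12, 0.5 * (ym - yp) / den, 0)
  off <- pmin(pmax(off, -1), 1)
  off[ic != imax] <- 0                  # argmax at the window edge: no refinement
  t_act <- tw[imax + 1L] + off * dt

  valid <- amp >= amp_thresh & dmax > 0 & dmax >= deriv_snr * dnoise &
    t_act > start & t_act < end
  t_act[!valid] <- NA_real_
  list(t_act = t_act, amplitude = amp, baseline = baseline,
       max_deriv = dmax, deriv_noise = dnoise)
}

# APD80: amplitude is the in-window peak (at or after activation) minus the
# pre-stimulus baseline; t80 is the first post-peak time the trace falls
# below baseline + 0.2 * amplitude, linearly interpolated between the two
# bracketing samples. Missing when the trace never recovers to that level
# inside the window (fused beat) or when t_act is missing.
.apd_core <- function(m, tt, t_act, start, end, stim, dt) {
  win <- which(tt >= start & tt < end)
  V <- m[win, , drop = FALSE]
  tw <- tt[win]
  P <- ncol(V); Tw <- nrow(V)

  base_rows <- which(tw < stim)
  if (length(base_rows) < 2) base_rows <- 1:2
  baseline <- colMeans(V[base_rows, , drop = FALSE])

  ta <- ifelse(is.na(t_act), Inf, t_act)
  after <- outer(tw, ta, ">=")
  Vm <- V; Vm[!after] <- -Inf
  ipk <- max.col(t(Vm), ties.method = "first")
  peak <- V[cbind(ipk, seq_len(P))]
  level <- baseline + 0.2 * (peak - baseline)

  below <- sweep(V, 2, level, "<") & (row(V) > rep(ipk, each = Tw))
  hit <- colSums(below) > 0
  i1 <- max.col(t(below), ties.method = "first")
  i1[!hit] <- 2L                        # placeholder, masked below
  i0 <- pmax(i1 - 1L, 1L)
  v0 <- V[cbind(i0, seq_len(P))]
  v1 <- V[cbind(i1, seq_len(P))]
  den <- v0 - v1
  t80 <- tw[i0] + dt * ifelse(abs(den) > 1e-12, (v0 - level) / den, 0)

  apd <- t80 - t_act
  bad <- is.na(t_act) | !hit | !is.finite(peak) | apd <= 0
  apd[bad] <- NA_real_
  t80[bad] <- NA_real_
  list(apd = apd, t80 = t80, peak = peak, level = level)
}

.window_fields <- function(window) {
  if (is.data.frame(window)) window <- as.list(window[1, ])
  if (is.null(window$stimulus_time))
    window$stimulus_time <- window$start + 10
  window
}

#' Activation time of a single-pixel trace
#'
#' The activation time is the time of the steepest upstroke (maximum first
#' derivative of phase 0) within the beat window, refined below the frame
#' interval by parabolic interpolation of the derivative peak. Returns
#' `NA` (not an error) when the trace carries no detectable upstroke.
#'
#' @param trace Normalized, upstroke-positive time series for one pixel
#'   (samples spanning the whole recording).
#' @param window A beat window: a list or one-row data frame with `start`,
#'   `end` and `stimulus_time` (ms).
#' @param frame_interval Sampling interval (ms).
#' @return Activation time in ms from the start of the recording, or `NA`.
#' @export
activation_time <- function(trace, window, frame_interval = 2) {
  w <- .window_fields(window)
  tt <- (seq_along(trace) - 1) * frame_interval
  res <- .act_core(matrix(trace, ncol = 1), tt, w$start, w$end,
                   w$stimulus_time, frame_interval)
  res$t_act[1]
}

#' APD80 of a single-pixel trace
#'
#' Action potential duration from the activation time to 80%
#' repolarization: the first post-peak time the trace falls to baseline +
#' 20% of the beat amplitude, linearly interpolated between samples.
#' Returns `NA` when the trace never recovers to that level within the
#' window (fused beat).
#'
#' @inheritParams activation_time
#' @param t_act Activation time (ms) as returned by [activation_time()].
#' @return APD80 in ms, or `NA`.
#' @export
apd80 <- function(trace, t_act, window, frame_interval = 2) {
  if (is.na(t_act)) return(NA_real_)
  w <- .window_fields(window)
  tt <- (seq_along(trace) - 1) * frame_interval
  res <- .apd_core(matrix(trace, ncol = 1), tt, t_act, w$start, w$end,
                   w$stimulus_time, frame_interval)
  res$apd[1]
}

#' Average a measurement over consecutive beats
#'
#' Arithmetic mean over the valid values of up to `n_beats` beats (three
#' by default, the usual convention of averaging three consecutive heart
#' beats). Missing beats are tolerated; the number of contributing beats
#' is attached as attribute `n`.
#'
#' @param values Per-beat measurements (may contain `NA`).
#' @param n_beats Maximum number of beats to average.
#' @return The mean (or `NA` if no beat is valid), with attribute `n`.
#' @export
beat_average <- function(values, n_beats = 3) {
  v <- head(values[!is.na(values)], n_beats)
  if (length(v) == 0) return(structure(NA_real_, n = 0L))
  structure(mean(v), n = length(v))
}

#' Diastolic interval
#'
#' DI = cycle length minus APD80: the recovery time between the end of one
#' action potential and the next stimulus. Defined only for
#' `0 < apd80 < cl`; an APD reaching the cycle length means the beats have
#' fused and no restitution pair exists.
#'
#' @param cl Cycle length(s), ms.
#' @param apd80 APD80 value(s), ms.
#' @return `cl - apd80`, ms.
#' @export
diastolic_interval <- function(cl, apd80) {
  if (any(!is.finite(cl) | !is.finite(apd80)))
    stop("cl and apd80 must be finite")
  if (any(apd80 <= 0)) stop("apd80 must be positive")
  if (any(apd80 >= cl)) stop("apd80 must be shorter than the cycle length")
  cl - apd80
}

#' Per-pixel activation and APD80 maps for each cycle length
#'
#' Applies the activation and APD80 detectors pixel-wise over the selected
#' beats of each analyzable cycle length, averages over beats (up to three,
#' per [beat_average()]), and attaches validity masks and ROI summary
#' statistics. Activation values are reported in ms relative to the window
#' start; beat counts per pixel are kept. A cycle length whose ROI is more
#' than half invalid is flagged `low_quality`.
#'
#' @param movie A `voltage_movie`; normalized automatically if needed.
#' @param windows Beat windows from [segment_beats()]; computed if `NULL`.
#' @param roi Half-open 0-based rectangle `c(r0, r1, c0, c1)` over which
#'   summary statistics are computed; `NULL` = whole frame.
#' @param n_beats Beats to average per cycle length.
#' @return A `map_set`: a list with one element per cycle length, each
#'   holding `activation` and `apd` map objects plus a `summary` list, and
#'   attribute `summary` (a data frame across cycle lengths).
#' @export
build_maps <- function(movie, windows = NULL, roi = NULL, n_beats = 3) {
  movie <- normalize_movie(movie)
  if (is.null(windows)) windows <- segment_beats(movie)
  d <- dim(movie$frames)
  nr <- d[2]; nc <- d[3]
  roi <- if (is.null(roi)) c(0L, nr, 0L, nc) else .check_roi(roi, nr, nc)
  m <- .as_pixel_matrix(movie$frames)
  tt <- frame_times(movie)
  analyzable_px <- as.vector(movie$mask$analyzable)

  out <- list()
  sum_rows <- list()
  for (cl in unique(windows$cl[windows$analyzable])) {
    sel <- windows[windows$cl == cl & windows$selected, , drop = FALSE]
    if (nrow(sel) == 0) next
    acts <- apds <- matrix(NA_real_, nr * nc, nrow(sel))
    for (b in seq_len(nrow(sel))) {
      w <- sel[b, ]
      a <- .act_core(m, tt, w$start, w$end, w$stimulus_time, movie$frame_interval)
      p <- .apd_core(m, tt, a$t_act, w$start, w$end, w$stimulus_time,
                     movie$frame_interval)
      acts[, b] <- a$t_act - w$start
      apds[, b] <- p$apd
    }
    acts[!analyzable_px, ] <- NA_real_
    apds[!analyzable_px, ] <- NA_real_
    act_n <- rowSums(!is.na(acts))
    apd_n <- rowSums(!is.na(apds))
    act_mean <- ifelse(act_n > 0, rowMeans(acts, na.rm = TRUE), NA_real_)
    apd_mean <- ifelse(apd_n > 0, rowMeans(apds, na.rm = TRUE), NA_real_)

    act_map <- structure(list(values = matrix(act_mean, nr, nc),
                              valid = matrix(act_n > 0, nr, nc),
                              n_beats = matrix(act_n, nr, nc),
                              cl = cl, pixel_pitch = movie$pixel_pitch,
                              beats = sel$beat_index, kind = "activation"),
                         class = "activation_map")
    apd_map <- structure(list(values = matrix(apd_mean, nr, nc),
                              valid = matrix(apd_n > 0, nr, nc),
                              n_beats = matrix(apd_n, nr, nc),
                              cl = cl, pixel_pitch = movie$pixel_pitch,
                              beats = sel$beat_index, kind = "apd80"),
                         class = "apd_map")

    ri <- (roi[1] + 1):roi[2]; ci <- (roi[3] + 1):roi[4]
    apd_roi <- apd_map$values[ri, ci]
    act_roi <- act_map$values[ri, ci]
    frac_valid <- mean(is.finite(apd_roi))
    summ <- list(cl = cl,
                 mean_apd80 = mean(apd_roi, na.rm = TRUE),
                 sd_apd80 = sd(as.vector(apd_roi), na.rm = TRUE),
                 mean_activation = mean(act_roi, na.rm = TRUE),
                 frac_valid = frac_valid,
                 low_quality = frac_valid < 0.5,
                 n_beats = nrow(sel))
    out[[as.character(cl)]] <- list(cl = cl, activation = act_map,
                                    apd = apd_map, summary = summ)
    sum_rows[[as.character(cl)]] <- as.data.frame(summ)
  }
  if (length(out) == 0) stop("no analyzable cycle length in this recording")
  structure(out, class = "map_set", roi = roi,
            summary = do.call(rbind, sum_rows))
}

#' @export
print.map_set <- function(x, ...) {
  cat("<map_set>\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
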