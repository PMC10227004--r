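#' Normalize a voltage movie
#'
#' Conditions a raw movie for measurement: corrects polarity so
#' depolarization is positive-going, then rescales each pixel linearly to
#' \[0, 1\] using robust extrema (1st/99th percentiles over the whole
#' recording). Pixels with no dynamic range are flagged in the pixel mask
#' and left untouched. The operation is idempotent: normalizing an already
#' normalized movie returns it unchanged (to within 1e-6).
#'
#' A pixel-quality mask is attached: per-pixel robust amplitude, a noise
#' estimate from first differences, their ratio (SNR), and an
#' `analyzable` flag (`SNR >= snr_min` and not flat).
#'
#' @param movie A `voltage_movie`.
#' @param snr_min Pixels with amplitude/noise below this are masked out of
#'   downstream map statistics.
#' @return A normalized `voltage_movie` with polarity `"voltage_up"`, a
#'   `$mask` list and `$normalized = TRUE`.
#' @export
normalize_movie <- function(movie, snr_min = 3) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (isTRUE(movie$normalized)) return(movie)
  d <- dim(movie$frames)
  m <- .as_pixel_matrix(movie$frames)
  if (movie$polarity == "fluorescence_down") m <- -m

  q <- apply(m, 2, quantile, probs = c(0.01, 0.99), names = FALSE)
  amp <- q[2, ] - q[1, ]
  flat <- amp < pmax(1e-12, 1e-3 * max(amp))
  if (all(flat)) stop("no dynamic signal: every pixel is flat")

  scl <- ifelse(flat, 1, amp)
  off <- ifelse(flat, 0, q[1, ])
  m <- (m - rep(off, each = d[1])) / rep(scl, each = d[1])

  dd <- m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE]
  noise <- apply(dd, 2, mad) / sqrt(2)
  amp_n <- apply(m, 2, quantile, probs = 0.99, names = FALSE) -
           apply(m, 2, quantile, probs = 0.01, names = FALSE)
  snr <- ifelse(noise > 0, amp_n / noise, Inf)
  analyzable <- !flat & snr >= snr_min

  out <- voltage_movie(.from_pixel_matrix(m, d[2], d[3]),
                       frame_interval = movie$frame_interval,
                       pixel_pitch = movie$pixel_pitch,
                       polarity = "voltage_up",
                       protocol = movie$protocol,
                       stimulus_times = movie$stimulus_times,
                       stimulus_cls = movie$stimulus_cls)
  out$mask <- list(analyzable = matrix(analyzable, d[2], d[3]),
                   flat = matrix(flat, d[2], d[3]),
                   amplitude = matrix(amp_n, d[2], d[3]),
                   noise = matrix(noise, d[2], d[3]),
                   snr = matrix(snr, d[2], d[3]))
  out$normalized <- TRUE
  out
}

#' Spatiotemporal filtering
#'
#' Gaussian spatial smoothing of each frame (separable, replicate edges)
#' followed by Savitzky-Golay temporal smoothing of each pixel trace
#' (polynomial order `min(3, temporal_window - 1)`). The identity settings
#' `spatial_sigma = 0, temporal_window = 1` return the input bit-for-bit.
#'
#' @param movie A `voltage_movie`.
#' @param spatial_sigma Gaussian sigma in pixels (>= 0).
#' @param temporal_window Odd Savitzky-Golay window length in frames (>= 1).
#' @return A filtered `voltage_movie` (mask and flags carried over).
#' @export
filter_movie <- function(movie, spatial_sigma = 1, temporal_window = 5) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (spatial_sigma < 0) stop("spatial_sigma must be >= 0")
  if (temporal_window < 1 || temporal_window %% 2 == 0)
    stop("temporal_window must be odd and >= 1")
  d <- dim(movie$frames)
  if (temporal_window > d[1]) stop("temporal_window longer than the recording")
  if (spatial_sigma == 0 && temporal_window == 1) return(movie)

  frames <- movie$frames
  if (spatial_sigma > 0) {
    kr <- .gauss_smoother(d[2], spatial_sigma)
    kc <- t(.gauss_smoother(d[3], spatial_sigma))
    for (f in seq_len(d[1])) frames[f, , ] <- kr %*% frames[f, , ] %*% kc
  }
  if (temporal_window > 1) {
    m <- .as_pixel_matrix(frames)
    Fm <- signal::sgolay(p = min(3, temporal_window - 1), n = temporal_window)
    Fm <- unclass(Fm)
    half <- (temporal_window - 1) %/% 2
    # interior by FIR convolution with the center row, edges by the
    # asymmetric projection rows (standard Savitzky-Golay edge handling)
    sm <- stats::filter(m, rev(Fm[half + 1, ]), sides = 2)
    sm <- matrix(as.numeric(sm), nrow(m), ncol(m))
    sm[seq_len(half), ] <-
      Fm[seq_len(half), , drop = FALSE] %*% m[seq_len(temporal_window), , drop = FALSE]
    sm[(d[1] - half + 1):d[1], ] <-
      Fm[(half + 2):temporal_window, , drop = FALSE] %*%
      m[(d[1] - temporal_window + 1):d[1], , drop = FALSE]
    frames <- .from_pixel_matrix(sm, d[2], d[3])
  }
  out <- movie
  out$frames <- frames
  out
}

#' Segment a recording into per-beat windows
#'
#' One window per stimulus, spanning `[stimulus - margin, stimulus + CL -
#' margin)` so that a diastolic baseline precedes each upstroke. The first
#' beat of each cycle-length train is marked transient; among the
#' remaining complete beats, up to `n_select` consecutive ones are
#' selected for measurement (three, matching the convention of averaging
#' three consecutive heart beats). A cycle length with fewer than two
#' beats in the recording is flagged unanalyzable rather than failing.
#'
#' @param movie A `voltage_movie` with stimulus metadata.
#' @param margin Pre-stimulus margin (ms).
#' @param n_select Number of non-transient beats to select per cycle length.
#' @return A data frame of class `beat_windows` with columns `cl`,
#'   `stimulus_time`, `start`, `end`, `beat_index`, `transient`,
#'   `complete`, `selected`, `analyzable`; unanalyzable cycle lengths are
#'   listed in `attr(, "unanalyzable_cls")`.
#' @export
segment_beats <- function(movie, margin = 10, n_select = 3) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (length(movie$stimulus_times) == 0)
    stop("movie has no stimulus metadata; cannot segment beats")
  dur <- movie_duration(movie)
  w <- data.frame(cl = movie$stimulus_cls,
                  stimulus_time = movie$stimulus_times)
  w$start <- pmax(0, w$stimulus_time - margin)
  w$end <- w$stimulus_time + w$cl - margin
  # beat index within each train (trains are contiguous runs of one CL)
  run <- cumsum(c(TRUE, diff(w$cl) != 0))
  w$beat_index <- stats::ave(seq_len(nrow(w)), run,
                             FUN = function(i) seq_along(i) - 1L)
  w$transient <- w$beat_index == 0L
  w$complete <- w$end <= dur + 1e-9

  w$selected <- FALSE
  w$analyzable <- TRUE
  bad <- numeric()
  for (cl in unique(w$cl)) {
    i <- which(w$cl == cl)
    if (length(i) < 2) {
      w$analyzable[i] <- FALSE
      bad <- c(bad, cl)
      next
    }
    cand <- i[!w$transient[i] & w$complete[i]]
    if (length(cand) == 0) {      # fall back to the transient beat(s)
      cand <- i[w$complete[i]]
      if (length(cand) == 0) {
        w$analyzable[i] <- FALSE
        bad <- c(bad, cl)
        next
      }
    }
    w$selected[head(cand, n_select)] <- TRUE
  }
  structure(w, class = c("beat_windows", "data.frame"),
            unanalyzable_cls = bad)
}
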