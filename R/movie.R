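#' Pacing protocol description
#'
#' A constant-pacing protocol: one or more trains of stimuli, one train per
#' cycle length, delivered as a line stimulus at one edge of the mapped
#' field. Defaults mirror a programmed-stimulation study design: cycle
#' lengths 400, 300, 250, 200 and 150 ms with 3-ms constant-current pulses.
#'
#' @param cycle_lengths Cycle lengths (ms), in the order the trains are
#'   delivered. All must be positive.
#' @param beats_per_cl Number of stimuli per cycle-length train. The first
#'   beat of each train is treated as a transient by the analysis side, so
#'   at least 4 beats are needed to average three consecutive beats.
#' @param stimulus_duration Stimulus pulse width (ms).
#' @param stimulus_site Which edge carries the line electrode: one of
#'   `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @return A `pacing_protocol` object.
#' @export
pacing_protocol <- function(cycle_lengths = c(400, 300, 250, 200, 150),
                            beats_per_cl = 4,
                            stimulus_duration = 3,
                            stimulus_site = "left") {
  if (length(cycle_lengths) < 1 || any(!is.finite(cycle_lengths)) ||
      any(cycle_lengths <= 0))
    stop("cycle_lengths must be positive and finite")
  if (anyDuplicated(cycle_lengths))
    stop("cycle_lengths must be distinct")
  if (beats_per_cl < 1) stop("beats_per_cl must be >= 1")
  if (!is.finite(stimulus_duration) || stimulus_duration <= 0)
    stop("stimulus_duration must be > 0")
  stimulus_site <- match.arg(stimulus_site, c("left", "right", "top", "bottom"))
  structure(list(cycle_lengths = as.numeric(cycle_lengths),
                 beats_per_cl = as.integer(beats_per_cl),
                 stimulus_duration = stimulus_duration,
                 stimulus_site = stimulus_site),
            class = "pacing_protocol")
}

#' Stimulus schedule implied by a pacing protocol
#'
#' Trains are delivered back to back: each train of `beats_per_cl` stimuli
#' at its cycle length, the next train starting one (old) cycle length after
#' the last stimulus of the previous train. The first stimulus is delayed by
#' `lead_in` ms so a diastolic baseline is observable before the first beat.
#'
#' @param protocol A [pacing_protocol()].
#' @param lead_in Delay before the first stimulus (ms).
#' @return A data frame with columns `time` (ms), `cl` (ms) and
#'   `beat_index` (0-based index within the train).
#' @export
stimulus_schedule <- function(protocol, lead_in = 20) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  t0 <- lead_in
  out <- vector("list", length(protocol$cycle_lengths))
  for (i in seq_along(protocol$cycle_lengths)) {
    cl <- protocol$cycle_lengths[i]
    times <- t0 + cl * (seq_len(protocol$beats_per_cl) - 1)
    out[[i]] <- data.frame(time = times, cl = cl,
                           beat_index = seq_len(protocol$beats_per_cl) - 1L)
    t0 <- times[length(times)] + cl
  }
  do.call(rbind, out)
}

#' Construct a voltage movie
#'
#' The common currency of simulation and analysis: a 3-D stack of frames
#' (time x row x col) of normalized optical signal, with acquisition
#' metadata attached. With a voltage-sensitive dye the raw fluorescence
#' *decreases* on depolarization; `polarity` records whether frames are
#' upstroke-positive (`"voltage_up"`) or dye-like (`"fluorescence_down"`).
#'
#' @param frames Numeric array, `time x row x col`.
#' @param frame_interval Frame interval (ms); default 2 ms.
#' @param pixel_pitch Pixel pitch (mm/pixel); default 30/128 mm for a
#'   128 x 128 sensor imaging a 30 x 30 mm field.
#' @param polarity `"voltage_up"` or `"fluorescence_down"`.
#' @param protocol The [pacing_protocol()] used, or `NULL`.
#' @param stimulus_times Stimulus onset times (ms from the first frame),
#'   strictly increasing.
#' @param stimulus_cls Cycle length (ms) of the train each stimulus belongs
#'   to; recycled if scalar.
#' @return A `voltage_movie` object (a list).
#' @export
voltage_movie <- function(frames, frame_interval = 2, pixel_pitch = 30 / 128,
                          polarity = c("voltage_up", "fluorescence_down"),
                          protocol = NULL, stimulus_times = numeric(),
                          stimulus_cls = numeric()) {
  polarity <- match.arg(polarity)
  if (length(dim(frames)) != 3L) stop("frames must be a 3-D array (time x row x col)")
  if (!all(is.finite(frames))) stop("frames must be finite")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (!is.finite(pixel_pitch) || pixel_pitch <= 0)
    stop("pixel_pitch must be > 0")
  if (length(stimulus_times) > 1 && any(diff(stimulus_times) <= 0))
    stop("stimulus_times must be strictly increasing")
  if (length(stimulus_cls) == 1L)
    stimulus_cls <- rep(stimulus_cls, length(stimulus_times))
  if (length(stimulus_cls) != length(stimulus_times))
    stop("stimulus_cls must match stimulus_times in length")
  structure(list(frames = frames,
                 frame_interval = frame_interval,
                 pixel_pitch = pixel_pitch,
                 polarity = polarity,
                 protocol = protocol,
                 stimulus_times = as.numeric(stimulus_times),
                 stimulus_cls = as.numeric(stimulus_cls)),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<voltage_movie> %d frames of %d x %d px, %.3g ms/frame (%.0f ms), %s\n",
              d[1], d[2], d[3], x$frame_interval, movie_duration(x), x$polarity))
  cat(sprintf("  pitch %.4f mm/px; %d stimuli at CLs {%s} ms\n",
              x$pixel_pitch, length(x$stimulus_times),
              paste(unique(x$stimulus_cls), collapse = ", ")))
  invisible(x)
}

#' Movie duration in ms
#'
#' Duration is the span covered by the frames at the stated frame interval,
#' i.e. `n_frames * frame_interval` (a 1000-frame movie sampled every 2 ms
#' covers 2000 ms).
#' @param movie A `voltage_movie`.
#' @return Duration (ms).
#' @export
movie_duration <- function(movie) {
  dim(movie$frames)[1] * movie$frame_interval
}

#' Frame timestamps in ms (time of frame k is (k-1) * frame_interval)
#' @param movie A `voltage_movie`.
#' @return Numeric vector of frame times.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$frames)[1]) - 1) * movie$frame_interval
}

# frames as a (time x pixel) matrix, pixels column-major in (row, col)
.as_pixel_matrix <- function(frames) {
  d <- dim(frames)
  dim(frames) <- c(d[1], d[2] * d[3])
  frames
}

.from_pixel_matrix <- function(m, nr, nc) {
  dim(m) <- c(nrow(m), nr, nc)
  m
}

#' Centered rectangular region of interest
#'
#' Returns a half-open 0-based rectangle `(r0, r1, c0, c1)` centered in the
#' mapped field and covering about `frac` of its linear extent, emulating
#' the practice of placing a measurement rectangle at the center of the
#' ventricular free wall.
#'
#' @param movie A `voltage_movie` (or an object with a `values` matrix).
#' @param frac Linear fraction of the field spanned by the ROI.
#' @return Integer vector `c(r0, r1, c0, c1)`, half-open, 0-based.
#' @export
default_roi <- function(movie, frac = 1 / 3) {
  d <- if (inherits(movie, "voltage_movie")) dim(movie$frames)[2:3]
       else dim(movie$values)
  half <- pmax(2L, as.integer(round(d * frac / 2)))
  ctr <- as.integer(floor(d / 2))
  c(ctr[1] - half[1], ctr[1] + half[1], ctr[2] - half[2], ctr[2] + half[2])
}

.check_roi <- function(roi, nr, nc) {
  if (length(roi) != 4) stop("roi must be c(r0, r1, c0, c1), half-open, 0-based")
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nr || roi[4] > nc ||
      roi[2] <= roi[1] || roi[4] <= roi[3])
    stop("roi outside grid or empty")
  as.integer(roi)
}

# run `expr` with a local RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  expr
}
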