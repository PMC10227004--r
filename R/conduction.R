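#' Two-point velocity probe
#'
#' A pair of pixel coordinates along the apparent propagation axis, from
#' which conduction velocity is computed as distance over activation-time
#' difference.
#'
#' @param p1,p2 Pixel coordinates `c(row, col)`, 0-based; must differ.
#' @param pixel_pitch Pixel pitch, mm/pixel.
#' @param selection_mode `"manual"` or `"auto"`.
#' @return A `vector_probe` object.
#' @export
vector_probe <- function(p1, p2, pixel_pitch = 30 / 128,
                         selection_mode = c("manual", "auto")) {
  selection_mode <- match.arg(selection_mode)
  p1 <- as.integer(round(p1)); p2 <- as.integer(round(p2))
  if (length(p1) != 2 || length(p2) != 2) stop("p1 and p2 must be (row, col)")
  if (all(p1 == p2)) stop("probe points must differ")
  structure(list(p1 = p1, p2 = p2, pixel_pitch = pixel_pitch,
                 selection_mode = selection_mode),
            class = "vector_probe")
}

#' Single-vector conduction velocity
#'
#' The two-point method: Euclidean distance between the probe points
#' divided by the absolute difference of their activation times, in cm/s.
#' Both activation times and the distance are attached for audit. An
#' activation-time difference below `min_dt` (default 0.5 ms, a quarter
#' frame after sub-sample refinement) is refused because quantization
#' noise would dominate the estimate.
#'
#' @param act_map An `activation_map` from [build_maps()].
#' @param probe A [vector_probe()].
#' @param min_dt Minimum |activation-time difference| (ms).
#' @return CV in cm/s, with attributes `t1`, `t2`, `distance_mm`.
#' @export
single_vector_cv <- function(act_map, probe, min_dt = 0.5) {
  stopifnot(inherits(act_map, "activation_map"), inherits(probe, "vector_probe"))
  v <- act_map$values
  idx1 <- cbind(probe$p1[1] + 1L, probe$p1[2] + 1L)
  idx2 <- cbind(probe$p2[1] + 1L, probe$p2[2] + 1L)
  if (any(idx1 < 1) || any(idx2 < 1) ||
      idx1[1] > nrow(v) || idx1[2] > ncol(v) ||
      idx2[1] > nrow(v) || idx2[2] > ncol(v))
    stop("probe point outside the map")
  t1 <- v[idx1]; t2 <- v[idx2]
  if (!is.finite(t1) || !is.finite(t2))
    stop("probe point falls on an invalid pixel")
  dtv <- abs(t2 - t1)
  if (dtv < min_dt)
    stop("points too close in time for a stable velocity")
  dist_mm <- sqrt(sum((probe$p1 - probe$p2)^2)) * probe$pixel_pitch
  structure((dist_mm / dtv) * 100,          # mm/ms -> cm/s
            t1 = t1, t2 = t2, distance_mm = dist_mm, dt_ms = dtv)
}

#' Automatic probe placement along the propagation axis
#'
#' Estimates the mean propagation direction from the smoothed spatial
#' gradient of activation time over the ROI and places the two probe
#' points on that axis through the ROI center, spanning at least `span`
#' of the ROI extent. When the gradient directions are incoherent
#' (circular variance above `max_circ_var`, as for a radial wave or pure
#' noise) the function refuses and advises a manual probe.
#'
#' @param act_map An `activation_map`.
#' @param roi Half-open 0-based rectangle; default: centered third.
#' @param span Fraction of the ROI extent the probe should span.
#' @param smooth_sigma Gaussian sigma (pixels) applied to the activation
#'   field before taking gradients.
#' @param max_circ_var Maximum tolerated circular variance of the
#'   gradient direction.
#' @return A [vector_probe()] with `selection_mode = "auto"` and
#'   attributes `angle` (radians) and `circ_var`.
#' @export
auto_probe <- function(act_map, roi = NULL, span = 0.8, smooth_sigma = 2,
                       max_circ_var = 0.5) {
  stopifnot(inherits(act_map, "activation_map"))
  v <- act_map$values
  nr <- nrow(v); nc <- ncol(v)
  roi <- if (is.null(roi)) default_roi(act_map) else .check_roi(roi, nr, nc)
  ri <- (roi[1] + 1):roi[2]; ci <- (roi[3] + 1):roi[4]
  sub <- v[ri, ci]
  if (mean(is.finite(sub)) < 0.5)
    stop("fewer than half of the ROI pixels carry a valid activation time")

  # NA-tolerant smoothing (normalized convolution), then central gradients
  f <- is.finite(sub)
  z <- ifelse(f, sub, 0)
  kr <- .gauss_smoother(nrow(sub), smooth_sigma)
  kc <- t(.gauss_smoother(ncol(sub), smooth_sigma))
  num <- kr %*% z %*% kc
  den <- kr %*% (f * 1) %*% kc
  sm <- ifelse(den > 0.2, num / den, NA_real_)

  gr <- (rbind(sm[-1, ], NA) - rbind(NA, sm[-nrow(sm), ])) / 2
  gc <- (cbind(sm[, -1], NA) - cbind(NA, sm[, -ncol(sm)])) / 2
  ok <- is.finite(gr) & is.finite(gc)
  mag <- sqrt(gr[ok]^2 + gc[ok]^2)
  use <- mag > 1e-9
  if (sum(use) < 10) stop("activation gradient too weak to orient a probe")
  ur <- (gr[ok] / mag)[use]; uc <- (gc[ok] / mag)[use]
  w <- mag[use]
  mr <- sum(w * ur) / sum(w); mc <- sum(w * uc) / sum(w)
  circ_var <- 1 - sqrt(mr^2 + mc^2)
  if (circ_var > max_circ_var)
    stop(sprintf(paste("incoherent activation gradient (circular variance",
                       "%.2f): select a manual probe"), circ_var))
  ang <- atan2(mr, mc)                       # direction of increasing time
  dir <- c(sin(ang), cos(ang))               # (row, col) unit vector

  ctr <- c(mean(range(ri)), mean(range(ci))) - 1   # 0-based center
  ext <- min((roi[2] - roi[1]) / abs(dir[1] + 1e-12),
             (roi[4] - roi[3]) / abs(dir[2] + 1e-12))
  half <- max(span * ext / 2, 2)
  pick <- function(sgn) {
    # walk inward from the requested endpoint until a valid pixel is found
    for (s in seq(half, 1, by = -1)) {
      p <- round(ctr + sgn * s * dir)
      if (p[1] >= roi[1] && p[1] < roi[2] && p[2] >= roi[3] && p[2] < roi[4] &&
          is.finite(v[p[1] + 1, p[2] + 1])) return(p)
    }
    stop("no valid pixel along the probe axis")
  }
  p1 <- pick(-1); p2 <- pick(1)
  if (all(p1 == p2)) stop("probe endpoints collapsed; ROI too small")
  pr <- vector_probe(p1, p2, act_map$pixel_pitch, "auto")
  attr(pr, "angle") <- ang
  attr(pr, "circ_var") <- circ_var
  pr
}

#' Isochrone contours of an activation map
#'
#' Contour lines of the activation-time field at multiples of `interval`
#' ms. On a plane wave the contours are parallel straight lines spaced
#' `cv * interval` apart; crowded contours indicate slow conduction.
#'
#' @param act_map An `activation_map`.
#' @param interval Contour interval, ms.
#' @return A list of class `isochrone_set`: `levels` (ms), `contours`
#'   (list of `x`/`y` paths in mm), `interval`. Warns when the activation
#'   span admits at most one contour.
#' @export
isochrone_map <- function(act_map, interval = 2) {
  stopifnot(inherits(act_map, "activation_map"))
  v <- act_map$values
  fin <- v[is.finite(v)]
  if (length(unique(fin)) < 2)
    stop("activation map has fewer than two distinct valid times")
  lo <- ceiling(min(fin) / interval) * interval
  hi <- max(fin)
  levels <- if (lo > hi) numeric() else seq(lo, hi, by = interval)
  if (length(levels) <= 1)
    warning("interval larger than the activation span: at most one contour")
  x <- (seq_len(nrow(v)) - 1) * act_map$pixel_pitch
  y <- (seq_len(ncol(v)) - 1) * act_map$pixel_pitch
  cl <- if (length(levels) == 0) list()
        else grDevices::contourLines(x, y, v, levels = levels)
  structure(list(levels = levels,
                 contours = lapply(cl, function(ct)
                   list(level = ct$level, x = ct$x, y = ct$y)),
                 interval = interval, pixel_pitch = act_map$pixel_pitch),
            class = "isochrone_set")
}
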