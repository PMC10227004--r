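.sidecar_keys <- c("frame_interval_ms", "pixel_pitch_mm", "polarity",
                   "stimulus_times_ms", "cycle_lengths_ms")

#' Write a voltage movie as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit TIFF page per frame plus `<path>.json` holding the
#' acquisition metadata (`frame_interval_ms`, `pixel_pitch_mm`,
#' `polarity`, `stimulus_times_ms`, `cycle_lengths_ms`, the per-stimulus
#' cycle lengths, and the value range used for integer quantization so
#' the round trip recovers the original scale).
#'
#' @param movie A `voltage_movie`.
#' @param path Output path; `.tif` is appended if absent.
#' @return Invisibly, the TIFF path.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  d <- dim(movie$frames)
  vmin <- min(movie$frames); vmax <- max(movie$frames)
  scl <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_len(d[1]), function(f)
    (movie$frames[f, , ] - vmin) / scl)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval_ms = movie$frame_interval,
               pixel_pitch_mm = movie$pixel_pitch,
               polarity = movie$polarity,
               stimulus_times_ms = movie$stimulus_times,
               cycle_lengths_ms = unique(movie$stimulus_cls),
               stimulus_cls_ms = movie$stimulus_cls,
               n_frames = d[1],
               value_range = c(vmin, vmax))
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voltage movie written by [write_movie()]
#'
#' Validates that the sidecar is present and complete (missing keys are
#' reported by name) and that the page count matches the metadata, then
#' restores the frames to their original floating-point scale (exact up
#' to 16-bit quantization).
#'
#' @param path TIFF path (or its basename without extension).
#' @return A `voltage_movie`.
#' @export
read_movie <- function(path) {
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  if (!file.exists(path)) stop("movie file not found: ", path)
  side <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(side)) stop("sidecar JSON not found: ", side,
                               " (required keys: ",
                               paste(.sidecar_keys, collapse = ", "), ")")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  missing <- setdiff(.sidecar_keys, names(meta))
  if (length(missing))
    stop("sidecar is missing required key(s): ", paste(missing, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(meta$n_frames) && length(pages) != meta$n_frames)
    stop(sprintf("frame count mismatch: TIFF has %d pages, sidecar says %d",
                 length(pages), meta$n_frames))
  vr <- if (!is.null(meta$value_range)) meta$value_range else c(0, 1)
  d <- dim(pages[[1]])
  frames <- array(0, c(length(pages), d[1], d[2]))
  for (f in seq_along(pages))
    frames[f, , ] <- pages[[f]] * (vr[2] - vr[1]) + vr[1]
  cls <- if (!is.null(meta$stimulus_cls_ms)) meta$stimulus_cls_ms
         else rep(meta$cycle_lengths_ms[1], length(meta$stimulus_times_ms))
  voltage_movie(frames, frame_interval = meta$frame_interval_ms,
                pixel_pitch = meta$pixel_pitch_mm,
                polarity = meta$polarity,
                stimulus_times = meta$stimulus_times_ms,
                stimulus_cls = cls)
}

#' Write ground-truth fields as per-beat CSV files
#'
#' @param gt A `ground_truth` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (i in seq_along(gt$beats)) {
    b <- gt$beats[[i]]
    base <- sprintf("beat%02d_cl%03d", i, b$cl)
    p1 <- file.path(dir, paste0(base, "_activation.csv"))
    p2 <- file.path(dir, paste0(base, "_apd80.csv"))
    write.table(b$activation, p1, sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(b$apd80, p2, sep = ",", row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

#' Serialize a group table in the conventional layout
#'
#' Rows are cycle lengths; per group a `mean ± SD` column (and n), then
#' the omnibus p; a final `p for trend` row. Degenerate inputs degrade
#' gracefully: no rows gives a headers-only CSV, a single group leaves
#' the p column empty.
#'
#' @param gt A `group_table` from [summarize_groups()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_group_table <- function(gt, path) {
  s <- gt$summary
  groups <- gt$groups
  fmt <- function(m, sdv, n) ifelse(is.na(m), "",
    ifelse(is.na(sdv), sprintf("%.3f (n=%d)", m, n),
           sprintf("%.3f ± %.3f (n=%d)", m, sdv, n)))
  out <- data.frame(cycle_length_ms = if (is.null(s)) numeric() else s$cl_ms)
  for (g in groups)
    out[[g]] <- if (is.null(s)) character() else
      fmt(s[[paste0(g, "_mean")]], s[[paste0(g, "_sd")]], s[[paste0(g, "_n")]])
  out$p_value <- if (is.null(s)) character() else
    ifelse(is.na(s$p_value) | length(groups) < 2, "",
           sprintf("%.4g", s$p_value))
  tr <- vapply(groups, function(g) {
    p <- gt$trend[[g]]$p
    if (is.finite(p)) sprintf("%.4g", p) else ""
  }, "")
  if (!is.null(s) && nrow(out) > 0 && any(nzchar(tr))) {
    out <- rbind(out, c(cycle_length_ms = NA, as.list(tr), p_value = ""))
    out$cycle_length_ms <- as.character(out$cycle_length_ms)
    out$cycle_length_ms[nrow(out)] <- "p for trend"
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a map as a CSV grid and a PNG rendering
#'
#' @param map An `activation_map` or `apd_map`.
#' @param path_base Path without extension; writes `.csv` and `.png`.
#' @return Invisibly, the paths.
#' @export
write_map <- function(map, path_base) {
  csv <- paste0(path_base, ".csv")
  png <- paste0(path_base, ".png")
  write.table(map$values, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  grDevices::png(png, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  plot_map(map)
  invisible(c(csv, png))
}

#' Render a map with a colorbar
#'
#' @param map An `activation_map` or `apd_map`.
#' @param probe Optional [vector_probe()] to overlay.
#' @param main Title; defaults to the map kind and cycle length.
#' @export
plot_map <- function(map, probe = NULL, main = NULL) {
  v <- map$values
  if (is.null(main))
    main <- sprintf("%s (ms), CL %g ms", map$kind, map$cl)
  pal <- grDevices::hcl.colors(64, "Spectral", rev = TRUE)
  rng <- range(v, na.rm = TRUE)
  graphics::layout(matrix(1:2, 1), widths = c(5, 1))
  op <- graphics::par(mar = c(4, 4, 3, 1))
  on.exit({ graphics::par(op); graphics::layout(1) })
  x <- (seq_len(ncol(v)) - 1) * map$pixel_pitch
  y <- (seq_len(nrow(v)) - 1) * map$pixel_pitch
  graphics::image(x, y, t(v)[, rev(seq_len(nrow(v))), drop = FALSE],
                  col = pal, zlim = rng, xlab = "x (mm)", ylab = "y (mm)",
                  main = main, useRaster = TRUE)
  if (!is.null(probe)) {
    px <- c(probe$p1[2], probe$p2[2]) * map$pixel_pitch
    py <- (nrow(v) - 1 - c(probe$p1[1], probe$p2[1])) * map$pixel_pitch
    graphics::lines(px, py, lwd = 2)
    graphics::points(px, py, pch = 19)
  }
  graphics::par(mar = c(4, 1, 3, 3))
  zseq <- seq(rng[1], rng[2], length.out = 64)
  graphics::image(1, zseq, matrix(zseq, 1), col = pal, xaxt = "n",
                  xlab = "", ylab = "", useRaster = TRUE)
  invisible(NULL)
}

#' Plot an isochrone set
#'
#' @param iso An `isochrone_set` from [isochrone_map()].
#' @param act_map Optional activation map drawn underneath.
#' @param probe Optional probe overlay.
#' @export
plot_isochrones <- function(iso, act_map = NULL, probe = NULL) {
  stopifnot(inherits(iso, "isochrone_set"))
  if (!is.null(act_map)) {
    plot_map(act_map, probe = probe,
             main = sprintf("isochrones every %g ms", iso$interval))
  } else {
    xs <- unlist(lapply(iso$contours, `[[`, "x"))
    ys <- unlist(lapply(iso$contours, `[[`, "y"))
    graphics::plot(range(xs), range(ys), type = "n", xlab = "x (mm)",
                   ylab = "y (mm)",
                   main = sprintf("isochrones every %g ms", iso$interval))
  }
  for (ct in iso$contours) graphics::lines(ct$x, ct$y)
  invisible(NULL)
}

#' Write a full analysis bundle under one run directory
#'
#' Serializes a group table (conventional CSV layout), per-cycle-length
#' maps (CSV + PNG), isochrone renderings, a machine-readable JSON of all
#' statistics and a manifest listing every file written. Re-running with
#' identical inputs reproduces identical CSV/JSON content.
#'
#' @param dir Run directory (created if needed).
#' @param group_tables Named list of `group_table` objects (optional).
#' @param map_sets Named list of `map_set` objects (optional).
#' @param extra Named list of additional JSON-serializable results.
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(dir, group_tables = NULL, map_sets = NULL,
                          extra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stats <- list()
  for (nm in names(group_tables)) {
    p <- file.path(dir, paste0("table_", nm, ".csv"))
    write_group_table(group_tables[[nm]], p)
    files <- c(files, p)
    gt <- group_tables[[nm]]
    stats[[nm]] <- list(summary = gt$summary,
                        trend = gt$trend,
                        dunn = lapply(gt$dunn, function(d)
                          if (is.null(d)) NULL else
                            list(run = d$run, p_unadjusted = d$p_unadjusted,
                                 p_holm = d$p_holm)))
  }
  for (nm in names(map_sets)) {
    ms <- map_sets[[nm]]
    for (cl in names(ms)) {
      base <- file.path(dir, sprintf("%s_cl%s", nm, cl))
      files <- c(files, write_map(ms[[cl]]$activation, paste0(base, "_activation")))
      files <- c(files, write_map(ms[[cl]]$apd, paste0(base, "_apd80")))
    }
    stats[[paste0(nm, "_map_summary")]] <- attr(ms, "summary")
  }
  if (!is.null(extra)) stats <- c(stats, extra)
  sp <- file.path(dir, "stats.json")
  jsonlite::write_json(stats, sp, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  files <- c(files, sp)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(files = basename(files)), mp, auto_unbox = TRUE)
  invisible(mp)
}
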