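# Spheroid morphometrics: mask segmentation, moment-based roundness,
# roundness-over-time traces, calcium dose summaries, and cryo-section
# straightened intensity profiles.

#' Segment the spheroid in a single frame
#'
#' Deterministic threshold/morphology segmenter: Otsu threshold,
#' morphological closing, hole filling, then the largest connected component
#' above `min_size`. (A trained pixel classifier would serve the same role;
#' downstream metrics depend only on the mask.)
#'
#' @param frame 2-D numeric matrix.
#' @param min_size minimum component area, px.
#' @param close_radius closing structuring-element radius, px.
#' @return logical mask.
#' @export
segment_spheroid <- function(frame, min_size = 50, close_radius = 3) {
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (diff(rng) == 0) stop("no spheroid: constant frame")
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  # contrast guard: a frame without a genuine bright object splits its own
  # noise, leaving fore/background barely separated
  mu_fg <- mean(norm[mask]); mu_bg <- mean(norm[!mask])
  if (!any(mask) || all(mask) ||
      (mu_fg - mu_bg) < 2 * (sd(norm[mask]) + sd(norm[!mask])))
    stop("no spheroid: insufficient foreground contrast")
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
  mask <- EBImage::closing(mask, brush)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("no spheroid: empty mask")
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_size)
    stop("no spheroid: largest component below min_size")
  matrix(lab == which.max(sizes), nrow(frame), ncol(frame))
}

# second-moment (covariance) eigenvalues of a mask's pixel coordinates
mask_moments <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  ny <- nrow(mask)
  y <- (idx - 1) %% ny + 1
  x <- (idx - 1) %/% ny + 1
  n <- length(idx)
  cy <- mean(y); cx <- mean(x)
  syy <- mean((y - cy)^2); sxx <- mean((x - cx)^2)
  sxy <- mean((y - cy) * (x - cx))
  tr <- syy + sxx; det <- syy * sxx - sxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  list(n = n, center = c(cy, cx),
       l1 = tr / 2 + disc, l2 = max(tr / 2 - disc, 0),
       angle = atan2(2 * sxy, sxx - syy) / 2)
}

#' Moment-based roundness of a binary mask
#'
#' `4 Area / (pi major_axis^2)` with the major axis taken from the
#' second-moment-equivalent ellipse (`major = 4 sqrt(lambda_max)`). Equals 1
#' for a disk and the axis ratio b/a for an ellipse; clipped to [0, 1].
#' The circularity `4 pi Area / Perimeter^2` is available as an alternative
#' through [spheroid_metrics()].
#'
#' @param mask logical matrix, non-empty.
#' @return roundness in [0, 1].
#' @export
roundness <- function(mask) {
  m <- mask_moments(mask)
  major <- 4 * sqrt(m$l1)
  r <- 4 * m$n / (pi * major^2)
  min(max(r, 0), 1)
}

#' Per-frame morphometrics of a spheroid mask
#'
#' @param mask logical matrix.
#' @param pixel_size micrometers per pixel.
#' @param frame_time frame time stamp (caller's unit).
#' @return one-row data.frame: frame_time, area (um^2), perimeter (um),
#'   major_axis, minor_axis (um), roundness, circularity.
#' @export
spheroid_metrics <- function(mask, pixel_size = 1, frame_time = NA) {
  m <- mask_moments(mask)
  img <- EBImage::Image(mask * 1)
  per <- EBImage::computeFeatures.shape(EBImage::bwlabel(img))[1, "s.perimeter"]
  major <- 4 * sqrt(m$l1) * pixel_size
  minor <- 4 * sqrt(m$l2) * pixel_size
  area <- m$n * pixel_size^2
  data.frame(frame_time = frame_time, area = area,
             perimeter = per * pixel_size,
             major_axis = major, minor_axis = minor,
             roundness = min(max(4 * area / (pi * major^2), 0), 1),
             circularity = 4 * pi * area / (per * pixel_size)^2)
}

#' Roundness over time for a spheroid movie
#'
#' Segments every frame and measures roundness; frames where segmentation
#' fails are flagged and filled by linear interpolation. More than 50
#' percent flagged frames is a quality error.
#'
#' @param movie single-channel `FrameStack` (or 3-D Y x X x T array plus
#'   `frame_interval`).
#' @param frame_interval min between frames (taken from the stack when
#'   omitted).
#' @param query_times_h optional times (h) at which to report interpolated
#'   roundness (e.g. `c(3, 20, 48)`).
#' @return an `IntensityTrace` with times in hours; interpolated query
#'   values in `attr(, "query")`, flagged frames in `attr(, "flagged")`.
#' @export
roundness_timeseries <- function(movie, frame_interval = NULL,
                                 query_times_h = NULL) {
  if (inherits(movie, "FrameStack")) {
    frame_interval <- frame_interval %||% movie$frame_interval
    arr <- if (dim(movie$data)[2] == 1)
      aperm(movie$data[, 1, 1, , , drop = FALSE][, 1, 1, , ], c(2, 3, 1))
    else central_projection(movie)
  } else {
    stopifnot(length(dim(movie)) == 3)
    if (is.null(frame_interval)) stop("frame_interval required for arrays")
    arr <- movie
  }
  nt <- dim(arr)[3]
  if (nt < 2) stop("need at least 2 frames")
  times_h <- (seq_len(nt) - 1) * frame_interval / 60
  vals <- rep(NA_real_, nt)
  for (f in seq_len(nt)) {
    m <- tryCatch(segment_spheroid(arr[, , f]), error = function(e) NULL)
    if (!is.null(m)) vals[f] <- roundness(m)
  }
  flagged <- which(is.na(vals))
  if (length(flagged) > nt / 2)
    stop("quality error: segmentation failed in more than half the frames")
  if (length(flagged))
    vals[flagged] <- approx(times_h[-flagged], vals[-flagged],
                            xout = times_h[flagged], rule = 2)$y
  tr <- intensity_trace(times_h, vals)
  attr(tr, "flagged") <- flagged
  if (!is.null(query_times_h))
    attr(tr, "query") <- data.frame(
      time_h = query_times_h,
      roundness = approx(times_h, vals, xout = query_times_h, rule = 2)$y)
  tr
}

#' Roundness summary across a calcium dose series
#'
#' @param movies named list: one entry per calcium concentration (name =
#'   mM value), each a list of movies (or of precomputed roundness
#'   `IntensityTrace`s with times in hours).
#' @param t_query_h comparison time, hours (published comparison at 20 h).
#' @return data.frame (ca_ext, mean_roundness, sd, n), ordered by dose.
#' @export
ca_dose_summary <- function(movies, t_query_h = 20) {
  if (!length(movies) || is.null(names(movies)))
    stop("movies must be a named list keyed by calcium concentration")
  rows <- lapply(names(movies), function(nm) {
    grp <- movies[[nm]]
    if (!length(grp)) stop("missing concentration group: ", nm)
    vals <- vapply(grp, function(m) {
      tr <- if (inherits(m, "IntensityTrace")) m else roundness_timeseries(m)
      approx(tr$times, tr$values, xout = t_query_h, rule = 2)$y
    }, numeric(1))
    data.frame(ca_ext = as.numeric(nm), mean_roundness = mean(vals),
               sd = sd(vals), n = length(vals))
  })
  out <- do.call(rbind, rows)
  out[order(out$ca_ext), , drop = FALSE]
}

# extract a named channel as a 2-D matrix from FrameStack / matrix input
section_channel <- function(image, channel) {
  if (inherits(image, "FrameStack")) {
    if (is.character(channel)) channel <- match(channel, image$channel_names)
    image$data[1, 1, channel, , ]
  } else if (is.matrix(image)) image else
    stop("image must be a FrameStack or a matrix")
}

#' Straightened intensity profiles of a spheroid section
#'
#' Detects the section mask, then samples the image along `n_axes` diameters
#' through the mask centroid (at 0, 60, 120 degrees for three axes) using a
#' band of `line_width_px` perpendicular width. Intensities are averaged
#' perpendicular to the axis, binned into `n_bins` along it, and normalized
#' to the profile maximum. The central bins (indices 30-50 of 100) of a
#' hollow section drop well below the peripheral bins.
#'
#' @param image 2-channel `FrameStack` (or matrix) of a section.
#' @param channel channel to profile (name or index; default "junction").
#' @param n_axes number of straightening axes (default 3).
#' @param line_width_px perpendicular averaging width, px (default 99).
#' @param n_bins bins along the axis (default 100).
#' @param mask_channel channel used to detect the section (default same as
#'   `channel`).
#' @return data.frame (axis_id, bin_index, relative_intensity).
#' @export
straighten_profile <- function(image, channel = "junction", n_axes = 3,
                               line_width_px = 99, n_bins = 100,
                               mask_channel = NULL) {
  ch <- section_channel(image, channel)
  mk <- section_channel(image, mask_channel %||% channel)
  mask <- EBImage::fillHull(segment_spheroid(mk))
  m <- mask_moments(mask)
  minor_extent <- 4 * sqrt(m$l2)
  if (line_width_px > 1.5 * minor_extent)
    stop("section smaller than the straightening line width")
  radius <- sqrt(max((which(mask, arr.ind = TRUE)[, 1] - m$center[1])^2 +
                     (which(mask, arr.ind = TRUE)[, 2] - m$center[2])^2))
  angles <- seq(0, by = pi / n_axes, length.out = n_axes)
  s <- seq(-radius, radius, length.out = n_bins)         # bin centers
  w <- seq(-(line_width_px - 1) / 2, (line_width_px - 1) / 2, by = 1)
  out <- lapply(seq_len(n_axes), function(ai) {
    th <- angles[ai]
    uy <- sin(th); ux <- cos(th)                        # along the axis
    vy <- cos(th); vx <- -sin(th)                       # perpendicular
    prof <- vapply(s, function(si) {
      py <- m$center[1] + si * uy + w * vy
      px <- m$center[2] + si * ux + w * vx
      mean(bilinear(ch, py, px), na.rm = TRUE)
    }, numeric(1))
    data.frame(axis_id = ai, bin_index = seq_len(n_bins),
               relative_intensity = prof / max(prof))
  })
  do.call(rbind, out)
}

#' Mean peripheral laminin intensity of a section
#'
#' The periphery is a morphological ring (section mask dilated minus eroded
#' by `ring_width`); laminin-positive pixels inside the ring are detected by
#' Otsu threshold and their background-subtracted mean intensity returned
#' (0 when nothing is detected).
#'
#' @param image 2-channel `FrameStack` of a section.
#' @param laminin_channel channel name or index (default "laminin").
#' @param mask_channel channel used to detect the section (default
#'   "junction").
#' @param ring_width half-width of the periphery ring, px.
#' @return mean laminin intensity over the detected peripheral pixels.
#' @export
periphery_laminin <- function(image, laminin_channel = "laminin",
                              mask_channel = "junction", ring_width = 4) {
  lam <- section_channel(image, laminin_channel)
  mk <- section_channel(image, mask_channel)
  mask <- EBImage::fillHull(segment_spheroid(mk))
  brush <- EBImage::makeBrush(2 * ring_width + 1, shape = "disc")
  ring <- EBImage::dilate(mask, brush) & !EBImage::erode(mask, brush)
  if (!any(ring)) stop("empty periphery ring")
  vals <- lam[ring]
  bg <- estimate_background(lam)
  rng <- range(vals)
  if (diff(rng) < 1e-12) return(max(mean(vals) - bg, 0))
  th <- EBImage::otsu(EBImage::Image((vals - rng[1]) / diff(rng)),
                      range = c(0, 1))
  pos <- vals[(vals - rng[1]) / diff(rng) > th]
  if (!length(pos)) return(0)
  detected <- mean(pos) - bg
  # nothing but background detected: report 0
  if (detected < 3 * (stats::mad(vals) + 1e-12) && mean(pos) <= bg + 1e-9)
    return(0)
  max(detected, 0)
}
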