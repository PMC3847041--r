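# Linear spectral unmixing and the two FRET estimators: the acceptor
# photobleach dequenching ratio and the baseline-normalized ratiometric
# trace. Abundances are obtained by per-pixel non-negative least squares
# against reference emission spectra, after per-band background subtraction.

#' Build a reference emission spectrum from a single-fluorophore ROI
#'
#' The reference is the L2-normalized mean spectrum over the ROI pixels after
#' per-band background subtraction (background estimated as the histogram
#' mode of the dimmest 10 percent of each band).
#'
#' @param stack a `SpectralStack`.
#' @param roi rectangular ROI `c(y0, y1, x0, x1)` or a logical mask.
#' @param name fluorophore label.
#' @return a `ReferenceSpectrum` (name, unit-norm weights, band_centers).
#' @export
build_reference_spectrum <- function(stack, roi, name = "reference") {
  stopifnot(inherits(stack, "SpectralStack"))
  m <- roi_mask(roi, dim(stack$data)[1:2])
  if (!any(m)) stop("empty ROI")
  b <- dim(stack$data)[3]
  spec <- numeric(b); bg <- numeric(b)
  for (i in seq_len(b)) {
    band <- stack$data[, , i]
    bg[i] <- estimate_background(band)
    spec[i] <- mean(band[m]) - bg[i]
  }
  if (sum(spec) <= 0 || max(spec) <= 1e-12)
    stop("low signal: ROI mean does not exceed background")
  spec[spec < 0] <- 0
  structure(list(name = name, weights = spec / sqrt(sum(spec^2)),
                 band_centers = stack$band_centers),
            class = "ReferenceSpectrum")
}

# per-pixel NNLS against spectral matrix S (B x K). Fast path: unconstrained
# least squares for all pixels at once; pixels with a negative coefficient
# are re-solved with true NNLS (active set).
nnls_pixels <- function(Y, S) {
  K <- ncol(S)
  XtX <- crossprod(S)
  C <- solve(XtX, crossprod(S, Y))               # K x npix, unconstrained
  bad <- which(apply(C < -1e-12, 2, any))
  for (p in bad) C[, p] <- pracma::lsqnonneg(S, Y[, p])$x
  C[C < 0] <- 0
  C
}

#' Linearly unmix a spectral stack into fluorophore abundances
#'
#' Solves a non-negative least-squares problem per pixel against the
#' reference spectra (abundances are physical intensities, hence the
#' non-negativity constraint). The flat spectral background is estimated per
#' band and subtracted first.
#'
#' @param stack a `SpectralStack`.
#' @param spectra list of at least two `ReferenceSpectrum` objects; the first
#'   two (or those named "donor"/"acceptor") define the returned pair.
#' @param subtract_background subtract the per-band background estimate
#'   before solving (default TRUE).
#' @return an `UnmixedPair`: `donor_abundance`, `acceptor_abundance`,
#'   `residual_norm` (all Y x X images), plus all abundances by name.
#' @export
unmix <- function(stack, spectra, subtract_background = TRUE) {
  stopifnot(inherits(stack, "SpectralStack"))
  if (length(spectra) < 2) stop("need at least two reference spectra")
  S <- vapply(spectra, function(s) s$weights, numeric(dim(stack$data)[3]))
  if (kappa(S, exact = TRUE) > 1e6)
    stop("ill-conditioned: reference spectra are nearly collinear")
  d <- dim(stack$data)
  Y <- t(matrix(stack$data, d[1] * d[2], d[3]))   # B x npix
  if (subtract_background) {
    bg <- vapply(seq_len(d[3]), function(i) estimate_background(stack$data[, , i]),
                 numeric(1))
    Y <- Y - bg
  }
  C <- nnls_pixels(Y, S)
  resid <- sqrt(colSums((Y - S %*% C)^2))
  nms <- vapply(seq_along(spectra), function(i)
    spectra[[i]]$name %||% paste0("s", i), character(1))
  abund <- lapply(seq_along(spectra), function(i) matrix(C[i, ], d[1], d[2]))
  names(abund) <- nms
  di <- if ("donor" %in% nms) which(nms == "donor")[1] else 1L
  ai <- if ("acceptor" %in% nms) which(nms == "acceptor")[1] else 2L
  structure(list(donor_abundance = abund[[di]],
                 acceptor_abundance = abund[[ai]],
                 abundances = abund,
                 residual_norm = matrix(resid, d[1], d[2])),
            class = "UnmixedPair")
}

#' Acceptor-photobleach FRET ratio
#'
#' Computes the donor dequenching ratio
#' `(I_postDonor - I_preDonor) / I_postDonor` from mean unmixed donor
#' abundances over the junction mask. Before computing the ratio the bleach
#' is verified: the mean acceptor abundance inside the bleach region must
#' have dropped by at least `bleach_threshold` (high-power bleaching is
#' near-complete; the guard catches failed bleaches and degraded data).
#'
#' @param pre,post `UnmixedPair`s of the pre- and post-bleach acquisitions.
#' @param junction_mask logical mask (or `c(y0, y1, x0, x1)` rectangle) of
#'   the junction.
#' @param bleach_roi region used for bleach verification; defaults to the
#'   junction mask.
#' @param bleach_threshold minimum fractional acceptor loss (default 0.5).
#' @return a `BleachFretResult`: `fret_ratio`, `i_pre_donor`, `i_post_donor`,
#'   `roi`.
#' @export
acceptor_bleach_fret <- function(pre, post, junction_mask, bleach_roi = NULL,
                                 bleach_threshold = 0.5) {
  stopifnot(inherits(pre, "UnmixedPair"), inherits(post, "UnmixedPair"))
  jm <- roi_mask(junction_mask, dim(pre$donor_abundance))
  if (!any(jm)) stop("empty junction mask")
  bm <- if (is.null(bleach_roi)) jm else
    roi_mask(bleach_roi, dim(pre$donor_abundance))
  a_pre <- mean(pre$acceptor_abundance[bm])
  a_post <- mean(post$acceptor_abundance[bm])
  if (a_pre <= 0 || (a_pre - a_post) / a_pre < bleach_threshold)
    stop(sprintf(
      "bleach failure: acceptor abundance dropped %.0f%% (need >= %.0f%%)",
      100 * (a_pre - max(a_post, 0)) / max(a_pre, 1e-12),
      100 * bleach_threshold))
  i_pre <- mean(pre$donor_abundance[jm])
  i_post <- mean(post$donor_abundance[jm])
  if (i_post <= 0) stop("degenerate: post-bleach donor intensity <= 0")
  structure(list(fret_ratio = (i_post - i_pre) / i_post,
                 i_pre_donor = i_pre, i_post_donor = i_post,
                 roi = junction_mask),
            class = "BleachFretResult")
}

#' @export
print.BleachFretResult <- function(x, ...) {
  cat(sprintf("Acceptor-bleach FRET: %.1f%%  (donor %.3f -> %.3f)\n",
              100 * x$fret_ratio, x$i_pre_donor, x$i_post_donor))
  invisible(x)
}

#' Ratiometric FRET trace around a chelation event
#'
#' Unmixes every frame of a lambda time series, forms the junction-mean
#' acceptor/donor abundance ratio per frame, normalizes it so the baseline
#' (pre-event) mean is 100 percent, and summarizes `fret_before` /
#' `fret_after` over declared windows. Frames whose donor mean is not
#' positive are flagged and excluded.
#'
#' @param series list with `stacks` (list of `SpectralStack`) and `times`,
#'   as returned by [generate_ratiometric_series()], or a bare list of
#'   stacks (then supply `times`).
#' @param spectra reference spectra passed to [unmix()].
#' @param junction_mask logical mask or rectangle of the junction.
#' @param event_time event time in the units of `times`.
#' @param times frame times; defaults to `series$times`.
#' @param before_window window for `fret_before`; default all frames before
#'   the event.
#' @param after_window window for `fret_after`; default the last 25 percent
#'   of frames (the ratio has then relaxed to its new level).
#' @return a `RatiometricTrace`: `times`, `ratio_percent`, `event_time`,
#'   `fret_before`, `fret_after`, `excluded_frames`.
#' @export
ratiometric_fret <- function(series, spectra, junction_mask, event_time,
                             times = NULL, before_window = NULL,
                             after_window = NULL) {
  stacks <- if (!is.null(series$stacks)) series$stacks else series
  times <- times %||% series$times
  if (is.null(times) || length(times) != length(stacks))
    stop("frame times missing or wrong length")
  if (event_time <= min(times) || event_time > max(times))
    stop("event_time outside the recorded series")
  jm <- roi_mask(junction_mask, dim(stacks[[1]]$data)[1:2])
  ratio <- rep(NA_real_, length(stacks))
  for (i in seq_along(stacks)) {
    u <- unmix(stacks[[i]], spectra)
    dmean <- mean(u$donor_abundance[jm])
    if (dmean <= 0) next                      # degenerate frame, excluded
    ratio[i] <- mean(u$acceptor_abundance[jm]) / dmean
  }
  excluded <- which(is.na(ratio))
  before_window <- before_window %||% c(min(times), event_time - 1e-9)
  after_window <- after_window %||%
    c(times[ceiling(length(times) * 0.75)], max(times))
  before <- !is.na(ratio) & times >= before_window[1] & times <= before_window[2]
  after <- !is.na(ratio) & times >= after_window[1] & times <= after_window[2]
  if (!any(before)) stop("no usable baseline frames before the event")
  ratio_percent <- 100 * ratio / mean(ratio[before])
  structure(list(times = times, ratio_percent = ratio_percent,
                 event_time = event_time,
                 fret_before = mean(ratio_percent[before]),
                 fret_after = mean(ratio_percent[after]),
                 excluded_frames = excluded),
            class = "RatiometricTrace")
}

#' @export
print.RatiometricTrace <- function(x, ...) {
  cat(sprintf(
    "Ratiometric FRET: before %.1f%%, after %.1f%% (event at t=%g, %d frames)\n",
    x$fret_before, x$fret_after, x$event_time, length(x$times)))
  invisible(x)
}
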