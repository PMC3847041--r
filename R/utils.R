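# Shared internal helpers: seeded RNG evaluation, background estimation,
# Gaussian emission model, small validators.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state, so generators are reproducible
#' without disturbing the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Estimate image background level
#'
#' The background is taken as the mode (histogram peak) of the dimmest
#' fraction of pixels, which is robust to bright foreground structures.
#'
#' @param x numeric array of intensities.
#' @param frac fraction of dimmest pixels considered (default 0.1).
#' @param nbins number of histogram bins over the dim tail.
#' @return scalar background estimate.
#' @export
estimate_background <- function(x, frac = 0.1, nbins = 64) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite pixels for background estimation")
  q <- stats::quantile(v, frac, names = FALSE)
  tailv <- v[v <= q]
  if (length(unique(tailv)) == 1L) return(tailv[1])
  h <- graphics::hist(tailv, breaks = nbins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Gaussian emission spectrum over detection bands
#'
#' Emission spectra are modeled as Gaussians in wavelength, the simplest
#' shape that preserves realistic spectral overlap between a ~475 nm and a
#' ~528 nm emitter over the 473-569 nm detection range.
#'
#' @param band_centers detection band centers in nm.
#' @param peak emission peak in nm.
#' @param sd spectral standard deviation in nm (default 25).
#' @param normalize if TRUE (default), scale to unit L2 norm.
#' @return numeric vector of band weights.
#' @export
spectrum_gaussian <- function(band_centers, peak, sd = 25, normalize = TRUE) {
  w <- exp(-(band_centers - peak)^2 / (2 * sd^2))
  if (normalize) w <- w / sqrt(sum(w^2))
  w
}

# rectangular ROI (y0, y1, x0, x1) -> logical mask
roi_mask <- function(roi, shape) {
  if (is.matrix(roi) || is.array(roi)) return(roi)
  stopifnot(length(roi) == 4)
  m <- matrix(FALSE, shape[1], shape[2])
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > shape[1] || roi[4] > shape[2])
    stop("ROI outside image")
  m[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
  m
}

# coordinate grids for an (ny, nx) image, 1-based (row, col)
pixel_grid <- function(shape) {
  ny <- shape[1]; nx <- shape[2]
  list(y = matrix(rep(seq_len(ny), nx), ny, nx),
       x = matrix(rep(seq_len(nx), each = ny), ny, nx))
}

# camera noise model: Gaussian shot-noise approximation with sd proportional
# to the signal, plus constant read noise
add_camera_noise <- function(signal, noise_sd, read_noise = 0) {
  if (noise_sd == 0 && read_noise == 0) return(signal)
  sdv <- sqrt((noise_sd * signal)^2 + read_noise^2)
  signal + rnorm(length(signal), 0, 1) * sdv
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g outside its valid range", name, x))
  invisible(x)
}

# bilinear interpolation of matrix `img` at (row, col) positions; points
# outside the image give NA
bilinear <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(y))
  ok <- y >= 1 & y <= ny & x >= 1 & x <= nx & is.finite(y) & is.finite(x)
  if (!any(ok)) return(out)
  y <- y[ok]; x <- x[ok]
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  v <- img[cbind(y0, x0)]       * (1 - fy) * (1 - fx) +
       img[cbind(y0 + 1, x0)]   * fy       * (1 - fx) +
       img[cbind(y0, x0 + 1)]   * (1 - fy) * fx +
       img[cbind(y0 + 1, x0 + 1)] * fy     * fx
  out[ok] <- v
  out
}
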