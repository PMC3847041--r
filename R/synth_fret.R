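# Synthetic spectral FRET scenes: two cells sharing a junction, imaged in
# lambda mode. Ground truth is the acceptor-bleach FRET ratio the scene
# should yield, so the unmix -> bleach-ratio pipeline can be validated by
# closed-loop parameter recovery.

#' Parameters of a synthetic spectral FRET scene
#'
#' @param fret_ratio_true the acceptor-bleach FRET ratio the scene should
#'   yield, a fraction in [0, 1).
#' @param image_shape image size (Y, X) in pixels.
#' @param pixel_size micrometers per pixel (default 106.07/512, the lambda
#'   acquisition geometry).
#' @param band_centers spectral detection band centers, nm; default twelve
#'   8.7 nm bands starting at 473 nm (the 473-569 nm detection range).
#' @param donor_peak,acceptor_peak emission peaks in nm (Cerulean-like 475,
#'   Venus-like 528).
#' @param spectrum_sd Gaussian emission width, nm.
#' @param noise_sd per-pixel multiplicative camera noise as a fraction of the
#'   signal.
#' @param read_noise constant additive noise floor.
#' @param background flat background offset added to every band.
#' @param sensitization acceptor sensitized-emission gain per unit of donor
#'   quench (affects realism only, not the recovered ratio).
#' @param seed RNG seed.
#' @return a `SceneParams` list.
#' @export
scene_params <- function(fret_ratio_true = 0.199,
                         image_shape = c(64, 64),
                         pixel_size = 106.07 / 512,
                         band_centers = seq(473, by = 8.7, length.out = 12),
                         donor_peak = 475, acceptor_peak = 528,
                         spectrum_sd = 25,
                         noise_sd = 0.02, read_noise = 0.002,
                         background = 0.02, sensitization = 0.6,
                         seed = 1) {
  check_scalar(fret_ratio_true, "fret_ratio_true", 0, 1, upper_open = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(read_noise, "read_noise", 0)
  check_scalar(background, "background", 0)
  if (length(band_centers) < 3)
    stop("invalid parameter: fewer than 3 spectral bands")
  if (any(diff(band_centers) <= 0))
    stop("invalid parameter: band_centers must be strictly increasing")
  stopifnot(length(image_shape) == 2, all(image_shape >= 16))
  structure(list(
    fret_ratio_true = fret_ratio_true, image_shape = as.integer(image_shape),
    pixel_size = pixel_size, band_centers = band_centers,
    donor_peak = donor_peak, acceptor_peak = acceptor_peak,
    spectrum_sd = spectrum_sd, noise_sd = noise_sd, read_noise = read_noise,
    background = background, sensitization = sensitization, seed = seed),
    class = "SceneParams")
}

# static scene geometry shared by the bleach and ratiometric generators:
# two cell bodies left/right, a junction stripe between them, and pure
# single-fluorophore reference ROIs inside each cell body
scene_layout <- function(shape) {
  ny <- shape[1]; nx <- shape[2]
  jx <- round(nx / 2) + c(-2L, 2L)               # junction stripe columns
  jy <- c(round(ny * 0.25), round(ny * 0.75))    # junction stripe rows
  c1 <- c(3L, ny - 2L, 3L, jx[1] - 3L)           # donor cell body
  c2 <- c(3L, ny - 2L, jx[2] + 3L, nx - 2L)      # acceptor cell body
  list(
    cell1 = c1, cell2 = c2,
    junction = c(jy[1], jy[2], jx[1], jx[2]),
    bleach_roi = c(jy[1] - 3L, jy[2] + 3L, jx[1] - 1L, jx[2] + 1L),
    donor_roi = c(round(ny * 0.35), round(ny * 0.65), c1[3] + 2L,
                  c1[3] + round((c1[4] - c1[3]) * 0.6)),
    acceptor_roi = c(round(ny * 0.35), round(ny * 0.65),
                     c2[3] + round((c2[4] - c2[3]) * 0.4), c2[4] - 2L))
}

# render one lambda frame from donor/acceptor abundance images
render_spectral <- function(donor_img, acceptor_img, params) {
  b <- params$band_centers
  wd <- spectrum_gaussian(b, params$donor_peak, params$spectrum_sd)
  wa <- spectrum_gaussian(b, params$acceptor_peak, params$spectrum_sd)
  ny <- nrow(donor_img); nx <- ncol(donor_img)
  arr <- array(0, c(ny, nx, length(b)))
  for (i in seq_along(b)) {
    sig <- params$background + donor_img * wd[i] + acceptor_img * wa[i]
    arr[, , i] <- add_camera_noise(sig, params$noise_sd, params$read_noise)
  }
  spectral_stack(arr, b)
}

#' Generate an acceptor-bleach spectral FRET scene
#'
#' Renders pre- and post-bleach lambda stacks of two cells with a shared
#' junction. In the pre-bleach image the junction donor is quenched by the
#' factor `1 - fret_ratio_true` and the acceptor is sensitized; the
#' post-bleach image zeroes the acceptor inside the bleach ROI and dequenches
#' the donor. Applying [build_reference_spectrum()], [unmix()] and
#' [acceptor_bleach_fret()] to a noiseless scene recovers `fret_ratio_true`
#' exactly.
#'
#' @param params a [scene_params()] object.
#' @return list with `pre`, `post` (`SpectralStack`s) and `truth` (scene
#'   parameters plus junction/bleach/reference ROIs as `c(y0, y1, x0, x1)`).
#' @export
generate_fret_scene <- function(params) {
  stopifnot(inherits(params, "SceneParams"))
  lay <- scene_layout(params$image_shape)
  ny <- params$image_shape[1]; nx <- params$image_shape[2]
  E <- params$fret_ratio_true
  d0 <- matrix(0, ny, nx); a0 <- matrix(0, ny, nx)
  d0[lay$cell1[1]:lay$cell1[2], lay$cell1[3]:lay$cell1[4]] <- 0.8
  a0[lay$cell2[1]:lay$cell2[2], lay$cell2[3]:lay$cell2[4]] <- 0.8
  jm <- roi_mask(lay$junction, params$image_shape)
  D0 <- 1.2; A0 <- 1.2
  pre_d <- d0; pre_a <- a0
  pre_d[jm] <- D0 * (1 - E)                       # donor quenched by FRET
  pre_a[jm] <- A0 + params$sensitization * E * D0 # sensitized emission
  post_d <- d0; post_a <- a0
  bm <- roi_mask(lay$bleach_roi, params$image_shape)
  post_d[jm] <- D0                                # dequenched
  post_a[jm] <- A0
  post_a[bm] <- 0                                 # acceptor photobleached
  with_seed(params$seed, {
    pre <- render_spectral(pre_d, pre_a, params)
    post <- render_spectral(post_d, post_a, params)
    list(pre = pre, post = post,
         truth = c(lay, list(params = params, junction_mask = jm)))
  })
}

#' Generate a ratiometric FRET time series around a chelation event
#'
#' Produces a time series of lambda stacks in which the junction
#' acceptor/donor ratio is constant before `event_time` and relaxes to
#' `(1 - drop_fraction)` of baseline afterwards, emulating calcium-chelator
#' addition during ratiometric FRET recording. Ground truth:
#' `fret_before` = 100 percent, `fret_after` = `100 * (1 - drop_fraction)`.
#'
#' @param params a [scene_params()] object (noise, bands, geometry).
#' @param drop_fraction fractional drop of the junction acceptor/donor ratio
#'   after the event, in [0, 1].
#' @param event_time chelator addition time, seconds.
#' @param duration total recording length, seconds.
#' @param dt frame interval, seconds (default 0.5).
#' @param relax_time exponential relaxation time of the drop, seconds.
#' @return list with `stacks` (list of `SpectralStack`), `times` (s),
#'   `event_time`, and `truth`.
#' @export
generate_ratiometric_series <- function(params, drop_fraction,
                                        event_time, duration,
                                        dt = 0.5, relax_time = 3) {
  stopifnot(inherits(params, "SceneParams"))
  check_scalar(drop_fraction, "drop_fraction", 0, 1)
  if (event_time <= 0 || event_time >= duration)
    stop("event_time outside the recorded series")
  lay <- scene_layout(params$image_shape)
  ny <- params$image_shape[1]; nx <- params$image_shape[2]
  jm <- roi_mask(lay$junction, params$image_shape)
  d0 <- matrix(0, ny, nx); a0 <- matrix(0, ny, nx)
  d0[lay$cell1[1]:lay$cell1[2], lay$cell1[3]:lay$cell1[4]] <- 0.8
  a0[lay$cell2[1]:lay$cell2[2], lay$cell2[3]:lay$cell2[4]] <- 0.8
  d0[jm] <- 1.0
  times <- seq(0, duration, by = dt)
  with_seed(params$seed, {
    stacks <- lapply(times, function(t) {
      rel <- if (t < event_time) 1 else
        1 - drop_fraction * (1 - exp(-(t - event_time) / relax_time))
      a <- a0
      a[jm] <- 1.2 * rel
      render_spectral(d0, a, params)
    })
    list(stacks = stacks, times = times, event_time = event_time,
         truth = c(lay, list(params = params, junction_mask = jm,
                             fret_before = 100,
                             fret_after = 100 * (1 - drop_fraction))))
  })
}
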