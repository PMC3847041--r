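# Synthetic spheroid formation movies and cryo-section images.
#
# A spheroid movie is a bright-on-dark aggregate whose mask roundness tracks
# a declared trajectory: constant `roundness_start` during a baseline, then
# a rising double exponential towards `roundness_plateau`. The rendered
# shape is an ellipse of constant area whose axis ratio equals the target
# roundness (the moment-based roundness of an ellipse is exactly its axis
# ratio), decorated with small lobes that shrink as compaction proceeds.

#' Parameters of a synthetic spheroid formation movie
#'
#' The roundness trajectory is `R(t) = roundness_start` for `t <= baseline_h`
#' and `plateau - A_f exp(-(t-t0)/tau_fast) - A_s exp(-(t-t0)/tau_slow)`
#' afterwards, with amplitudes split `amp_fast_frac` : `1 - amp_fast_frac`
#' and tied to continuity at the breakpoint.
#'
#' @param roundness_start,roundness_plateau trajectory endpoints in (0, 1].
#' @param tau_fast,tau_slow time constants, h (`tau_fast < tau_slow`).
#' @param baseline_h flat baseline before compaction starts, h.
#' @param amp_fast_frac fraction of the rise carried by the fast component.
#' @param ca_ext optional external calcium, mM; when given,
#'   `roundness_plateau` is derived from it via [ca_roundness_map()].
#' @param frame_interval min between frames (5, the spheroid acquisition).
#' @param duration movie length, h (48 for the full assay).
#' @param image_shape (Y, X) pixels.
#' @param pixel_size micrometers per pixel.
#' @param equiv_radius area-equivalent spheroid radius, px.
#' @param lobe_amp amplitude of the 5-fold lobes at the start of formation.
#' @param intensity,background foreground/background levels.
#' @param noise_sd per-pixel camera noise fraction.
#' @param seed RNG seed.
#' @return a `SpheroidParams` list.
#' @export
spheroid_params <- function(roundness_start = 0.15, roundness_plateau = 0.68,
                            tau_fast = 1.5, tau_slow = 10, baseline_h = 0.5,
                            amp_fast_frac = 0.8, ca_ext = NULL,
                            frame_interval = 5, duration = 48,
                            image_shape = c(128, 128), pixel_size = 3.3,
                            equiv_radius = 18, lobe_amp = 0.05,
                            intensity = 1, background = 0.05,
                            noise_sd = 0.02, seed = 1) {
  if (!is.null(ca_ext)) roundness_plateau <- ca_roundness_map(ca_ext)
  check_scalar(roundness_start, "roundness_start", 0, 1, lower_open = TRUE)
  check_scalar(roundness_plateau, "roundness_plateau", 0, 1,
               lower_open = TRUE)
  if (tau_fast >= tau_slow) stop("tau_fast must be smaller than tau_slow")
  check_scalar(tau_fast, "tau_fast", 0, lower_open = TRUE)
  check_scalar(baseline_h, "baseline_h", 0)
  structure(list(roundness_start = roundness_start,
                 roundness_plateau = roundness_plateau,
                 tau_fast = tau_fast, tau_slow = tau_slow,
                 baseline_h = baseline_h, amp_fast_frac = amp_fast_frac,
                 ca_ext = ca_ext, frame_interval = frame_interval,
                 duration = duration, image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, equiv_radius = equiv_radius,
                 lobe_amp = lobe_amp, intensity = intensity,
                 background = background, noise_sd = noise_sd, seed = seed),
            class = "SpheroidParams")
}

#' Ground-truth roundness trajectory
#' @param params a [spheroid_params()] object.
#' @param t_h time(s) in hours.
#' @return roundness value(s).
#' @export
spheroid_trajectory <- function(params, t_h) {
  dR <- params$roundness_plateau - params$roundness_start
  af <- params$amp_fast_frac * dR
  as_ <- (1 - params$amp_fast_frac) * dR
  t0 <- params$baseline_h
  ifelse(t_h <= t0, params$roundness_start,
         params$roundness_plateau -
           af * exp(-(t_h - t0) / params$tau_fast) -
           as_ * exp(-(t_h - t0) / params$tau_slow))
}

# render one spheroid frame: lobed ellipse of target roundness q, constant
# area, fixed orientation theta0
render_spheroid_frame <- function(shape, q, equiv_radius, lobe_amp, progress,
                                  theta0, intensity, background) {
  a <- equiv_radius / sqrt(q)      # major semi-axis
  b <- equiv_radius * sqrt(q)      # minor semi-axis
  g <- pixel_grid(shape)
  yc <- (shape[1] + 1) / 2; xc <- (shape[2] + 1) / 2
  dy <- g$y - yc; dx <- g$x - xc
  u <- dx * cos(theta0) + dy * sin(theta0)     # along major axis
  v <- -dx * sin(theta0) + dy * cos(theta0)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  amp <- lobe_amp * (1 - progress)
  inside <- rho <= 1 + amp * cos(5 * phi + theta0)
  img <- matrix(background, shape[1], shape[2])
  img[inside] <- intensity
  img
}

#' Generate a synthetic spheroid formation movie
#'
#' @param params a [spheroid_params()] object.
#' @return list with `movie` (single-channel `FrameStack`; `frame_interval`
#'   in minutes) and `truth`: `times_h`, the roundness trajectory, and
#'   `params`. Trajectory and mask roundness agree within ~0.02
#'   (discretization and lobes).
#' @export
generate_spheroid_movie <- function(params) {
  stopifnot(inherits(params, "SpheroidParams"))
  with_seed(params$seed, {
    shape <- params$image_shape
    times_h <- seq(0, params$duration, by = params$frame_interval / 60)
    nt <- length(times_h)
    theta0 <- runif(1, 0, pi)
    traj <- spheroid_trajectory(params, times_h)
    prog <- (traj - params$roundness_start) /
      max(params$roundness_plateau - params$roundness_start, 1e-9)
    prog <- pmin(pmax(prog, 0), 1)
    data <- array(0, c(nt, 1, 1, shape[1], shape[2]))
    for (f in seq_len(nt)) {
      img <- render_spheroid_frame(shape, traj[f], params$equiv_radius,
                                   params$lobe_amp, prog[f], theta0,
                                   params$intensity, params$background)
      data[f, 1, 1, , ] <- add_camera_noise(img, params$noise_sd, 0.002)
    }
    movie <- frame_stack(data, frame_interval = params$frame_interval,
                         pixel_size = params$pixel_size,
                         channel_names = "transmitted")
    list(movie = movie,
         truth = list(times_h = times_h, roundness = traj, params = params))
  })
}

#' Generate a synthetic spheroid cryo-section image
#'
#' The junction channel is a line lattice filling a disk (or an annulus when
#' `hollow`, emulating a hollow-core spheroid); the laminin channel is a
#' peripheral ring of mean intensity `laminin_level` (the extracellular
#' matrix shell).
#'
#' @param hollow logical; empty the central core of the junction lattice.
#' @param laminin_level mean intensity of the peripheral laminin ring (>= 0).
#' @param image_shape (Y, X) pixels.
#' @param radius section radius, px.
#' @param inner_frac inner radius of the hollow core as a fraction of
#'   `radius`.
#' @param lattice_spacing,lattice_width junction lattice geometry, px.
#' @param ring_width laminin ring width, px.
#' @param noise_sd per-pixel camera noise fraction.
#' @param seed RNG seed.
#' @return list with `image` (2-channel `FrameStack`, channels "junction",
#'   "laminin") and `truth` (geometry and parameters).
#' @export
generate_section_image <- function(hollow = FALSE, laminin_level = 1,
                                   image_shape = c(256, 256), radius = 80,
                                   inner_frac = 0.75, lattice_spacing = 10,
                                   lattice_width = 1.5, ring_width = 4,
                                   noise_sd = 0, seed = 1) {
  check_scalar(laminin_level, "laminin_level", 0)
  with_seed(seed, {
    g <- pixel_grid(image_shape)
    yc <- (image_shape[1] + 1) / 2; xc <- (image_shape[2] + 1) / 2
    r <- sqrt((g$y - yc)^2 + (g$x - xc)^2)
    disk <- r <= radius
    core <- r <= inner_frac * radius
    lat <- (abs((g$y - yc) %% lattice_spacing) < lattice_width) |
           (abs((g$x - xc) %% lattice_spacing) < lattice_width)
    jct_mask <- disk & lat & (!hollow | !core)
    junction <- matrix(0.02, image_shape[1], image_shape[2])
    junction[jct_mask] <- 1
    ring <- abs(r - radius) <= ring_width / 2
    laminin <- matrix(0, image_shape[1], image_shape[2])
    laminin[ring] <- laminin_level
    data <- array(0, c(1, 1, 2, image_shape[1], image_shape[2]))
    data[1, 1, 1, , ] <- add_camera_noise(junction, noise_sd, 0)
    data[1, 1, 2, , ] <- add_camera_noise(laminin, noise_sd, 0)
    img <- frame_stack(data, channel_names = c("junction", "laminin"))
    list(image = img,
         truth = list(hollow = hollow, laminin_level = laminin_level,
                      radius = radius, inner_frac = inner_frac,
                      center = c(yc, xc)))
  })
}
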