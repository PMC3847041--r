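# Synthetic junction disassembly: a pre-established junction whose intensity
# is constant until a chelation event (plus an optional onset lag) and then
# decays exponentially to a plateau. The rendered movie carries per-pixel
# camera noise; the junction-mean trace therefore has noise reduced by the
# junction pixel count, as in the real assay.

#' Parameters of a synthetic junction disassembly movie
#'
#' The noiseless junction intensity follows
#' `I(t) = 1` for `t <= event_time + lag_true`, then
#' `plateau + (1 - plateau) exp(-(t - event - lag)/tau_true)`.
#'
#' @param tau_true decay time constant, min (> 0).
#' @param lag_true onset delay after the event, min (>= 0).
#' @param event_time chelator addition time, min (default 15, the baseline
#'   recording length).
#' @param plateau_fraction asymptotic intensity fraction in [0, 1].
#' @param frame_interval min between frames (5, the disassembly acquisition).
#' @param duration movie length, min.
#' @param image_shape (Y, X) pixels.
#' @param noise_sd per-pixel camera noise fraction.
#' @param membrane_intensity,background dim structures of the scene.
#' @param seed RNG seed.
#' @return a `DisassemblyParams` list.
#' @export
disassembly_params <- function(tau_true = 2.63, lag_true = 0,
                               event_time = 15, plateau_fraction = 0.9,
                               frame_interval = 5, duration = 75,
                               image_shape = c(64, 64), noise_sd = 0.02,
                               membrane_intensity = 0.12, background = 0,
                               seed = 1) {
  check_scalar(tau_true, "tau_true", 0, lower_open = TRUE)
  check_scalar(lag_true, "lag_true", 0)
  check_scalar(plateau_fraction, "plateau_fraction", 0, 1)
  check_scalar(noise_sd, "noise_sd", 0)
  if (event_time < 0 || event_time >= duration)
    stop("event_time must lie inside the movie")
  structure(list(tau_true = tau_true, lag_true = lag_true,
                 event_time = event_time,
                 plateau_fraction = plateau_fraction,
                 frame_interval = frame_interval, duration = duration,
                 image_shape = as.integer(image_shape), noise_sd = noise_sd,
                 membrane_intensity = membrane_intensity,
                 background = background, seed = seed),
            class = "DisassemblyParams")
}

# closed-form noiseless junction intensity at time t (absolute units of the
# junction channel, background included)
disassembly_intensity <- function(params, t) {
  t0 <- params$event_time + params$lag_true
  p <- params$plateau_fraction
  rel <- ifelse(t <= t0, 1, p + (1 - p) * exp(-(t - t0) / params$tau_true))
  params$background + rel
}

#' Generate a synthetic junction disassembly movie
#'
#' Renders two dim cells with one bright pre-established junction whose
#' intensity follows the closed-form decay of [disassembly_params()]; every
#' pixel carries camera noise. The truth includes the closed-form intensity
#' function so noiseless traces can be checked analytically.
#'
#' @param params a [disassembly_params()] object.
#' @return list with `movie` (single-channel `FrameStack`), and `truth`:
#'   `times`, `junction_mask`, `intensity(t)` closed form, `params`.
#' @export
generate_disassembly_movie <- function(params) {
  stopifnot(inherits(params, "DisassemblyParams"))
  with_seed(params$seed, {
    shape <- params$image_shape
    times <- seq(0, params$duration, by = params$frame_interval)
    nt <- length(times)
    lay <- scene_layout(shape)
    jm <- roi_mask(lay$junction, shape)
    base <- matrix(params$background, shape[1], shape[2])
    base[roi_mask(lay$cell1, shape)] <- params$membrane_intensity
    base[roi_mask(lay$cell2, shape)] <- params$membrane_intensity
    data <- array(0, c(nt, 1, 1, shape[1], shape[2]))
    for (f in seq_len(nt)) {
      img <- base
      img[jm] <- disassembly_intensity(params, times[f])
      data[f, 1, 1, , ] <- add_camera_noise(img, params$noise_sd, 0)
    }
    movie <- frame_stack(data, frame_interval = params$frame_interval,
                         channel_names = "junction")
    list(movie = movie,
         truth = list(times = times, junction_mask = jm,
                      intensity = function(t) disassembly_intensity(params, t),
                      params = params))
  })
}

#' Measured junction-mean disassembly trace of a synthetic movie
#'
#' Convenience wrapper: renders the movie, projects it and measures the
#' junction-mean intensity trace over the true junction mask.
#'
#' @param params a [disassembly_params()] object.
#' @return an `IntensityTrace` with `event_time` set.
#' @export
generate_disassembly_trace <- function(params) {
  gen <- generate_disassembly_movie(params)
  proj <- aperm(gen$movie$data[, 1, 1, , , drop = FALSE][, 1, 1, , ],
                c(2, 3, 1))
  junction_intensity_trace(gen$truth$junction_mask, proj, gen$truth$times,
                           event_time = params$event_time)
}
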