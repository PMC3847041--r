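# Synthetic junction assembly movies: a field of stationary membrane-labelled
# cells on a jittered grid whose interfaces light up as junctions are born
# from an inhomogeneous Poisson process (flat baseline, then linear growth of
# the expected observed count at rate_true). A separate nuclei channel
# provides the watershed marker. Ground truth carries birth times and
# per-frame presence masks.

#' Parameters of a synthetic junction assembly movie
#'
#' Birth times are drawn from a Poisson process with cumulative intensity
#' `rate_true / presence_fraction * max(0, t - baseline_min)`, so that the
#' presence-thinned \emph{observed} junction count grows at `rate_true`
#' junctions/min after the baseline. Each born junction is present in a given
#' later frame with probability `presence_fraction` (always present at its
#' birth frame).
#'
#' @param rate_true expected slope of the observed junction count,
#'   junctions/min.
#' @param n_cells number of cells; laid out on a jittered square grid.
#' @param baseline_min flat baseline before the first junctions, min.
#' @param frame_interval min between frames (2, the assembly acquisition).
#' @param duration movie length, min.
#' @param presence_fraction per-frame presence probability of a born
#'   junction.
#' @param image_shape (Y, X) pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_z number of z planes (rendered planes are optically identical up
#'   to noise; 2 is the minimum the central projection uses).
#' @param noise_sd per-pixel camera noise fraction.
#' @param junction_intensity,membrane_intensity,background intensity levels
#'   of the junction channel.
#' @param seed RNG seed.
#' @return an `AssemblyParams` list.
#' @export
assembly_params <- function(rate_true = 0.203, n_cells = 25,
                            baseline_min = 30, frame_interval = 2,
                            duration = 120, presence_fraction = 0.82,
                            image_shape = c(128, 128), pixel_size = 0.66,
                            n_z = 2, noise_sd = 0.02,
                            junction_intensity = 1,
                            membrane_intensity = 0.12, background = 0.02,
                            seed = 1) {
  check_scalar(rate_true, "rate_true", 0)
  check_scalar(presence_fraction, "presence_fraction", 0, 1)
  check_scalar(baseline_min, "baseline_min", 0)
  if (duration <= baseline_min)
    stop("duration must exceed baseline_min")
  if (n_cells < 4) stop("need at least 4 cells")
  structure(list(rate_true = rate_true, n_cells = as.integer(n_cells),
                 baseline_min = baseline_min, frame_interval = frame_interval,
                 duration = duration, presence_fraction = presence_fraction,
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, n_z = as.integer(n_z),
                 noise_sd = noise_sd,
                 junction_intensity = junction_intensity,
                 membrane_intensity = membrane_intensity,
                 background = background, seed = seed),
            class = "AssemblyParams")
}

# jittered-grid cell layout; eligible junction pairs are rook-adjacent cells
assembly_layout <- function(params) {
  side <- ceiling(sqrt(params$n_cells))
  ny <- params$image_shape[1]; nx <- params$image_shape[2]
  sp_y <- ny / side; sp_x <- nx / side
  ids <- seq_len(params$n_cells)
  gy <- (ids - 1) %/% side; gx <- (ids - 1) %% side
  cy <- (gy + 0.5) * sp_y + runif(params$n_cells, -2, 2)
  cx <- (gx + 0.5) * sp_x + runif(params$n_cells, -2, 2)
  pairs <- NULL
  for (i in ids) for (j in ids) {
    if (j <= i) next
    if ((gy[j] == gy[i] && abs(gx[j] - gx[i]) == 1) ||
        (gx[j] == gx[i] && abs(gy[j] - gy[i]) == 1))
      pairs <- rbind(pairs, c(i, j))
  }
  list(cy = cy, cx = cx, pairs = pairs, spacing = min(sp_y, sp_x))
}

# pixel index sets: per-cell membrane rings and per-pair junction segments
assembly_pixel_sets <- function(lay, shape) {
  g <- pixel_grid(shape)
  n <- length(lay$cy)
  D <- matrix(0, prod(shape), n)
  for (i in seq_len(n))
    D[, i] <- sqrt((c(g$y) - lay$cy[i])^2 + (c(g$x) - lay$cx[i])^2)
  r_cell <- 0.42 * lay$spacing
  membrane <- which(matrixMinAbs(D - r_cell) <= 1)
  jct <- vector("list", nrow(lay$pairs))
  half_len <- 0.30 * lay$spacing
  for (p in seq_len(nrow(lay$pairs))) {
    i <- lay$pairs[p, 1]; j <- lay$pairs[p, 2]
    my <- (lay$cy[i] + lay$cy[j]) / 2; mx <- (lay$cx[i] + lay$cx[j]) / 2
    dmid <- sqrt((c(g$y) - my)^2 + (c(g$x) - mx)^2)
    jct[[p]] <- which(abs(D[, i] - D[, j]) <= 2 & dmid <= half_len)
  }
  list(membrane = membrane, junction = jct)
}

# row-wise min of |M| (helper; keeps assembly_pixel_sets readable)
matrixMinAbs <- function(M) {
  out <- abs(M[, 1])
  for (i in seq_len(ncol(M))[-1]) out <- pmin(out, abs(M[, i]))
  out
}

#' Generate a synthetic junction assembly movie
#'
#' @param params an [assembly_params()] object.
#' @return list with `movie` (a 2-channel `FrameStack`, channels "junction"
#'   and "nuclei") and `truth`: data frame of junctions (pair ids, birth
#'   time/frame), a presence matrix (junction x frame), per-pair junction
#'   pixel index sets, cell center coordinates, and the expected observed
#'   count curve.
#' @export
generate_assembly_movie <- function(params) {
  stopifnot(inherits(params, "AssemblyParams"))
  with_seed(params$seed, {
    shape <- params$image_shape
    times <- seq(0, params$duration, by = params$frame_interval)
    nt <- length(times)
    lay <- assembly_layout(params)
    px <- assembly_pixel_sets(lay, shape)
    # junction birth process
    pf <- max(params$presence_fraction, 1e-9)
    lam <- params$rate_true / pf * (params$duration - params$baseline_min)
    n_births <- if (params$rate_true == 0) 0L else rpois(1, lam)
    n_pairs <- nrow(lay$pairs)
    if (n_births > n_pairs) n_births <- n_pairs   # pairs exhausted: truncate
    birth_t <- sort(params$baseline_min +
                      runif(n_births) * (params$duration - params$baseline_min))
    pair_idx <- sample.int(n_pairs, n_births)
    birth_frame <- findInterval(birth_t, times + 1e-9) + 1L
    birth_frame[birth_frame > nt] <- nt
    presence <- matrix(FALSE, n_births, nt)
    for (k in seq_len(n_births)) {
      f0 <- birth_frame[k]
      presence[k, f0] <- TRUE
      if (f0 < nt)
        presence[k, (f0 + 1):nt] <- runif(nt - f0) < params$presence_fraction
    }
    # nuclei template
    g <- pixel_grid(shape)
    nuc0 <- matrix(0, shape[1], shape[2])
    for (i in seq_len(params$n_cells))
      nuc0 <- nuc0 + exp(-((g$y - lay$cy[i])^2 + (g$x - lay$cx[i])^2) /
                           (2 * 5^2))
    # junction-channel template without junctions
    base0 <- matrix(params$background, shape[1], shape[2])
    base0[px$membrane] <- params$membrane_intensity
    data <- array(0, c(nt, params$n_z, 2L, shape[1], shape[2]))
    for (f in seq_len(nt)) {
      jframe <- base0
      on <- which(presence[, f])
      for (k in on)
        jframe[px$junction[[pair_idx[k]]]] <- params$junction_intensity
      for (z in seq_len(params$n_z)) {
        data[f, z, 1, , ] <- add_camera_noise(jframe, params$noise_sd, 0.002)
        data[f, z, 2, , ] <- add_camera_noise(nuc0, params$noise_sd, 0.002)
      }
    }
    movie <- frame_stack(data, frame_interval = params$frame_interval,
                         pixel_size = params$pixel_size,
                         channel_names = c("junction", "nuclei"))
    junctions <- if (n_births) data.frame(
      cell_i = lay$pairs[pair_idx, 1], cell_j = lay$pairs[pair_idx, 2],
      birth_time = birth_t, birth_frame = birth_frame) else
      data.frame(cell_i = integer(), cell_j = integer(),
                 birth_time = numeric(), birth_frame = integer())
    expected_count <- params$rate_true * pmax(0, times - params$baseline_min)
    list(movie = movie,
         truth = list(params = params, times = times, junctions = junctions,
                      presence = presence,
                      junction_pixels = px$junction[pair_idx],
                      centers = data.frame(cell_id = seq_len(params$n_cells),
                                           y = lay$cy, x = lay$cx),
                      expected_count = expected_count))
  })
}

#' Generate synthetic junction presence tracks (no rendering)
#'
#' Draws per-frame presence indicators for `n_junctions` junctions directly,
#' each present with probability `presence_fraction` per frame after a birth
#' frame, and wraps them as `JunctionTrack` objects via the same presence
#' rule as the tracker (pixel count >= min_area). Used to validate the
#' lifetime statistic without the imaging chain.
#'
#' @param params an [assembly_params()] object.
#' @param n_junctions number of tracks to draw.
#' @param n_pixels pixel count given to present frames (>= min_area).
#' @param min_area presence threshold in pixels.
#' @return list of `JunctionTrack` objects, with frame `times` attribute.
#' @export
generate_junction_tracks <- function(params, n_junctions = 50, n_pixels = 25,
                                     min_area = 5) {
  stopifnot(inherits(params, "AssemblyParams"))
  with_seed(params$seed, {
    times <- seq(0, params$duration, by = params$frame_interval)
    nt <- length(times)
    tracks <- lapply(seq_len(n_junctions), function(k) {
      f0 <- sample.int(max(findInterval(params$baseline_min, times), 1L), 1)
      npx <- integer(nt)
      npx[f0] <- n_pixels
      if (f0 < nt)
        npx[(f0 + 1):nt] <-
          ifelse(runif(nt - f0) < params$presence_fraction, n_pixels, 0L)
      new_junction_track(pair_key(2L * k - 1L, 2L * k),
                         cells = c(2L * k - 1L, 2L * k),
                         n_pixels = npx,
                         pixels = lapply(npx, function(n) seq_len(n)),
                         min_area = min_area)
    })
    attr(tracks, "times") <- times
    tracks
  })
}
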