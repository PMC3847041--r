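# Junction detection and tracking with identity preservation.
#
# A junction is the set of suprathreshold pixels whose two closest cell
# centers form a given unordered pair. Cell identities come from a watershed
# computed on the (x, y, t) volume, so a cell -- and therefore every junction
# it participates in -- keeps one id across the movie even when the junction
# is discontinuous in space or time.

#' Encode an unordered cell pair as a single numeric key
#' @param i,j cell ids (positive integers, any order).
#' @export
pair_key <- function(i, j) pmin(i, j) * 1e5 + pmax(i, j)

#' Decode a pair key into its two cell ids
#' @param key numeric key from [pair_key()].
#' @return 2-column matrix (cell_i, cell_j).
#' @export
pair_cells <- function(key) {
  i <- key %/% 1e5
  cbind(cell_i = i, cell_j = key - i * 1e5)
}

#' Central maximum-intensity projection of a z-stack movie
#'
#' Per frame, the pixelwise maximum of the two planes nearest the stack
#' center (for Z = 6 these are planes 3 and 4).
#'
#' @param stack a `FrameStack`.
#' @param channel channel name or index (default 1).
#' @return numeric array Y x X x T.
#' @export
central_projection <- function(stack, channel = 1) {
  stopifnot(inherits(stack, "FrameStack"))
  if (is.character(channel)) channel <- match(channel, stack$channel_names)
  d <- dim(stack$data)
  nz <- d[2]
  if (nz == 1) {
    warning("single z plane: projection is a pass-through")
    lo <- hi <- 1L
  } else {
    lo <- floor(nz / 2); hi <- lo + 1L
  }
  out <- array(0, c(d[4], d[5], d[1]))
  for (f in seq_len(d[1]))
    out[, , f] <- pmax(stack$data[f, lo, channel, , ],
                       stack$data[f, hi, channel, , ])
  out
}

#' Otsu threshold mask with small-object removal
#'
#' Thresholds the image at the Otsu level (maximal between-class variance)
#' and removes connected components smaller than `min_area` pixels. When a
#' frame belongs to a movie, pass a movie-level threshold (see
#' [movie_otsu()]): a frame that does not yet contain the bright structure
#' class has no junction mode in its histogram, and a per-frame Otsu level
#' would then fall between background and dim membrane instead.
#'
#' @param image 2-D numeric matrix.
#' @param min_area minimum component size in pixels (default 5).
#' @param threshold optional absolute threshold overriding the per-frame
#'   Otsu level.
#' @return logical mask.
#' @export
threshold_mask <- function(image, min_area = 5, threshold = NULL) {
  rng <- range(image)
  if (diff(rng) == 0) stop("no contrast: constant image")
  if (is.null(threshold)) {
    norm <- (image - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > th
  } else {
    mask <- image > threshold
  }
  if (min_area > 1 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Movie-level Otsu threshold
#'
#' Otsu level computed on the pooled intensity histogram of a whole movie,
#' so that frames acquired before any junction exists are thresholded on the
#' same absolute scale as later frames.
#'
#' @param arr 3-D array Y x X x T.
#' @return absolute threshold value.
#' @export
movie_otsu <- function(arr) {
  rng <- range(arr)
  if (diff(rng) == 0) stop("no contrast: constant movie")
  norm <- matrix(as.numeric(arr - rng[1]) / diff(rng), ncol = 1)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Segment and track cells through a movie by watershed in (x, y, t)
#'
#' The marker channel (typically nuclei) is smoothed, thresholded (Otsu on
#' the pooled movie histogram) and distance-transformed, and a watershed is
#' computed on every frame; basins are then connected through the time axis
#' by mutual-best pixel overlap between consecutive frames, so each
#' (x, y, t)-connected basin -- one cell -- keeps a single label for the
#' whole series. When two cells merge, the larger-overlap basin carries the
#' identity on and the other identity ends (downstream, junctions of such
#' pairs are flagged and excluded).
#'
#' @param marker 3-D numeric array Y x X x T (e.g. from
#'   [central_projection()] of the nuclei channel).
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @param tolerance,ext watershed parameters (see [EBImage::watershed()]).
#' @return a `CellCenters` object: data frame (frame, cell_id, y, x) with the
#'   relabelled (persistent-id) volume in `attr(, "labels")`.
#' @export
segment_cells_xyt <- function(marker, sigma = 2, tolerance = 1, ext = 1) {
  stopifnot(length(dim(marker)) == 3)
  if (diff(range(marker)) == 0) stop("no cells: constant marker volume")
  sm <- EBImage::gblur(marker, sigma = sigma)
  rng <- range(sm)
  if (diff(rng) == 0) stop("no cells: constant marker volume")
  smn <- (sm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(as.numeric(smn), ncol = 1)),
                      range = c(0, 1))
  mask <- smn > th
  if (!any(mask)) stop("no cells: empty marker mask")
  D <- EBImage::distmap(mask)                 # per-frame 2-D distance
  ws <- as.array(EBImage::watershed(D, tolerance = tolerance, ext = ext))
  ws <- ws * mask
  if (max(ws) == 0) stop("no cells: watershed produced no basins")
  nt <- dim(marker)[3]
  # union-find over (frame, per-frame label) nodes, linked by mutual-best
  # pixel overlap between consecutive frames: (x, y, t) basin connectivity
  maxlab <- max(ws)
  node <- function(f, l) (f - 1L) * maxlab + l
  parent <- seq_len(nt * maxlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (f in seq_len(nt - 1L)) {
    a <- ws[, , f]; b <- ws[, , f + 1L]
    both <- a > 0 & b > 0
    if (!any(both)) next
    key <- (a[both] - 1) * maxlab + b[both]
    tab <- table(key)
    kv <- as.numeric(names(tab)); ov <- as.integer(tab)
    ai <- (kv - 1) %/% maxlab + 1; bi <- (kv - 1) %% maxlab + 1
    # mutual best match
    best_for_a <- tapply(seq_along(kv), ai, function(ii) ii[which.max(ov[ii])])
    best_for_b <- tapply(seq_along(kv), bi, function(ii) ii[which.max(ov[ii])])
    links <- intersect(unlist(best_for_a), unlist(best_for_b))
    for (ii in links) {
      ra <- find(node(f, ai[ii])); rb <- find(node(f + 1L, bi[ii]))
      if (ra != rb) parent[rb] <- ra
    }
  }
  # persistent ids in order of first appearance
  id_map <- new.env(parent = emptyenv())
  next_id <- 0L
  rows <- vector("list", nt)
  g <- pixel_grid(dim(marker)[1:2])
  labels <- array(0L, dim(ws))
  for (f in seq_len(nt)) {
    lab <- ws[, , f]
    idx <- which(lab > 0)
    if (!length(idx)) next
    locals <- sort(unique(lab[idx]))
    pids <- vapply(locals, function(l) {
      r <- as.character(find(node(f, l)))
      if (is.null(id_map[[r]])) {
        next_id <<- next_id + 1L
        id_map[[r]] <- next_id
      }
      id_map[[r]]
    }, integer(1))
    relab <- integer(maxlab)
    relab[locals] <- pids
    labels[, , f][idx] <- relab[lab[idx]]
    ids <- relab[lab[idx]]
    ord <- order(unique(ids))
    rows[[f]] <- data.frame(
      frame = f,
      cell_id = as.integer(sort(unique(ids))),
      y = as.numeric(tapply(g$y[idx], ids, mean)),
      x = as.numeric(tapply(g$x[idx], ids, mean)))
  }
  centers <- do.call(rbind, rows)
  structure(centers, labels = labels, class = c("CellCenters", "data.frame"))
}

#' Two-closest-neighbor pair map
#'
#' For every pixel, the unordered pair of the two cell centers nearest to it
#' (Euclidean distance), encoded with [pair_key()]. Ties are broken towards
#' ascending cell id.
#'
#' @param centers a `CellCenters` data frame (frame, cell_id, y, x).
#' @param shape image shape (Y, X).
#' @param frames frames to compute (default all in `centers`).
#' @return list (per frame) of numeric Y x X pair-key matrices.
#' @export
two_closest_neighbor_map <- function(centers, shape, frames = NULL) {
  frames <- frames %||% sort(unique(centers$frame))
  lapply(frames, function(f) {
    cf <- centers[centers$frame == f, , drop = FALSE]
    cf <- cf[order(cf$cell_id), , drop = FALSE]
    if (nrow(cf) < 2) stop("insufficient cells: need >= 2 centers in frame ", f)
    k <- two_closest_kernel(cf$y, cf$x, shape[1], shape[2])
    id1 <- cf$cell_id[k$i1]; id2 <- cf$cell_id[k$i2]
    matrix(pair_key(id1, id2), shape[1], shape[2])
  })
}

#' Mask of pixels within a maximum distance of any cell center
#'
#' @param centers a `CellCenters` data frame.
#' @param shape image shape (Y, X).
#' @param max_dist maximum distance to the nearest center, micrometers.
#' @param pixel_size micrometers per pixel (default 1 = `max_dist` in px).
#' @param frames frames to compute (default all).
#' @return list (per frame) of logical masks.
#' @export
distance_mask <- function(centers, shape, max_dist = 30, pixel_size = 1,
                          frames = NULL) {
  check_scalar(max_dist, "max_dist", 0, lower_open = TRUE)
  frames <- frames %||% sort(unique(centers$frame))
  max_px <- max_dist / pixel_size
  lapply(frames, function(f) {
    cf <- centers[centers$frame == f, , drop = FALSE]
    k <- two_closest_kernel(cf$y, cf$x, shape[1], shape[2])
    matrix(k$d1 <= max_px, shape[1], shape[2])
  })
}

new_junction_track <- function(key, cells, n_pixels, pixels, min_area,
                               excluded = FALSE, reason = NA_character_) {
  presence <- n_pixels >= min_area
  structure(list(junction_id = key, cells = cells,
                 presence = presence, n_pixels = n_pixels, pixels = pixels,
                 birth_frame = if (any(presence)) which(presence)[1] else NA,
                 excluded = excluded, reason = reason),
            class = "JunctionTrack")
}

#' @export
print.JunctionTrack <- function(x, ...) {
  cat(sprintf(
    "JunctionTrack %d-%d: present %d/%d frames, birth frame %s%s\n",
    x$cells[1], x$cells[2], sum(x$presence), length(x$presence),
    as.character(x$birth_frame),
    if (x$excluded) paste0(" [excluded: ", x$reason, "]") else ""))
  invisible(x)
}

#' Extract junction tracks from per-frame masks and pair maps
#'
#' Per frame, the pixels of junction `p` are
#' `threshold_mask & distance_mask & (pair_map == p)`; the junction is
#' present when its pixel count reaches `min_area`. Identity is the pair key
#' itself, so gaps in space or time never split a track. Tracks touching the
#' image border, and (when `centers` is given) pairs whose cells approach
#' within `merge_dist` pixels or whose cells drop out of the segmentation,
#' are flagged `excluded` -- the automated counterpart of manual curation of
#' incomplete or merged segmentations.
#'
#' @param threshold_masks,pair_maps,dist_masks per-frame lists of equal
#'   length and shape (see [threshold_mask()], [two_closest_neighbor_map()],
#'   [distance_mask()]).
#' @param min_area presence threshold in pixels (default 5).
#' @param centers optional `CellCenters` for the merge heuristic.
#' @param exclude_border flag tracks with pixels on the image border.
#' @param merge_dist center distance (px) below which a pair is considered
#'   merged.
#' @return list of `JunctionTrack` objects.
#' @export
extract_junctions <- function(threshold_masks, pair_maps, dist_masks,
                              min_area = 5, centers = NULL,
                              exclude_border = TRUE, merge_dist = 5) {
  nt <- length(threshold_masks)
  stopifnot(length(pair_maps) == nt, length(dist_masks) == nt)
  shape <- dim(threshold_masks[[1]])
  per_key <- new.env(parent = emptyenv())
  for (f in seq_len(nt)) {
    elig <- threshold_masks[[f]] & dist_masks[[f]]
    idx <- which(elig)
    if (!length(idx)) next
    keys <- pair_maps[[f]][idx]
    for (grp in split(idx, keys)) {
      key <- as.character(pair_maps[[f]][grp[1]])
      rec <- per_key[[key]] %||% list(n = integer(nt), px = vector("list", nt))
      rec$n[f] <- length(grp)
      rec$px[[f]] <- grp
      per_key[[key]] <- rec
    }
  }
  keys <- as.numeric(ls(per_key))
  keys <- keys[order(keys)]
  tracks <- list()
  for (key in keys) {
    rec <- per_key[[as.character(key)]]
    if (!any(rec$n >= min_area)) next
    cells <- pair_cells(key)
    excluded <- FALSE; reason <- NA_character_
    if (exclude_border) {
      allpx <- unlist(rec$px)
      ry <- (allpx - 1) %% shape[1] + 1
      rx <- (allpx - 1) %/% shape[1] + 1
      if (any(ry == 1 | ry == shape[1] | rx == 1 | rx == shape[2])) {
        excluded <- TRUE; reason <- "touches image border"
      }
    }
    if (!excluded && !is.null(centers)) {
      ci <- centers[centers$cell_id == cells[1], ]
      cj <- centers[centers$cell_id == cells[2], ]
      common <- intersect(ci$frame, cj$frame)
      if (length(common) < nt) {
        excluded <- TRUE; reason <- "cell identity lost in some frames"
      } else {
        dd <- sqrt((ci$y[match(common, ci$frame)] -
                      cj$y[match(common, cj$frame)])^2 +
                   (ci$x[match(common, ci$frame)] -
                      cj$x[match(common, cj$frame)])^2)
        if (any(dd < merge_dist)) {
          excluded <- TRUE; reason <- "cell basins merged"
        }
      }
    }
    tracks[[length(tracks) + 1L]] <-
      new_junction_track(key, c(cells[1], cells[2]), rec$n, rec$px,
                         min_area, excluded, reason)
  }
  tracks
}

#' Run the full junction detection and tracking pipeline on a movie
#'
#' Convenience chain: central projection of the junction and marker
#' channels, movie-level Otsu threshold masks, (x, y, t) watershed cell
#' segmentation, two-closest-neighbor pair maps, distance masking, and
#' junction extraction.
#'
#' @param movie a `FrameStack` with a junction channel and a nuclei (marker)
#'   channel.
#' @param junction_channel,marker_channel channel names or indices.
#' @param max_dist distance-mask radius, micrometers.
#' @param min_area junction presence threshold, px.
#' @return list with `tracks`, `centers`, `times`, and the intermediate
#'   per-frame `masks`.
#' @export
track_junctions <- function(movie, junction_channel = "junction",
                            marker_channel = "nuclei", max_dist = 30,
                            min_area = 5) {
  stopifnot(inherits(movie, "FrameStack"))
  proj_j <- central_projection(movie, junction_channel)
  proj_n <- central_projection(movie, marker_channel)
  shape <- dim(proj_j)[1:2]
  nt <- dim(proj_j)[3]
  th <- movie_otsu(proj_j)
  masks <- lapply(seq_len(nt), function(f)
    threshold_mask(proj_j[, , f], min_area = min_area, threshold = th))
  centers <- segment_cells_xyt(proj_n)
  pmaps <- two_closest_neighbor_map(centers, shape)
  dmasks <- distance_mask(centers, shape, max_dist = max_dist,
                          pixel_size = movie$pixel_size)
  tracks <- extract_junctions(masks, pmaps, dmasks, min_area = min_area,
                              centers = centers)
  list(tracks = tracks, centers = centers, times = frame_times(movie),
       masks = masks)
}

#' Junction count per frame (assembly curve)
#'
#' @param tracks list of `JunctionTrack`s from one field of view.
#' @param times frame times, min.
#' @param include_excluded count flagged tracks too (default FALSE).
#' @return an `IntensityTrace` of junction counts over time.
#' @export
assembly_curve <- function(tracks, times, include_excluded = FALSE) {
  nt <- length(times)
  counts <- integer(nt)
  for (tr in tracks) {
    if (tr$excluded && !include_excluded) next
    counts <- counts + as.integer(tr$presence[seq_len(nt)])
  }
  intensity_trace(times, counts)
}

#' Junction lifetime within an observation window
#'
#' Percentage of frames inside `[window_start, window_end]` in which the
#' track is present.
#'
#' @param track a `JunctionTrack`.
#' @param times frame times, min.
#' @param window_start,window_end window bounds, min (the published summary
#'   window is 60 to 120 min).
#' @return lifetime in percent.
#' @export
junction_lifetime <- function(track, times, window_start = 60,
                              window_end = 120) {
  sel <- times >= window_start & times <= window_end
  if (!any(sel)) stop("empty lifetime window")
  first_birth <- if (is.na(track$birth_frame)) Inf else times[track$birth_frame]
  if (first_birth > window_end)
    stop("track born after the lifetime window")
  100 * mean(track$presence[sel])
}

#' Mean junction intensity over time
#'
#' Per frame, the mean image intensity over the track's pixels. Frames in
#' which the junction is absent use the most recent known pixel set
#' (holdover rule; frames before the first appearance use the first known
#' set), so disassembling junctions keep a defined trace.
#'
#' @param track a `JunctionTrack`, or a logical mask / pixel index vector
#'   defining a fixed pixel set.
#' @param images 3-D array Y x X x T (e.g. [central_projection()] output).
#' @param times frame times, min.
#' @param event_time optional event time stored on the trace.
#' @return an `IntensityTrace`.
#' @export
junction_intensity_trace <- function(track, images, times,
                                     event_time = NULL) {
  nt <- dim(images)[3]
  npix <- prod(dim(images)[1:2])
  if (inherits(track, "JunctionTrack")) {
    have <- which(track$n_pixels > 0)
    if (!length(have)) stop("track has no pixels in any frame")
    vals <- numeric(nt)
    cur <- track$pixels[[have[1]]]
    for (f in seq_len(nt)) {
      if (f <= length(track$n_pixels) && track$n_pixels[f] > 0)
        cur <- track$pixels[[f]]
      vals[f] <- mean(images[cur + (f - 1) * npix])
    }
  } else {
    idx <- if (is.logical(track)) which(track) else as.integer(track)
    if (!length(idx)) stop("empty pixel set")
    vals <- vapply(seq_len(nt),
                   function(f) mean(images[idx + (f - 1) * npix]),
                   numeric(1))
  }
  intensity_trace(times, vals, event_time)
}
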