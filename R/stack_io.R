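# Stack and table I/O.
#
# On-disk dialect: multi-page TIFF (32-bit float pages, page order T-major,
# then Z, then C) accompanied by a YAML sidecar ("<file>.yaml") that records
# the axis sizes and physical metadata. Plain TIFFs without a sidecar are
# accepted when the metadata is supplied through `config`.
#
# Conventions fixed for reproducibility: pixel coordinates are 1-based
# (row, column) as everywhere in R; time is minutes from acquisition start
# unless a function documents hours.

#' Construct a multichannel time-lapse stack
#'
#' @param data 5-D numeric array ordered T x Z x C x Y x X. Lower-dimensional
#'   arrays are promoted by prepending singleton axes (a 2-D image becomes
#'   T = Z = C = 1).
#' @param frame_interval time between frames, minutes.
#' @param pixel_size pixel size, micrometers.
#' @param channel_names character vector of length C.
#' @return a `FrameStack` object.
#' @export
frame_stack <- function(data, frame_interval = 1, pixel_size = 1,
                        channel_names = NULL) {
  nd <- length(dim(data) %||% stop("'data' must be an array"))
  if (nd < 2 || nd > 5) stop("'data' must have 2 to 5 dimensions")
  while (length(dim(data)) < 5)
    dim(data) <- c(1L, dim(data))
  check_scalar(frame_interval, "frame_interval", lower = 0, lower_open = TRUE)
  check_scalar(pixel_size, "pixel_size", lower = 0, lower_open = TRUE)
  nc <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length must equal the channel axis")
  structure(list(data = data, frame_interval = frame_interval,
                 pixel_size = pixel_size, channel_names = channel_names),
            class = "FrameStack")
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "FrameStack: T=%d Z=%d C=%d Y=%d X=%d  dt=%g min  px=%g um  [%s]\n",
    d[1], d[2], d[3], d[4], d[5], x$frame_interval, x$pixel_size,
    paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Frame acquisition times of a stack, minutes
#' @param x a `FrameStack`.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "FrameStack"))
  (seq_len(dim(x$data)[1]) - 1) * x$frame_interval
}

#' Construct a spectral (lambda-mode) stack
#'
#' @param data 3-D numeric array Y x X x B of per-band emission intensities.
#' @param band_centers detection band centers in nm, strictly increasing,
#'   length B (at least 3).
#' @return a `SpectralStack` object.
#' @export
spectral_stack <- function(data, band_centers) {
  if (length(dim(data)) != 3) stop("'data' must be a Y x X x B array")
  b <- dim(data)[3]
  if (b < 3) stop("a spectral stack needs at least 3 bands")
  if (length(band_centers) != b)
    stop("band_centers length must equal the band axis")
  if (any(diff(band_centers) <= 0))
    stop("band_centers must be strictly increasing")
  structure(list(data = data, band_centers = as.numeric(band_centers)),
            class = "SpectralStack")
}

#' @export
print.SpectralStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("SpectralStack: %d x %d px, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a stack to disk
#'
#' Writes a multi-page 32-bit float TIFF plus a YAML metadata sidecar.
#' Page order for a `FrameStack` is T-major, then Z, then C.
#'
#' @param x a `FrameStack` or `SpectralStack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "FrameStack")) {
    d <- dim(x$data)
    pages <- vector("list", d[1] * d[2] * d[3])
    i <- 1L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
      pages[[i]] <- x$data[t, z, ch, , ]
      i <- i + 1L
    }
    meta <- list(kind = "frame_stack", axes = "TZCYX",
                 sizes = as.integer(d),
                 frame_interval = x$frame_interval,
                 pixel_size = x$pixel_size,
                 channel_names = as.list(x$channel_names))
  } else if (inherits(x, "SpectralStack")) {
    d <- dim(x$data)
    pages <- lapply(seq_len(d[3]), function(b) x$data[, , b])
    meta <- list(kind = "spectral_stack", axes = "YXB",
                 sizes = as.integer(d),
                 band_centers = as.numeric(x$band_centers))
  } else stop("unsupported stack type")
  # TIFF pages are stored normalized to [0, 1] (the writer's contract); the
  # physical range goes into the sidecar and is restored on read
  vmin <- min(vapply(pages, min, numeric(1)))
  vmax <- max(vapply(pages, max, numeric(1)))
  scale <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(pages, function(p) (p - vmin) / scale)
  meta$value_min <- vmin
  meta$value_scale <- scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a stack from disk
#'
#' Reads a (multi-page) TIFF and reconstructs the declared axis order from
#' its YAML sidecar. Without a sidecar, a single-page TIFF is promoted to a
#' T = Z = C = 1 `FrameStack` and multi-page files need `config`.
#'
#' @param path TIFF path.
#' @param config optional list supplying metadata when no sidecar exists:
#'   `sizes` (T, Z, C) for frame stacks or `band_centers` for spectral
#'   stacks, plus `frame_interval` / `pixel_size` / `channel_names`.
#' @return a `FrameStack` or `SpectralStack`.
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else config
  if (!is.null(meta$value_scale))
    pages <- lapply(pages, function(p)
      p * meta$value_scale + (meta$value_min %||% 0))
  if (is.null(meta)) {
    if (length(pages) == 1L)
      return(frame_stack(pages[[1]]))
    stop("format error: multi-page TIFF without sidecar or config metadata")
  }
  if (identical(meta$kind, "spectral_stack") || !is.null(meta$band_centers)) {
    b <- length(pages)
    arr <- array(0, c(dim(pages[[1]]), b))
    for (i in seq_len(b)) arr[, , i] <- pages[[i]]
    return(spectral_stack(arr, meta$band_centers))
  }
  sizes <- as.integer(meta$sizes[1:3] %||%
                        stop("format error: sidecar/config lacks axis sizes"))
  if (prod(sizes) != length(pages))
    stop("format error: page count does not match declared T*Z*C")
  if (is.null(meta$frame_interval) || is.null(meta$pixel_size))
    warning("frame_interval/pixel_size missing; using defaults of 1")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(sizes, ny, nx))
  i <- 1L
  for (t in seq_len(sizes[1])) for (z in seq_len(sizes[2]))
    for (ch in seq_len(sizes[3])) {
      arr[t, z, ch, , ] <- pages[[i]]
      i <- i + 1L
    }
  frame_stack(arr,
              frame_interval = meta$frame_interval %||% 1,
              pixel_size = meta$pixel_size %||% 1,
              channel_names = unlist(meta$channel_names) %||% NULL)
}

#' Write a homogeneous record table as CSV
#'
#' @param records a data.frame, or a list of identically named lists.
#' @param path output CSV path (UTF-8, '.' decimal separator).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (!length(records)) stop("empty record list")
    fields <- lapply(records, function(r) sort(names(r)))
    if (!all(vapply(fields, identical, logical(1), fields[[1]])))
      stop("heterogeneous records: field names differ")
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  } else stop("records must be a data.frame or list of records")
  if (!nrow(df)) stop("empty record list")
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#' @param path CSV path.
#' @export
read_table_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8")
}
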