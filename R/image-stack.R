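#' Calibrated multi-channel image stack
#'
#' Container for 3D `(z, y, x)` or 4D `(t, z, y, x)` voxel grids, one array
#' per channel, with a common physical voxel size. All channels must share
#' grid dimensions. Coordinates are 0-based in exported tables; array
#' indexing inside R is the usual 1-based.
#'
#' @param channels Named list of numeric arrays, all with identical `dim`
#'   of length 3 (`z, y, x`) or 4 (`t, z, y, x`).
#' @param voxel_size Numeric length-3 vector `c(x, y, z)` in um per
#'   pixel/slice; all components > 0.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  nd <- length(dims[[1L]])
  if (!nd %in% c(3L, 4L)) stop("channel arrays must be 3D (z,y,x) or 4D (t,z,y,x)")
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("all channels must share the same grid dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers c(x, y, z) in um")
  names(voxel_size) <- c("x", "y", "z")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_stack>  %s grid [%s], voxel %g x %g x %g um, channels: %s\n",
              if (length(d) == 3L) "z,y,x" else "t,z,y,x",
              paste(d, collapse = " x "),
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @rdname image_stack
#' @param stack An `image_stack`.
#' @param channel Channel name; defaults to the first channel.
#' @export
stack_channel <- function(stack, channel = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(channel)) return(stack$channels[[1L]])
  if (!channel %in% names(stack$channels))
    stop("no channel named '", channel, "'")
  stack$channels[[channel]]
}

#' Physical volume of one voxel in um^3
#' @param stack An `image_stack`, or a numeric `c(x, y, z)` voxel size.
#' @export
voxel_volume <- function(stack) {
  vs <- if (inherits(stack, "image_stack")) stack$voxel_size else as.numeric(stack)
  prod(vs)
}

#' Extract a single time frame from a 4D stack
#' @param stack An `image_stack` with 4D `(t, z, y, x)` channels.
#' @param t Frame index (1-based).
#' @return A 3D `image_stack`.
#' @export
stack_frame <- function(stack, t) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1L]])
  if (length(d) != 4L) stop("`stack` is not a time series")
  if (t < 1L || t > d[1L]) stop("frame index out of range")
  ch <- lapply(stack$channels, function(a) array(a[t, , , ], dim = d[-1L]))
  image_stack(ch, stack$voxel_size)
}

# --- TIFF round trip ---------------------------------------------------------
# Stacks are written as multi-page 32-bit float TIFF, pages in channel-major
# then z order (then t for 4D), accompanied by a JSON companion file
# (<path>.json) recording dims, channel names, an intensity scale, and
# PhysicalSizeX/Y/Z so a round trip preserves calibration. Pages are stored
# scaled into [0, 1] (the range the TIFF writer expects for floats) and
# rescaled on read.

.stack_meta_path <- function(path) paste0(path, ".json")

#' Write / read an image stack as multi-page TIFF plus JSON companion
#'
#' The companion file `<path>.json` carries the grid dimensions, channel
#' names, physical voxel sizes (`PhysicalSizeX/Y/Z`, um) and the intensity
#' scale used to pack the data into the float TIFF.
#'
#' @param stack An [image_stack()].
#' @param path Output `.tif` path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()] equal to what was written (up to float32
#'   precision).
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1L]])
  lo <- min(vapply(stack$channels, min, numeric(1)))
  hi <- max(vapply(stack$channels, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  meta <- list(
    dims = d, order = if (length(d) == 3L) "czyx" else "ctzyx",
    channels = names(stack$channels),
    intensity_offset = lo, intensity_scale = scale,
    PhysicalSizeX = stack$voxel_size[["x"]],
    PhysicalSizeY = stack$voxel_size[["y"]],
    PhysicalSizeZ = stack$voxel_size[["z"]])
  pages <- list()
  for (ch in stack$channels) {
    a <- (ch - lo) / scale
    nz <- d[length(d) - 2L]; nt <- if (length(d) == 4L) d[1L] else 1L
    for (ti in seq_len(nt)) for (zi in seq_len(nz)) {
      m <- if (length(d) == 3L) a[zi, , ] else a[ti, zi, , ]
      pages[[length(pages) + 1L]] <- m
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(meta, .stack_meta_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(.stack_meta_path(path)))
    stop("missing companion metadata file ", .stack_meta_path(path))
  meta <- jsonlite::read_json(.stack_meta_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  d <- as.integer(meta$dims)
  nz <- d[length(d) - 2L]; ny <- d[length(d) - 1L]; nx <- d[length(d)]
  nt <- if (length(d) == 4L) d[1L] else 1L
  per_ch <- nz * nt
  channels <- list()
  for (ci in seq_along(meta$channels)) {
    block <- pages[(ci - 1L) * per_ch + seq_len(per_ch)]
    a <- array(0, dim = c(nz, ny, nx, nt))
    k <- 0L
    for (ti in seq_len(nt)) for (zi in seq_len(nz)) {
      k <- k + 1L
      a[zi, , , ti] <- block[[k]]
    }
    a <- a * meta$intensity_scale + meta$intensity_offset
    channels[[meta$channels[ci]]] <-
      if (length(d) == 3L) array(a[, , , 1L], dim = c(nz, ny, nx))
      else aperm(a, c(4L, 1L, 2L, 3L))
  }
  image_stack(channels, c(meta$PhysicalSizeX, meta$PhysicalSizeY, meta$PhysicalSizeZ))
}
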