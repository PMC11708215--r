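## 3D nuclear segmentation: blur -> Otsu -> morphological refinement ->
## component labelling, with all measurements taken from the unprocessed
## intensities. Arrays are (z, y, x); sigma and structuring elements are in
## pixel/slice units because the processing chain operates on the grid, not
## in um; calibrated areas/volumes are computed only at measurement time.

# 1D Gaussian weights, radius 3*sigma
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# convolve a 3D array along one axis (1=z, 2=y, 3=x) with symmetric
# (reflective) boundary padding
.conv_axis <- function(a, axis, kernel) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  L <- dim(ap)[1L]
  m <- matrix(ap, nrow = L)
  r <- (length(kernel) - 1L) / 2
  idx <- c(rev(seq_len(min(r, L))), seq_len(L), L + 1 - rev(seq_len(min(r, L))))
  while (length(idx) < L + 2 * r) idx <- c(idx[1L], idx, idx[length(idx)])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = L, ncol = ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * mp[(k - 1L) + seq_len(L), , drop = FALSE]
  aperm(array(out, dim = dim(ap)), order(perm))
}

#' Separable 3D Gaussian blur
#'
#' Smooths a stack with a separable Gaussian, the first step of the
#' segmentation chain. `sigma` is given as `(x, y, z)` in pixel / slice
#' units (the default `c(5, 5, 1)` blurs strongly in-plane and mildly
#' across slices, matching the anisotropy of confocal stacks). Boundaries
#' are handled by reflection. The input is not modified.
#'
#' @param x A 3D `(z, y, x)` numeric array or an [image_stack()].
#' @param sigma Length-3 numeric `(sigma_x, sigma_y, sigma_z)`, each >= 0;
#'   a component of 0 disables blurring along that axis.
#' @param channel Channel to blur when `x` is an `image_stack`.
#' @return A blurred array of the same dimensions.
#' @export
gaussian_blur_3d <- function(x, sigma = c(5, 5, 1), channel = NULL) {
  a <- if (inherits(x, "image_stack")) stack_channel(x, channel) else x
  stopifnot(is.array(a), length(dim(a)) == 3L)
  sigma <- as.numeric(sigma)
  if (length(sigma) != 3L || any(sigma < 0)) stop("`sigma` must be 3 values >= 0")
  out <- a
  # array axes are (z, y, x); sigma is (x, y, z)
  out <- .conv_axis(out, 3L, .gauss_kernel(sigma[1L]))
  out <- .conv_axis(out, 2L, .gauss_kernel(sigma[2L]))
  out <- .conv_axis(out, 1L, .gauss_kernel(sigma[3L]))
  out
}

#' Global Otsu threshold of a stack
#'
#' Builds a 256-bin histogram over the intensity range of the (typically
#' pre-blurred) stack and picks the single global threshold maximizing the
#' between-class variance; ties are broken toward the lower threshold.
#' Voxels strictly above the threshold are foreground.
#'
#' @param x A 3D numeric array or [image_stack()].
#' @param channel Channel when `x` is an `image_stack`.
#' @return A logical array (the mask) with attribute `"threshold"` holding
#'   the intensity cutoff.
#' @export
otsu_threshold <- function(x, channel = NULL) {
  a <- if (inherits(x, "image_stack")) stack_channel(x, channel) else x
  stopifnot(is.array(a), length(dim(a)) == 3L)
  rng <- range(a)
  if (!all(is.finite(rng))) stop("stack contains non-finite values")
  if (rng[1L] == rng[2L])
    stop("constant stack: Otsu threshold undefined (no intensity contrast)")
  nb <- 256L
  breaks <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  bin <- pmin(pmax(findInterval(a, breaks, all.inside = TRUE), 1L), nb)
  counts <- tabulate(bin, nbins = nb)
  p <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(nb + 1L)]) / 2
  w0 <- cumsum(p)[-nb]                      # class {bins <= k}, k = 1..255
  mu0 <- cumsum(p * mids)[-nb]
  mu_t <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)                   # which.max takes the first tie
  thr <- breaks[k + 1L]
  mask <- a > thr
  attr(mask, "threshold") <- thr
  mask
}

# offsets of a digital ball of the given radius (includes the centre)
.ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# translate a logical 3D array; exposed voxels become `fill`
.shift3 <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  if (length(zs) < 1 || length(ys) < 1 || length(xs) < 1) return(out)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

.erode3 <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets)))
    out <- out & .shift3(mask, offsets$dz[i], offsets$dy[i], offsets$dx[i],
                         fill = FALSE)
  out
}

.dilate3 <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets)))
    out <- out | .shift3(mask, offsets$dz[i], offsets$dy[i], offsets$dx[i],
                         fill = FALSE)
  out
}

# fill cavities: background components (6-connectivity) not reaching the
# border become foreground. Used per z-slice first, then in full 3D.
.fill_holes3 <- function(mask) {
  bg <- label3d_cpp(!mask, dim(mask), connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(bg[c(1L, d[1L]), , ], bg[, c(1L, d[2L]), ], bg[, , c(1L, d[3L])]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

.fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[1L])) {
    sl <- array(mask[z, , ], dim = c(1L, d[2L], d[3L]))
    mask[z, , ] <- .fill_holes3(sl)[1L, , ]
  }
  mask
}

#' Morphological refinement of a segmentation mask
#'
#' Applies, in order: erode, dilate, open (erode-dilate), close
#' (dilate-erode), then fill holes (per z-slice, then in 3D), all with a
#' digital ball structuring element. This removes speckle, smooths nucleus
#' boundaries and closes interior cavities left by dim chromatin.
#'
#' @param mask Logical 3D array.
#' @param element_radius Structuring-element radius in voxels (default 1,
#'   the 6-neighbourhood ball).
#' @return The refined logical array.
#' @export
refine_mask <- function(mask, element_radius = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  off <- .ball_offsets(element_radius)
  m <- .erode3(mask, off)
  m <- .dilate3(m, off)
  m <- .dilate3(.erode3(m, off), off)   # open
  m <- .erode3(.dilate3(m, off), off)   # close
  m <- .fill_holes_slicewise(m)
  .fill_holes3(m)
}

#' Label connected components and measure them on the raw stack
#'
#' 3D connected-component labelling (26-connectivity) of a refined mask.
#' Components smaller than `min_voxels` are discarded and the survivors
#' relabelled 1..n in first-contact order. All intensity measurements are
#' taken from the unprocessed stack: blur and morphology shape the label
#' set only, never the measured values.
#'
#' @param mask Logical 3D array (typically from [refine_mask()]).
#' @param stack Raw intensities: a 3D array or [image_stack()]; `NULL`
#'   leaves the intensity columns `NA`.
#' @param voxel_size `c(x, y, z)` in um (taken from `stack` when it is an
#'   `image_stack`).
#' @param min_voxels Minimum component size in voxels (default 27, a 3x3x3
#'   block).
#' @param channel Measurement channel when `stack` is an `image_stack`.
#' @return A `label_volume`: list with the integer `labels` array
#'   (background 0), the measurement `table` (label, voxel_count,
#'   volume_um3, centroid_z/y/x in 1-based voxel coordinates,
#'   total_intensity, mean_intensity), and `voxel_size`.
#' @export
label_components <- function(mask, stack = NULL, voxel_size = NULL,
                             min_voxels = 27L, channel = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  raw <- NULL
  if (!is.null(stack)) {
    if (inherits(stack, "image_stack")) {
      raw <- stack_channel(stack, channel)
      if (is.null(voxel_size)) voxel_size <- stack$voxel_size
    } else raw <- stack
    if (!identical(dim(raw), dim(mask)))
      stop("mask and stack dimensions differ")
  }
  if (is.null(voxel_size)) stop("`voxel_size` required (or pass an image_stack)")
  labs <- label3d_cpp(mask, dim(mask), connectivity = 26L)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= min_voxels)
  d <- dim(mask)
  if (length(keep) == 0L) {
    return(structure(list(labels = array(0L, dim = d),
                          table = .empty_label_table(),
                          voxel_size = voxel_size),
                     class = "label_volume"))
  }
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  new_labs <- array(0L, dim = d)
  pos <- labs > 0L
  new_labs[pos] <- relab[labs[pos]]
  idx <- which(new_labs > 0L)
  lab_at <- new_labs[idx]
  zc <- ((idx - 1L) %% d[1L]) + 1L
  yc <- (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L
  xc <- ((idx - 1L) %/% (d[1L] * d[2L])) + 1L
  vc <- as.integer(tabulate(lab_at, nbins = length(keep)))
  vv <- voxel_volume(voxel_size)
  tab <- data.frame(
    label = seq_along(keep),
    voxel_count = vc,
    volume_um3 = vc * vv,
    centroid_z = as.numeric(tapply(zc, lab_at, mean)),
    centroid_y = as.numeric(tapply(yc, lab_at, mean)),
    centroid_x = as.numeric(tapply(xc, lab_at, mean)),
    total_intensity = NA_real_, mean_intensity = NA_real_)
  if (!is.null(raw)) {
    tot <- as.numeric(tapply(raw[idx], lab_at, sum))
    tab$total_intensity <- tot
    tab$mean_intensity <- tot / vc
  }
  structure(list(labels = new_labs, table = tab, voxel_size = voxel_size),
            class = "label_volume")
}

.empty_label_table <- function() {
  data.frame(label = integer(), voxel_count = integer(), volume_um3 = numeric(),
             centroid_z = numeric(), centroid_y = numeric(), centroid_x = numeric(),
             total_intensity = numeric(), mean_intensity = numeric())
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume>  %d component(s), grid [%s]\n",
              nrow(x$table), paste(dim(x$labels), collapse = " x ")))
  if (nrow(x$table)) print(head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Full segmentation chain on one channel
#'
#' Convenience wrapper running [gaussian_blur_3d()], [otsu_threshold()],
#' [refine_mask()] and [label_components()] with the standard defaults.
#'
#' @inheritParams gaussian_blur_3d
#' @inheritParams label_components
#' @param element_radius Structuring-element radius for [refine_mask()].
#' @return A `label_volume`, measured on the raw channel.
#' @export
segment_nuclei <- function(x, sigma = c(5, 5, 1), element_radius = 1,
                           min_voxels = 27L, channel = NULL,
                           voxel_size = NULL) {
  raw <- if (inherits(x, "image_stack")) stack_channel(x, channel) else x
  if (inherits(x, "image_stack") && is.null(voxel_size)) voxel_size <- x$voxel_size
  blurred <- gaussian_blur_3d(raw, sigma = sigma)
  mask <- refine_mask(otsu_threshold(blurred), element_radius = element_radius)
  label_components(mask, stack = raw, voxel_size = voxel_size,
                   min_voxels = min_voxels)
}

# shoelace polygon area; vertices in order
.polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Midsection area from follicle-nucleus positions
#'
#' The follicle-cell nuclear shell outlines the egg chamber. For each
#' z-slice, the chamber cross-section is approximated by the filled convex
#' hull of the follicle-nucleus centroids present in that slice; the slice
#' with the largest hull area is the midsection. This automates the manual
#' polygon trace with a deterministic geometric rule (egg chambers are
#' near-convex through stage 10).
#'
#' @param follicle A `label_volume` of follicle nuclei (from
#'   [label_components()] / [segment_nuclei()]).
#' @return A list with `z_index` (1-based slice), `area_um2`, and
#'   `per_slice` (data frame of slice areas).
#' @export
midsection_area <- function(follicle) {
  stopifnot(inherits(follicle, "label_volume"))
  labs <- follicle$labels
  d <- dim(labs)
  vs <- as.numeric(follicle$voxel_size)
  names(vs) <- c("x", "y", "z")
  res <- data.frame(z_index = seq_len(d[1L]), n_nuclei = 0L, area_um2 = NA_real_)
  for (z in seq_len(d[1L])) {
    sl <- labs[z, , ]
    idx <- which(sl > 0L)
    if (!length(idx)) next
    lab <- sl[idx]
    yy <- ((idx - 1L) %% d[2L]) + 1L
    xx <- ((idx - 1L) %/% d[2L]) + 1L
    cy <- tapply(yy, lab, mean) * vs[["y"]]
    cx <- tapply(xx, lab, mean) * vs[["x"]]
    res$n_nuclei[z] <- length(cy)
    if (length(cy) < 3L) next
    pts <- cbind(cx, cy)
    hull <- grDevices::chull(pts)
    res$area_um2[z] <- .polygon_area(pts[hull, , drop = FALSE])
  }
  if (all(is.na(res$area_um2)))
    stop("fewer than 3 follicle nuclei in every slice: midsection undefined")
  best <- which.max(res$area_um2)
  list(z_index = res$z_index[best], area_um2 = res$area_um2[best],
       per_slice = res)
}

#' Translational registration of two frames
#'
#' Estimates the integer-pixel `(dy, dx)` translation that aligns frame `b`
#' to frame `a` by maximizing the circular cross-correlation (computed via
#' FFT) of their maximum-intensity projections. A positive `dy` means `b`
#' is displaced downward (larger y) relative to `a`.
#'
#' @param frame_a,frame_b 3D `(z, y, x)` arrays or 2D `(y, x)` matrices of
#'   the same size.
#' @return Integer vector `c(dy, dx)`; shifting `b` by `-c(dy, dx)` (see
#'   [shift_frame()]) aligns it to `a`.
#' @export
register_translation <- function(frame_a, frame_b) {
  mip <- function(f) {
    if (length(dim(f)) == 3L) apply(f, c(2L, 3L), max) else as.matrix(f)
  }
  a <- mip(frame_a); b <- mip(frame_b)
  if (!identical(dim(a), dim(b))) stop("frames must have identical dimensions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("empty or constant frame: registration undefined")
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  d <- dim(a)
  wrap <- function(i, n) { s <- i - 1L; if (s > n %/% 2) s - n else s }
  c(dy = wrap(peak[[1L]], d[1L]), dx = wrap(peak[[2L]], d[2L]))
}

#' Translate a frame by whole pixels
#'
#' @param frame 2D matrix or 3D `(z, y, x)` array.
#' @param dy,dx Shift in pixels; exposed pixels are zero-filled.
#' @return The shifted frame.
#' @export
shift_frame <- function(frame, dy, dx) {
  if (length(dim(frame)) == 3L) {
    out <- array(0, dim = dim(frame))
    d <- dim(frame)
    zs <- seq_len(d[1L])
    ys <- max(1, 1 + dy):min(d[2L], d[2L] + dy)
    xs <- max(1, 1 + dx):min(d[3L], d[3L] + dx)
    out[zs, ys, xs] <- frame[zs, ys - dy, xs - dx]
    return(out)
  }
  d <- dim(frame)
  out <- matrix(0, d[1L], d[2L])
  ys <- max(1, 1 + dy):min(d[1L], d[1L] + dy)
  xs <- max(1, 1 + dx):min(d[2L], d[2L] + dx)
  out[ys, xs] <- frame[ys - dy, xs - dx]
  out
}
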