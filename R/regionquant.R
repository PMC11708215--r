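## Region-based normalized fluorescence quantification. Named egg-chamber
## regions: NCN (nurse-cell nuclei), NCC (nurse-cell cytoplasm), AO / PO
## (anterior / posterior oocyte cytoplasm), FOLLICLE_REF (follicle-nucleus
## reference), OOCYTE_TOTAL. Regional concentrations are measured as mean
## raw intensity in a square ROI replicated over a short z-range below the
## follicle border and normalized to the follicle reference of the same
## frame, which cancels any global per-frame gain (exposure, bleaching).

.rq_regions <- c("NCN", "NCC", "AO", "PO", "FOLLICLE_REF", "OOCYTE_TOTAL")

#' Specification of a quantification region
#'
#' Defaults encode the standard sampling scheme: a 20 x 20 pixel box in 3
#' z-slices spaced 3 um apart starting 9 um below the follicle border,
#' with regional distance constraints of 17 um to the relevant border.
#'
#' @param region One of `"NCN"`, `"NCC"`, `"AO"`, `"PO"`,
#'   `"FOLLICLE_REF"`, `"OOCYTE_TOTAL"`.
#' @param roi_edge_px Edge of the square ROI in pixels.
#' @param max_distance_um Maximum distance of the ROI centre to the
#'   region's defining border, um.
#' @param z_offset_um Depth of the first sampled slice below the follicle
#'   border, um.
#' @param n_slices Number of sampled z-slices.
#' @param slice_step_um Spacing of sampled slices, um.
#' @return A `region_spec`.
#' @export
region_spec <- function(region, roi_edge_px = 20L, max_distance_um = 17,
                        z_offset_um = 9, n_slices = 3L, slice_step_um = 3) {
  region <- match.arg(region, .rq_regions)
  if (roi_edge_px < 1L) stop("`roi_edge_px` must be >= 1")
  if (n_slices < 1L) stop("`n_slices` must be >= 1")
  if (max_distance_um < 0 || z_offset_um < 0 || slice_step_um < 0)
    stop("distances must be >= 0")
  structure(list(region = region, roi_edge_px = as.integer(roi_edge_px),
                 max_distance_um = max_distance_um, z_offset_um = z_offset_um,
                 n_slices = as.integer(n_slices), slice_step_um = slice_step_um),
            class = "region_spec")
}

#' Total intensity of the oocyte over the top half of a stack
#'
#' Older chambers cannot be imaged to full depth, so yolk totals are taken
#' over one half of the chamber: all z-slices from the top surface through
#' the midsection, summed over oocyte-mask voxels of the raw channel.
#'
#' @param stack 3D array or [image_stack()].
#' @param oocyte_mask Logical array congruent with the stack.
#' @param midsection_z Midsection slice index (inclusive upper bound of
#'   the summed range).
#' @param channel Channel when `stack` is an `image_stack`.
#' @return Total raw intensity (scalar).
#' @export
oocyte_total_intensity <- function(stack, oocyte_mask, midsection_z,
                                   channel = NULL) {
  a <- if (inherits(stack, "image_stack")) stack_channel(stack, channel) else stack
  stopifnot(identical(dim(a), dim(oocyte_mask)))
  if (midsection_z < 1L || midsection_z > dim(a)[1L])
    stop("`midsection_z` out of range")
  half <- oocyte_mask
  if (midsection_z < dim(a)[1L])
    half[(midsection_z + 1L):dim(a)[1L], , ] <- FALSE
  if (!any(half)) stop("empty oocyte mask in the top half of the stack")
  sum(a[half])
}

#' Normalize a raw intensity by the follicle reference of the same frame
#'
#' Divides by the total (for yolk totals) or mean (for regional
#' concentrations) raw intensity over the follicle-nucleus voxels of the
#' same frame. Because reference and signal share every global gain
#' factor, the ratio is invariant to exposure changes and photobleaching.
#'
#' @param raw Raw intensity value(s) to normalize.
#' @param follicle Logical mask, or a `label_volume` whose nonzero labels
#'   are the follicle nuclei.
#' @param stack Raw frame (3D array or [image_stack()]).
#' @param mode `"total"` or `"mean"` follicle statistic.
#' @param channel Channel when `stack` is an `image_stack`.
#' @return `raw / reference`, with the reference attached as an attribute.
#' @export
normalize_by_follicle <- function(raw, follicle, stack,
                                  mode = c("total", "mean"), channel = NULL) {
  mode <- match.arg(mode)
  a <- if (inherits(stack, "image_stack")) stack_channel(stack, channel) else stack
  mask <- if (inherits(follicle, "label_volume")) follicle$labels > 0L else follicle
  stopifnot(identical(dim(a), dim(mask)))
  if (!any(mask)) stop("empty follicle reference mask")
  ref <- if (mode == "total") sum(a[mask]) else mean(a[mask])
  if (!is.finite(ref) || ref <= 0)
    stop("follicle reference intensity is zero or undefined")
  out <- raw / ref
  attr(out, "reference") <- ref
  out
}

# 2D integral-image box sums of a (ny, nx) matrix for all edge-`e` boxes;
# returns matrix indexed by top-left corner
.box_sums <- function(m, e) {
  cs <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed cumsum table
  cs <- t(cs)
  pad <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  pad[-1L, -1L] <- cs
  ny <- nrow(m) - e + 1L; nx <- ncol(m) - e + 1L
  if (ny < 1L || nx < 1L) return(matrix(numeric(0), 0, 0))
  pad[(1L + e):(nrow(m) + 1L), (1L + e):(ncol(m) + 1L)] -
    pad[1L:ny, (1L + e):(ncol(m) + 1L)] -
    pad[(1L + e):(nrow(m) + 1L), 1L:nx] + pad[1L:ny, 1L:nx]
}

# in-plane border pixels of a 2D mask (pixels with a 4-neighbour outside)
.mask_border2d <- function(m) {
  up <- rbind(m[-1L, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  lf <- cbind(m[, -1L, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  m & !(up & dn & lf & rt)
}

# min distance (um) from candidate centres to a set of border pixels
.min_dist_um <- function(cy, cx, border_yx, voxel_size) {
  if (!nrow(border_yx)) return(rep(Inf, length(cy)))
  by <- border_yx[, 1L] * voxel_size[["y"]]
  bx <- border_yx[, 2L] * voxel_size[["x"]]
  vapply(seq_along(cy), function(i)
    sqrt(min((cy[i] * voxel_size[["y"]] - by)^2 +
               (cx[i] * voxel_size[["x"]] - bx)^2)), numeric(1L))
}

#' Deterministic placement of a regional quantification ROI
#'
#' Finds the `roi_edge_px` square (replicated over the spec's z-slices,
#' placed below the follicle border) that satisfies the region's
#' membership and distance constraints while containing no nuclear voxels,
#' then - because many positions usually qualify - picks the one whose
#' centre is farthest from any nuclear voxel, ties broken by smallest
#' `(y, x)`. This replaces per-frame manual placement with a reproducible
#' rule.
#'
#' Regional constraints (centre distances, in um):
#' * `NCC`: inside the chamber, outside the oocyte, within
#'   `max_distance_um` of the oocyte border.
#' * `AO`: inside the oocyte, within `max_distance_um` of the nurse-oocyte
#'   border.
#' * `PO`: inside the oocyte, within `max_distance_um` of the posterior
#'   chamber border.
#' * `FOLLICLE_REF`: maximal follicle-mask coverage (no nuclear-free
#'   requirement; the follicle nuclei are the signal).
#'
#' @param frame A 3D [image_stack()] or array (used for dimensions only).
#' @param spec A [region_spec()].
#' @param geometry List of logical masks congruent with the frame:
#'   `chamber`, `oocyte`, `nuclei`, `follicle`.
#' @param voxel_size `c(x, y, z)` um (from the stack when available).
#' @param candidate_stride Grid stride (pixels) when scanning candidate
#'   positions; 1 scans every position.
#' @return A `region_roi`: list with `region`, `y`/`x` (top-left, 1-based),
#'   `edge_px`, `z_slices`, and the centre coordinates in um.
#' @export
place_region_roi <- function(frame, spec, geometry, voxel_size = NULL,
                             candidate_stride = 2L) {
  stopifnot(inherits(spec, "region_spec"))
  a <- if (inherits(frame, "image_stack")) stack_channel(frame) else frame
  if (inherits(frame, "image_stack") && is.null(voxel_size))
    voxel_size <- frame$voxel_size
  if (is.null(voxel_size)) stop("`voxel_size` required")
  names(voxel_size) <- c("x", "y", "z")
  d <- dim(a)
  for (nm in c("chamber", "oocyte", "nuclei", "follicle"))
    if (!nm %in% names(geometry)) stop("geometry lacks mask '", nm, "'")

  # z-slices: offset below the follicle border (top of the chamber)
  z_top <- which(apply(geometry$chamber, 1L, any))[1L]
  if (is.na(z_top)) stop("empty chamber mask")
  depths <- spec$z_offset_um + (seq_len(spec$n_slices) - 1L) * spec$slice_step_um
  z_slices <- unique(pmin(d[1L], z_top + round(depths / voxel_size[["z"]])))

  e <- spec$roi_edge_px
  if (e > d[2L] || e > d[3L]) stop("ROI larger than the frame")
  collapse <- function(mask) {
    m <- matrix(FALSE, d[2L], d[3L])
    for (z in z_slices) m <- m | mask[z, , ]
    m
  }
  flatten_all <- function(mask) {          # TRUE where mask holds in ALL slices
    m <- matrix(TRUE, d[2L], d[3L])
    for (z in z_slices) m <- m & mask[z, , ]
    m
  }
  nuc2d <- collapse(geometry$nuclei)
  cham2d <- flatten_all(geometry$chamber)
  oo2d <- flatten_all(geometry$oocyte)
  fol2d <- collapse(geometry$follicle)

  ys <- seq(1L, d[2L] - e + 1L, by = candidate_stride)
  xs <- seq(1L, d[3L] - e + 1L, by = candidate_stride)
  cand <- expand.grid(y = ys, x = xs)
  cy <- cand$y + (e - 1) / 2
  cx <- cand$x + (e - 1) / 2

  if (spec$region == "FOLLICLE_REF") {
    bs <- .box_sums(fol2d * 1, e)
    score <- bs[cbind(cand$y, cand$x)]
    if (max(score) <= 0) stop("no follicle coverage for region FOLLICLE_REF")
    best <- which(score == max(score))
    best <- best[order(cand$y[best], cand$x[best])][1L]
    return(.make_roi(spec, cand$y[best], cand$x[best], z_slices, cy[best],
                     cx[best], voxel_size))
  }

  nuc_bs <- .box_sums(nuc2d * 1, e)
  inside_bs <- switch(spec$region,
                      NCC = .box_sums((cham2d & !oo2d) * 1, e),
                      AO = , PO = .box_sums(oo2d * 1, e))
  ok <- nuc_bs[cbind(cand$y, cand$x)] == 0 &
    inside_bs[cbind(cand$y, cand$x)] == e * e

  border_yx <- switch(spec$region,
    # nurse-oocyte interface: oocyte border pixels adjacent to non-oocyte
    # chamber (not the outer chamber boundary)
    NCC = , AO = {
      oo <- collapse(geometry$oocyte)
      nurse2d <- collapse(geometry$chamber) & !oo & !collapse(geometry$follicle)
      grown <- .mask_border2d(oo) &
        (rbind(nurse2d[-1L, , drop = FALSE], FALSE) |
           rbind(FALSE, nurse2d[-nrow(nurse2d), , drop = FALSE]) |
           cbind(nurse2d[, -1L, drop = FALSE], FALSE) |
           cbind(FALSE, nurse2d[, -ncol(nurse2d), drop = FALSE]))
      which(grown, arr.ind = TRUE)
    },
    PO = {
      # posterior border: the oocyte's own boundary in its posterior half
      # (excluding the nurse-facing interface)
      oo <- collapse(geometry$oocyte)
      ob <- which(.mask_border2d(oo), arr.ind = TRUE)
      oo_px <- which(oo, arr.ind = TRUE)
      x_centroid <- mean(oo_px[, 2L])
      ob[ob[, 2L] >= x_centroid, , drop = FALSE]
    })
  if (any(ok)) {
    dist_border <- rep(Inf, nrow(cand))
    dist_border[ok] <- .min_dist_um(cy[ok], cx[ok], border_yx, voxel_size)
    ok <- ok & dist_border <= spec$max_distance_um
  }
  if (!any(ok))
    stop("no nuclear-free position satisfies the constraints for region ",
         spec$region)
  nuc_yx <- which(nuc2d, arr.ind = TRUE)
  dist_nuc <- .min_dist_um(cy[ok], cx[ok], nuc_yx, voxel_size)
  cand_ok <- cand[ok, , drop = FALSE]
  best <- which(dist_nuc == max(dist_nuc))
  best <- best[order(cand_ok$y[best], cand_ok$x[best])][1L]
  .make_roi(spec, cand_ok$y[best], cand_ok$x[best], z_slices,
            cand_ok$y[best] + (e - 1) / 2, cand_ok$x[best] + (e - 1) / 2,
            voxel_size)
}

.make_roi <- function(spec, y, x, z_slices, cy, cx, voxel_size) {
  structure(list(region = spec$region, y = y, x = x,
                 edge_px = spec$roi_edge_px, z_slices = z_slices,
                 center_y_um = cy * voxel_size[["y"]],
                 center_x_um = cx * voxel_size[["x"]]),
            class = "region_roi")
}

#' @export
print.region_roi <- function(x, ...) {
  cat(sprintf("<region_roi %s>  %dpx box at (y=%d, x=%d), z-slices %s\n",
              x$region, x$edge_px, x$y, x$x,
              paste(x$z_slices, collapse = ",")))
  invisible(x)
}

# mean raw intensity of a placed ROI
.roi_mean <- function(a, roi) {
  ys <- roi$y:(roi$y + roi$edge_px - 1L)
  xs <- roi$x:(roi$x + roi$edge_px - 1L)
  mean(a[roi$z_slices, ys, xs])
}

#' Normalized regional time series from an image series
#'
#' For every `frame_stride`-th frame, places each requested regional ROI
#' (NCC, AO, PO) with [place_region_roi()], measures its mean raw
#' intensity, and normalizes by the mean follicle-nucleus intensity of the
#' same frame. NCN is measured over the nuclear mask and reported both as
#' total intensity and as concentration (total / nuclear volume), also
#' follicle-normalized.
#'
#' @param series A `dumping_series` (from [simulate_dumping_series()]) or a
#'   list with `frames` (list of [image_stack()]), `times`, and `geometry`
#'   (static masks plus `nuclei_by_frame`).
#' @param regions Character vector of regions to quantify.
#' @param frame_stride Sample every n-th frame (default 5).
#' @param channel Channel to measure.
#' @return Data frame: `frame`, `t_h`, `region`, `raw`, `reference`,
#'   `normalized`, plus `volume_um3` for NCN rows.
#' @export
region_timeseries <- function(series, regions = c("NCN", "NCC", "AO", "PO"),
                              frame_stride = 5L, channel = "histone") {
  regions <- match.arg(regions, .rq_regions, several.ok = TRUE)
  geo <- series$geometry
  frames_idx <- seq(1L, length(series$frames), by = frame_stride)
  vv <- voxel_volume(series$frames[[1L]])
  out <- list()
  specs <- lapply(setdiff(regions, "NCN"), region_spec)
  for (i in frames_idx) {
    fr <- series$frames[[i]]
    a <- stack_channel(fr, channel)
    nuclei <- geo$nuclei_by_frame[[i]]
    geometry <- list(chamber = geo$chamber, oocyte = geo$oocyte,
                     nuclei = nuclei, follicle = geo$follicle)
    ref <- mean(a[geo$follicle])
    if (!is.finite(ref) || ref <= 0) stop("zero follicle reference in frame ", i)
    for (sp in specs) {
      roi <- place_region_roi(fr, sp, geometry)
      raw <- .roi_mean(a, roi)
      out[[length(out) + 1L]] <- data.frame(
        frame = i, t_h = series$times[i], region = sp$region,
        raw = raw, reference = ref, normalized = raw / ref,
        volume_um3 = NA_real_)
    }
    if ("NCN" %in% regions) {
      if (!any(nuclei)) next
      tot <- sum(a[nuclei])
      vol <- sum(nuclei) * vv
      out[[length(out) + 1L]] <- data.frame(
        frame = i, t_h = series$times[i], region = "NCN",
        raw = tot, reference = ref, normalized = tot / ref,
        volume_um3 = vol)
    }
  }
  do.call(rbind, out)
}

#' Nuclear total, volume and concentration over time
#'
#' From per-frame nuclear totals and volumes (e.g. segmentation
#' measurements), computes concentration = total / volume. If the nuclear
#' volume vanishes the series terminates there and is flagged.
#'
#' @param totals Per-frame total nuclear intensities.
#' @param volumes_um3 Per-frame nuclear volumes, um^3.
#' @param t_h Frame times in hours.
#' @return Data frame `t_h`, `total`, `volume_um3`, `concentration`, with
#'   attribute `"terminated"` TRUE if the label vanished before the end.
#' @export
nuclear_concentration_series <- function(totals, volumes_um3, t_h) {
  stopifnot(length(totals) == length(volumes_um3),
            length(totals) == length(t_h))
  alive <- volumes_um3 > 0
  last <- if (all(alive)) length(t_h) else which(!alive)[1L] - 1L
  if (last < 1L) stop("nuclear volume is zero from the first frame")
  i <- seq_len(last)
  out <- data.frame(t_h = t_h[i], total = totals[i],
                    volume_um3 = volumes_um3[i],
                    concentration = totals[i] / volumes_um3[i])
  attr(out, "terminated") <- last < length(t_h)
  out
}

#' Export a regional time series as CSV
#'
#' @param series Data frame from [region_timeseries()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_region_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
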