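## Nurse-cell dumping phantom. Histone signal flows through a first-order
## compartment chain: nurse nuclei -> nurse-cell cytoplasm (NCC) ->
## anterior oocyte (AO) -> posterior oocyte (PO). The chain is solved
## exactly with the matrix exponential, so ground-truth totals carry no
## integrator error; forward Euler is kept as an independent cross-check.
## Each frame is rendered into a calibrated stack with uniform compartment
## concentrations, nurse nuclei shrinking in volume at their own rate, and
## a constant follicle-nucleus shell acting as the normalization reference.

#' Parameters of the dumping-flux generator
#'
#' @param k_nuc_out Rate nuclei -> nurse cytoplasm (1/h).
#' @param k_ncc_ao Rate nurse cytoplasm -> anterior oocyte (1/h).
#' @param k_ao_po Rate anterior -> posterior oocyte (1/h).
#' @param nuclear_shrink_rate Exponential decay rate of total nuclear
#'   volume (1/h); independent of the signal rates, so concentration
#'   `total/volume` can rise transiently when it exceeds `k_nuc_out`.
#' @param duration,dt Time span and frame interval in hours.
#' @param initial_nuclear_total Signal initially in the nuclei (arbitrary
#'   intensity units).
#' @param noise_sd Additive Gaussian noise on rendered frames.
#' @param voxel_size `c(x, y, z)` in um for the rendered stacks.
#' @param seed Integer seed (noise only; the dynamics are deterministic).
#' @return A `dumping_flow_params` list.
#' @export
dumping_flow_params <- function(k_nuc_out = 0.8, k_ncc_ao = 0.5,
                                k_ao_po = 0.3, nuclear_shrink_rate = 0.25,
                                duration = 12, dt = 0.25,
                                initial_nuclear_total = 1e6,
                                noise_sd = 0,
                                voxel_size = c(1, 1, 3),
                                seed = NULL) {
  rates <- c(k_nuc_out, k_ncc_ao, k_ao_po, nuclear_shrink_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (dt <= 0) stop("`dt` must be > 0")
  if (duration < dt) stop("`duration` must be >= dt")
  if (initial_nuclear_total <= 0) stop("`initial_nuclear_total` must be > 0")
  structure(list(k_nuc_out = k_nuc_out, k_ncc_ao = k_ncc_ao,
                 k_ao_po = k_ao_po, nuclear_shrink_rate = nuclear_shrink_rate,
                 duration = duration, dt = dt,
                 initial_nuclear_total = initial_nuclear_total,
                 noise_sd = noise_sd, voxel_size = as.numeric(voxel_size),
                 seed = seed),
            class = "dumping_flow_params")
}

# rate matrix of the conservative 4-compartment chain
.dumping_rate_matrix <- function(params) {
  k1 <- params$k_nuc_out; k2 <- params$k_ncc_ao; k3 <- params$k_ao_po
  matrix(c(-k1,   0,   0, 0,
            k1, -k2,   0, 0,
             0,  k2, -k3, 0,
             0,   0,  k3, 0),
         nrow = 4L, byrow = TRUE,
         dimnames = list(c("nuclei", "ncc", "ao", "po"), NULL))
}

#' Exact compartment totals of the dumping chain
#'
#' Evaluates the linear ODE solution `x(t) = expm(A t) x(0)` at the given
#' times. Because the chain has no degradation term, the four totals sum to
#' the initial nuclear total exactly at every time.
#'
#' @param params A [dumping_flow_params()].
#' @param times Times in hours (default the frame grid `seq(0, duration, dt)`).
#' @param method `"expm"` (exact) or `"euler"` (forward Euler at `dt`,
#'   retained as a cross-check; errors when `rate * dt >= 1`).
#' @return Matrix with rows `nuclei`, `ncc`, `ao`, `po`, one column per time.
#' @export
dumping_compartment_totals <- function(params,
                                       times = seq(0, params$duration, by = params$dt),
                                       method = c("expm", "euler")) {
  stopifnot(inherits(params, "dumping_flow_params"))
  method <- match.arg(method)
  A <- .dumping_rate_matrix(params)
  x0 <- c(params$initial_nuclear_total, 0, 0, 0)
  if (method == "expm") {
    out <- vapply(times, function(t)
      as.numeric(Matrix::expm(A * t) %*% x0), numeric(4L))
  } else {
    kmax <- max(params$k_nuc_out, params$k_ncc_ao, params$k_ao_po)
    if (kmax * params$dt >= 1)
      stop("Euler unstable: rate * dt = ", format(kmax * params$dt), " >= 1")
    tmax <- max(times)
    grid <- seq(0, tmax + params$dt, by = params$dt)
    xs <- matrix(0, nrow = 4L, ncol = length(grid))
    xs[, 1L] <- x0
    for (i in seq_len(length(grid) - 1L))
      xs[, i + 1L] <- xs[, i] + params$dt * (A %*% xs[, i])
    out <- xs[, vapply(times, function(t) which.min(abs(grid - t)), integer(1L)),
              drop = FALSE]
  }
  rownames(out) <- rownames(A)
  out
}

# static dumping geometry: a stage 10-11 sized chamber (~160 x 80 um) with
# the oocyte occupying the posterior half, so the anterior/posterior 17-um
# bands are well separated; nurse nuclei are voxelized per frame because
# they shrink
.dumping_geometry <- function(voxel_size, nurse_radius_um = 6) {
  vs <- voxel_size
  dims <- c(ceiling(42 / vs[3L]), ceiling(92 / vs[2L]), ceiling(176 / vs[1L]))
  center <- c(dims[1L] * vs[3L], dims[2L] * vs[2L], dims[3L] * vs[1L]) / 2
  semi <- c(16, 40, 80)  # (z, y, x) um
  chamber <- .ellipsoid_mask(dims, vs, center, semi)
  # follicle shell nuclei at the chamber boundary
  follicle <- chamber &
    !.ellipsoid_mask(dims, vs, center, pmax(semi - 2.5, 0.5))
  g <- .coord_grids(dims, vs)
  xg <- outer(outer(rep(TRUE, dims[1L]), rep(TRUE, dims[2L])), g$x)
  x_cut <- center[3L]                            # oocyte = posterior half
  oocyte <- chamber & !follicle & (xg >= x_cut)
  band <- 17                                     # um, regional band width
  ao <- oocyte & (xg < x_cut + band)
  x_post <- max(g$x[apply(oocyte, 3L, any)])
  po <- oocyte & (xg >= x_post - band)
  # nurse-nucleus centres: fixed anterior positions
  nc <- rbind(c(center[1L], center[2L] - 14, center[3L] - 55),
              c(center[1L], center[2L] + 14, center[3L] - 55),
              c(center[1L], center[2L] - 14, center[3L] - 30),
              c(center[1L], center[2L] + 14, center[3L] - 30))
  nuclei0 <- array(FALSE, dim = dims)
  for (k in seq_len(nrow(nc)))
    nuclei0[.sphere_voxels(dims, vs, nc[k, ], nurse_radius_um)] <- TRUE
  ncc <- chamber & !oocyte & !nuclei0 & !follicle
  list(dims = dims, center = center, semi = semi, chamber = chamber,
       oocyte = oocyte, ao = ao, po = po, follicle = follicle, ncc = ncc,
       nurse_centers = nc, nurse_radius = nurse_radius_um,
       voxel_size = vs)
}

#' Simulate a nurse-cell dumping image series
#'
#' Solves the compartment chain exactly, then renders each frame: nurse
#' nuclei (shrinking at `nuclear_shrink_rate`), NCC, AO and PO regions each
#' carry their compartment total spread uniformly over their voxels, and a
#' follicle-nucleus shell holds a constant reference intensity. Emits exact
#' per-frame compartment totals and nuclear volumes alongside the frames.
#'
#' @param params A [dumping_flow_params()].
#' @return A `dumping_series`: list with `frames` (list of single-channel
#'   `histone` [image_stack()]s), `times` (hours), `truth` (data frame:
#'   frame, t_h, the four compartment totals, nuclear_volume_um3),
#'   `geometry` (static masks plus per-frame `nuclei` masks), and `params`.
#' @export
simulate_dumping_series <- function(params) {
  stopifnot(inherits(params, "dumping_flow_params"))
  .eval_with_seed(params$seed, function() {
    times <- seq(0, params$duration, by = params$dt)
    totals <- dumping_compartment_totals(params, times)
    geo <- .dumping_geometry(params$voxel_size)
    vs <- geo$voxel_size
    vv <- voxel_volume(vs)
    follicle_level <- 50
    frames <- vector("list", length(times))
    nuclei_masks <- vector("list", length(times))
    truth <- data.frame(frame = seq_along(times), t_h = times,
                        nuclei_total = totals["nuclei", ],
                        ncc_total = totals["ncc", ],
                        ao_total = totals["ao", ],
                        po_total = totals["po", ],
                        nuclear_volume_um3 = NA_real_)
    for (i in seq_along(times)) {
      r_t <- geo$nurse_radius * exp(-params$nuclear_shrink_rate * times[i] / 3)
      nuc <- array(FALSE, dim = geo$dims)
      if (r_t >= min(vs) / 2)
        for (k in seq_len(nrow(geo$nurse_centers)))
          nuc[.sphere_voxels(geo$dims, vs, geo$nurse_centers[k, ], r_t)] <- TRUE
      nvox <- sum(nuc)
      truth$nuclear_volume_um3[i] <- nvox * vv
      a <- array(0, dim = geo$dims)
      if (nvox > 0) a[nuc] <- totals["nuclei", i] / nvox
      a[geo$ncc] <- totals["ncc", i] / sum(geo$ncc)
      a[geo$ao] <- totals["ao", i] / sum(geo$ao)
      # PO overlaps nothing by construction; AO and PO are disjoint bands
      a[geo$po] <- totals["po", i] / sum(geo$po)
      a[geo$follicle] <- follicle_level
      if (params$noise_sd > 0)
        a <- a + stats::rnorm(length(a), sd = params$noise_sd)
      frames[[i]] <- image_stack(list(histone = a), vs)
      nuclei_masks[[i]] <- nuc
    }
    structure(list(frames = frames, times = times, truth = truth,
                   geometry = c(geo, list(nuclei_by_frame = nuclei_masks)),
                   params = params),
              class = "dumping_series")
  })
}

#' @export
print.dumping_series <- function(x, ...) {
  cat(sprintf("<dumping_series>  %d frames over %g h (dt = %g h), grid [%s]\n",
              length(x$frames), x$params$duration, x$params$dt,
              paste(dim(x$frames[[1L]]$channels[[1L]]), collapse = " x ")))
  invisible(x)
}
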