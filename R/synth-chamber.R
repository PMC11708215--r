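## Egg-chamber image phantom. Renders an ellipsoidal chamber on a
## calibrated voxel grid: a shell of follicle nuclei on the boundary,
## nurse nuclei in the anterior compartment, and an oocyte occupying a
## prescribed fraction of the midsection area, with per-channel gains and
## additive Gaussian noise. Every nucleus is reported in a ground-truth
## table (centroid, radius, voxelized volume, integrated intensity).

#' Parameters of the egg-chamber phantom
#'
#' @param age_h Chamber age in hours; sets the midsection area through
#'   `area_curve`. Alternatively give `stage` (2..14) and the age is the
#'   stage midpoint of the default timeline.
#' @param stage Optional stage id used when `age_h` is `NULL`.
#' @param voxel_size `c(x, y, z)` in um (default `c(0.17, 0.17, 3)`, the
#'   calibration regime of the source imaging; tests use coarser grids).
#' @param n_nurse_nuclei Number of nurse nuclei (<= 15, the 16-cell cyst
#'   minus the oocyte).
#' @param n_follicle_nuclei Follicle nuclei on the chamber surface.
#' @param follicle_nucleus_radius,nurse_nucleus_radius Radii in um.
#' @param oocyte_fraction Fraction of the midsection area occupied by the
#'   oocyte, in `[0, 1]`.
#' @param aspect Ratio of the anterior-posterior (x) semi-axis to the y
#'   semi-axis of the chamber ellipsoid.
#' @param area_curve [growth_curve()] mapping age to midsection area.
#' @param channel_gains Named gains for the rendered channels `histone`
#'   (all nuclei), `cortex` (chamber boundary shell) and `yolk` (oocyte).
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param nucleus_clearance_um Minimum clear gap (um) kept between nurse
#'   nuclei and between nurse nuclei and the follicle shell, so that
#'   blurred masks of neighbouring nuclei remain separable.
#' @param seed Integer seed.
#' @return A `chamber_phantom_params` list.
#' @export
chamber_phantom_params <- function(age_h = NULL, stage = 8L,
                                   voxel_size = c(0.17, 0.17, 3),
                                   n_nurse_nuclei = 15L,
                                   n_follicle_nuclei = 80L,
                                   follicle_nucleus_radius = 2.5,
                                   nurse_nucleus_radius = 5,
                                   oocyte_fraction = 0.30,
                                   aspect = 1.3,
                                   area_curve = growth_curve(273, 0.06, "area"),
                                   channel_gains = c(histone = 1, cortex = 1, yolk = 1),
                                   noise_sd = 0,
                                   nucleus_clearance_um = 3,
                                   seed = NULL) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers c(x, y, z)")
  if (oocyte_fraction < 0 || oocyte_fraction > 1)
    stop("`oocyte_fraction` must be in [0, 1]")
  if (n_nurse_nuclei > 15L) stop("`n_nurse_nuclei` must be <= 15")
  if (is.null(age_h)) {
    tl <- stage_durations(default_stage_frequencies(),
                          compute_total_duration(5.2, compute_epr(51.5, 35.63)))
    age_h <- stage_midpoint_age(tl, stage)
  }
  structure(list(age_h = age_h, voxel_size = voxel_size,
                 n_nurse_nuclei = as.integer(n_nurse_nuclei),
                 n_follicle_nuclei = as.integer(n_follicle_nuclei),
                 follicle_nucleus_radius = follicle_nucleus_radius,
                 nurse_nucleus_radius = nurse_nucleus_radius,
                 oocyte_fraction = oocyte_fraction, aspect = aspect,
                 nucleus_clearance_um = nucleus_clearance_um,
                 area_curve = area_curve,
                 channel_gains = channel_gains, noise_sd = noise_sd,
                 seed = seed),
            class = "chamber_phantom_params")
}

# voxel-center coordinate grids (um) for a (nz, ny, nx) grid
.coord_grids <- function(dims, voxel_size) {
  list(z = (seq_len(dims[1L]) - 0.5) * voxel_size[3L],
       y = (seq_len(dims[2L]) - 0.5) * voxel_size[2L],
       x = (seq_len(dims[3L]) - 0.5) * voxel_size[1L])
}

# logical array of voxels whose centers lie within an ellipsoid
.ellipsoid_mask <- function(dims, voxel_size, center, semi) {
  g <- .coord_grids(dims, voxel_size)
  dz2 <- ((g$z - center[1L]) / semi[1L])^2
  dy2 <- ((g$y - center[2L]) / semi[2L])^2
  dx2 <- ((g$x - center[3L]) / semi[3L])^2
  outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
}

# add a voxelized sphere to a logical array; returns updated mask and count
.sphere_voxels <- function(dims, voxel_size, center, radius) {
  lo <- pmax(1L, floor((center - radius) / voxel_size[c(3, 2, 1)]) + 1L)
  hi <- pmin(dims, ceiling((center + radius) / voxel_size[c(3, 2, 1)]))
  if (any(lo > hi)) return(integer(0))
  zr <- lo[1L]:hi[1L]; yr <- lo[2L]:hi[2L]; xr <- lo[3L]:hi[3L]
  zc <- (zr - 0.5) * voxel_size[3L]
  yc <- (yr - 0.5) * voxel_size[2L]
  xc <- (xr - 0.5) * voxel_size[1L]
  d2 <- outer(outer((zc - center[1L])^2, (yc - center[2L])^2, `+`),
              (xc - center[3L])^2, `+`)
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  if (!nrow(inside)) return(integer(0))
  (zr[inside[, 1L]]) +
    dims[1L] * ((yr[inside[, 2L]]) - 1L) +
    dims[1L] * dims[2L] * ((xr[inside[, 3L]]) - 1L)
}

#' Render a synthetic egg-chamber stack with ground truth
#'
#' Builds the chamber geometry from the phantom parameters, renders the
#' `histone`, `cortex` and `yolk` channels, and returns exact ground truth
#' for every nucleus and compartment. The oocyte occupies the posterior
#' part of the chamber, cut so that its share of the midsection-slice area
#' equals `oocyte_fraction` to within one pixel row.
#'
#' @param params A [chamber_phantom_params()].
#' @return A list with `stack` ([image_stack()]), `labels` (a
#'   `label_volume` of all nuclei, ground-truth table included), `truth`
#'   (per-nucleus data frame: id, type, centroid_z/y/x in um, radius_um,
#'   voxel_count, volume_um3, integrated_intensity), and `masks` (logical
#'   arrays: chamber, oocyte, nuclei, follicle, nurse_region).
#' @export
simulate_chamber_stack <- function(params) {
  stopifnot(inherits(params, "chamber_phantom_params"))
  .eval_with_seed(params$seed, function() {
    vs <- params$voxel_size
    A <- predict(params$area_curve, params$age_h)
    a_x <- sqrt(A * params$aspect / pi)       # AP semi-axis (um)
    b_y <- a_x / params$aspect
    c_z <- b_y
    margin <- 2 * params$follicle_nucleus_radius + 2
    dims <- c(ceiling(2 * (c_z + margin) / vs[3L]),
              ceiling(2 * (b_y + margin) / vs[2L]),
              ceiling(2 * (a_x + margin) / vs[1L]))
    center <- c(dims[1L] * vs[3L], dims[2L] * vs[2L], dims[3L] * vs[1L]) / 2
    semi <- c(c_z, b_y, a_x)                  # (z, y, x) order

    chamber <- .ellipsoid_mask(dims, vs, center, semi)
    if (!any(chamber)) stop("grid too small to contain the chamber ellipsoid")

    # oocyte: posterior voxels beyond an x-cut chosen on the midsection slice
    mid_z <- which.max(vapply(seq_len(dims[1L]),
                              function(z) sum(chamber[z, , ]), numeric(1)))
    sl <- chamber[mid_z, , ]
    col_counts <- colSums(sl)
    # fraction of midsection pixels at or beyond each candidate x-cut;
    # pick the column boundary closest to the requested oocyte fraction
    frac_from <- rev(cumsum(rev(col_counts))) / sum(col_counts)
    oocyte <- array(FALSE, dim = dims)
    if (params$oocyte_fraction > 0) {
      x_cut_px <- which.min(abs(frac_from - params$oocyte_fraction))
      g <- .coord_grids(dims, vs)
      oocyte <- chamber & outer(outer(rep(TRUE, dims[1L]), rep(TRUE, dims[2L])),
                                g$x >= g$x[x_cut_px])
    }

    # follicle nuclei on the ellipsoid surface (Fibonacci lattice)
    nf <- params$n_follicle_nuclei
    i <- seq_len(nf) - 0.5
    phi <- acos(1 - 2 * i / nf)
    theta <- pi * (1 + sqrt(5)) * i
    fc <- cbind(z = center[1L] + semi[1L] * cos(phi),
                y = center[2L] + semi[2L] * sin(phi) * sin(theta),
                x = center[3L] + semi[3L] * sin(phi) * cos(theta))

    # nurse nuclei: random non-overlapping spheres in the anterior interior,
    # kept `clearance` um away from each other and from the follicle shell so
    # blur-dilated masks stay separable
    rn <- params$nurse_nucleus_radius
    clearance <- params$nucleus_clearance_um
    inner <- .ellipsoid_mask(dims, vs, center,
                             pmax(semi - rn - params$follicle_nucleus_radius -
                                    clearance, 1))
    anterior_ok <- inner & !oocyte
    # stay clear of the oocyte border by one nurse-nucleus radius
    if (any(oocyte)) {
      g <- .coord_grids(dims, vs)
      x_border <- min(g$x[apply(oocyte, 3, any)])
      anterior_ok <- anterior_ok &
        outer(outer(rep(TRUE, dims[1L]), rep(TRUE, dims[2L])), g$x < x_border - rn)
    }
    cand <- which(anterior_ok)
    nn <- params$n_nurse_nuclei
    nc <- matrix(NA_real_, nrow = max(nn, 1L), ncol = 3L)
    fail_msg <- paste0("could not place ", nn, " non-overlapping nurse ",
                       "nuclei of radius ", rn,
                       " um in the anterior compartment after bounded retries")
    if (nn > 0L) {
      if (!length(cand)) stop(fail_msg)
      # greedy farthest-point placement over a seeded candidate subsample:
      # start at a random admissible voxel, then repeatedly take the
      # candidate farthest from all placed nuclei. Near the packing
      # capacity this succeeds wherever a packing exists, where plain
      # rejection sampling is seed-fragile.
      sub <- cand[sample.int(length(cand), size = min(length(cand), 4000L))]
      zc <- ((sub - 1L) %% dims[1L]) + 1L
      yc <- (((sub - 1L) %/% dims[1L]) %% dims[2L]) + 1L
      xc <- ((sub - 1L) %/% (dims[1L] * dims[2L])) + 1L
      pts <- cbind((zc - 0.5) * vs[3L], (yc - 0.5) * vs[2L],
                   (xc - 0.5) * vs[1L])
      min_sep <- 2 * rn + clearance
      greedy_from <- function(first) {
        out <- matrix(NA_real_, nrow = nn, ncol = 3L)
        mind <- rep(Inf, nrow(pts))
        for (k in seq_len(nn)) {
          p <- if (k == 1L) pts[first, ] else pts[which.max(mind), ]
          out[k, ] <- p
          mind <- pmin(mind, sqrt((pts[, 1L] - p[1L])^2 +
                                    (pts[, 2L] - p[2L])^2 +
                                    (pts[, 3L] - p[3L])^2))
          if (k < nn && max(mind) < min_sep) return(NULL)
        }
        out
      }
      # restart from the extreme candidates first (near-optimal packings
      # start at the boundary), then a few random starts
      starts <- unique(c(which.min(pts[, 3L]), which.max(pts[, 3L]),
                         which.min(pts[, 2L]), which.max(pts[, 2L]),
                         which.min(pts[, 1L]), which.max(pts[, 1L]),
                         sample.int(nrow(pts), min(nrow(pts), 8L))))
      sol <- NULL
      for (f in starts) {
        sol <- greedy_from(f)
        if (!is.null(sol)) break
      }
      if (is.null(sol)) stop(fail_msg)
      nc[seq_len(nn), ] <- sol
    }
    nc <- nc[seq_len(nn), , drop = FALSE]

    # voxelize all nuclei, build labels and truth
    labels <- array(0L, dim = dims)
    truth <- data.frame()
    all_centers <- rbind(fc[, c("z", "y", "x")], nc)
    radii <- c(rep(params$follicle_nucleus_radius, nf), rep(rn, nn))
    types <- c(rep("follicle", nf), rep("nurse", nn))
    gain_h <- params$channel_gains[["histone"]]
    base <- 100
    for (k in seq_len(nrow(all_centers))) {
      idx <- .sphere_voxels(dims, vs, all_centers[k, ], radii[k])
      idx <- idx[labels[idx] == 0L]
      labels[idx] <- k
      truth <- rbind(truth, data.frame(
        id = k, type = types[k],
        centroid_z_um = all_centers[k, 1L],
        centroid_y_um = all_centers[k, 2L],
        centroid_x_um = all_centers[k, 3L],
        radius_um = radii[k],
        voxel_count = length(idx),
        volume_um3 = length(idx) * voxel_volume(vs),
        integrated_intensity = gain_h * base * length(idx)))
    }
    nuclei <- labels > 0L

    # channels
    cortex_shell <- chamber & !.ellipsoid_mask(dims, vs, center, pmax(semi - 1.5, 0.5))
    histone <- array(0, dim = dims); histone[nuclei] <- gain_h * base
    cortex <- array(0, dim = dims)
    cortex[cortex_shell] <- params$channel_gains[["cortex"]] * base
    yolk <- array(0, dim = dims)
    yolk[oocyte] <- params$channel_gains[["yolk"]] * base
    if (params$noise_sd > 0) {
      histone <- histone + stats::rnorm(length(histone), sd = params$noise_sd)
      cortex <- cortex + stats::rnorm(length(cortex), sd = params$noise_sd)
      yolk <- yolk + stats::rnorm(length(yolk), sd = params$noise_sd)
    }
    stack <- image_stack(list(histone = histone, cortex = cortex, yolk = yolk), vs)

    vv <- voxel_volume(vs)
    sizes <- tabulate(labels[nuclei], nbins = nrow(all_centers))
    lv <- structure(list(labels = labels,
                         table = data.frame(label = seq_along(sizes),
                                            voxel_count = sizes,
                                            volume_um3 = sizes * vv,
                                            type = types),
                         voxel_size = vs),
                    class = "label_volume")
    list(stack = stack, labels = lv, truth = truth,
         masks = list(chamber = chamber, oocyte = oocyte, nuclei = nuclei,
                      follicle = labels > 0L & labels <= nf,
                      nurse_region = chamber & !oocyte & !nuclei),
         mid_z = mid_z)
  })
}
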