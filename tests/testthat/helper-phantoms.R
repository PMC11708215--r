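# Shared fixtures, built once per test run and cached. All phantoms are
# generated in code; grid sizes are kept small enough that the whole suite
# runs in well under a minute apart from the chamber-recovery cases.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# two well-separated 10-um spheres on a 0.5-um isotropic grid: large enough
# that blur-induced mask dilation (~0.15 um) is negligible against radius
two_sphere_phantom <- function() fixture("two_sphere", function() {
  vs <- c(0.5, 0.5, 0.5)
  dims <- c(60L, 60L, 120L)
  a <- array(0, dims)
  centers <- list(c(15, 15, 15), c(15, 15, 45))
  idx <- lapply(centers, function(cc)
    ovoquant:::.sphere_voxels(dims, vs, cc, 10))
  for (i in idx) a[i] <- 100
  list(stack = a, voxel_size = vs, radius = 10, centers = centers,
       voxel_counts = lengths(idx))
})

# a small zero-noise chamber phantom used across segmentation tests
chamber_fixture <- function() fixture("chamber", function() {
  simulate_chamber_stack(chamber_phantom_params(
    age_h = 30, voxel_size = c(0.5, 0.5, 1), n_nurse_nuclei = 3,
    n_follicle_nuclei = 40, nurse_nucleus_radius = 5,
    follicle_nucleus_radius = 4, oocyte_fraction = 0.3,
    noise_sd = 0, seed = 101))
})

# default dumping series (zero noise) shared by flux/quantification tests
dumping_fixture <- function() fixture("dumping", function() {
  simulate_dumping_series(dumping_flow_params(duration = 12, dt = 0.25))
})

# match measured components to ground-truth nuclei by nearest centroid
match_components <- function(table, truth, voxel_size) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((table$centroid_z * voxel_size[3] - truth$centroid_z_um[i])^2 +
                (table$centroid_y * voxel_size[2] - truth$centroid_y_um[i])^2 +
                (table$centroid_x * voxel_size[1] - truth$centroid_x_um[i])^2)
    which.min(d)
  }, integer(1))
}

# independent brute-force Otsu oracle: scans every candidate split of the
# same 256-bin histogram and maximizes between-class variance directly
brute_force_otsu <- function(a) {
  rng <- range(a)
  nb <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  bin <- pmin(pmax(findInterval(a, breaks, all.inside = TRUE), 1L), nb)
  counts <- tabulate(bin, nbins = nb)
  mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  n <- sum(counts)
  best_k <- NA_integer_; best_v <- -Inf
  for (k in 1:(nb - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):nb] * mids[(k + 1):nb]) / n1
    v <- (n0 / n) * (n1 / n) * (m0 - m1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_k <- k }
  }
  breaks[best_k + 1L]
}
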