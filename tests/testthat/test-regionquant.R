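test_that("oocyte totals sum raw voxels over the top half exactly", {
  a <- array(0, c(10, 12, 12))
  mask <- array(FALSE, c(10, 12, 12))
  mask[2:8, 4:9, 4:9] <- TRUE
  a[mask] <- 3.5
  v_half <- sum(mask[1:5, , ])
  expect_equal(oocyte_total_intensity(a, mask, midsection_z = 5), 3.5 * v_half)
  # subset monotonicity in the midsection bound
  t4 <- oocyte_total_intensity(a, mask, 4)
  t8 <- oocyte_total_intensity(a, mask, 8)
  expect_lte(t4, t8)
  expect_error(oocyte_total_intensity(a, array(FALSE, c(10, 12, 12)), 5),
               "empty")
})

test_that("constant-rate yolk accumulation is recovered from rendered frames", {
  # frames with oocyte intensity growing linearly at `rate` per hour
  ph <- chamber_fixture()
  oo <- ph$masks$oocyte
  rate <- 240            # intensity units / h over the whole oocyte
  times <- seq(0, 6, by = 1)
  follicle <- ph$masks$follicle
  totals <- vapply(times, function(t) {
    a <- array(0, dim(oo))
    a[oo] <- rate * t / sum(oo)
    a[follicle] <- 20
    raw <- oocyte_total_intensity(a, oo, midsection_z = ph$mid_z)
    normalize_by_follicle(raw, follicle, a, mode = "total")[1]
  }, numeric(1))
  fit <- stats::lm(totals ~ times)
  ref_total <- 20 * sum(follicle)
  expect_equal(unname(stats::coef(fit)[2]), rate / ref_total,
               tolerance = 0.05)
  resid <- stats::residuals(fit)
  expect_lt(max(abs(resid)), 1e-9 * max(totals))
})

test_that("follicle normalization cancels global gains exactly", {
  ds <- dumping_fixture()
  fr <- ds$frames[[6]]
  a <- stack_channel(fr, "histone")
  fol <- ds$geometry$follicle
  raw <- sum(a[ds$geometry$ao])
  n1 <- normalize_by_follicle(raw, fol, a, mode = "total")
  n2 <- normalize_by_follicle(raw * 3.7, fol, a * 3.7, mode = "total")
  expect_equal(as.numeric(n2), as.numeric(n1), tolerance = 1e-12)
  n3 <- normalize_by_follicle(mean(a[ds$geometry$ao]), fol, a, mode = "mean")
  n4 <- normalize_by_follicle(mean(a[ds$geometry$ao]) * 0.2, fol, a * 0.2,
                              mode = "mean")
  expect_equal(as.numeric(n4), as.numeric(n3), tolerance = 1e-12)
  expect_error(normalize_by_follicle(raw, fol, a * 0, mode = "mean"),
               "zero")
})

test_that("synthetic bleaching leaves normalized static series flat", {
  ds <- simulate_dumping_series(dumping_flow_params(
    k_nuc_out = 0, k_ncc_ao = 0, k_ao_po = 0, nuclear_shrink_rate = 0,
    duration = 4, dt = 1))
  fol <- ds$geometry$follicle
  nuc <- ds$geometry$nuclei_by_frame[[1]]
  vals <- vapply(seq_along(ds$frames), function(i) {
    decay <- exp(-0.3 * ds$times[i])
    a <- stack_channel(ds$frames[[i]], "histone") * decay
    normalize_by_follicle(sum(a[nuc]), fol, a, mode = "total")[1]
  }, numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 1e-12)
})

test_that("regional ROIs satisfy their defining constraints on the phantom", {
  ds <- dumping_fixture()
  geo <- ds$geometry
  geometry <- list(chamber = geo$chamber, oocyte = geo$oocyte,
                   nuclei = geo$nuclei_by_frame[[1]], follicle = geo$follicle)
  vs <- ds$frames[[1]]$voxel_size
  rois <- lapply(c("NCC", "AO", "PO"), function(rg)
    place_region_roi(ds$frames[[1]], region_spec(rg), geometry))
  names(rois) <- c("NCC", "AO", "PO")
  for (rg in names(rois)) {
    roi <- rois[[rg]]
    ys <- roi$y:(roi$y + roi$edge_px - 1L)
    xs <- roi$x:(roi$x + roi$edge_px - 1L)
    # nuclear-free in every sampled slice
    expect_equal(sum(geometry$nuclei[roi$z_slices, ys, xs]), 0)
  }
  # containment in the ground-truth compartments at the sampled slices
  ncc <- rois$NCC
  expect_true(all(geo$ncc[ncc$z_slices,
                          ncc$y:(ncc$y + ncc$edge_px - 1L),
                          ncc$x:(ncc$x + ncc$edge_px - 1L)] |
                    !geo$chamber[ncc$z_slices,
                                 ncc$y:(ncc$y + ncc$edge_px - 1L),
                                 ncc$x:(ncc$x + ncc$edge_px - 1L)]))
  ao <- rois$AO
  expect_true(all(geo$oocyte[ao$z_slices,
                             ao$y:(ao$y + ao$edge_px - 1L),
                             ao$x:(ao$x + ao$edge_px - 1L)]))
  po <- rois$PO
  expect_true(all(geo$oocyte[po$z_slices,
                             po$y:(po$y + po$edge_px - 1L),
                             po$x:(po$x + po$edge_px - 1L)]))
  # AO centre near the nurse-oocyte interface, PO centre posterior of AO
  x_interface_um <- min(which(apply(geo$oocyte, 3, any))) * vs[["x"]]
  expect_lte(ao$center_x_um - x_interface_um, 17 + vs[["x"]])
  expect_gt(po$center_x_um, ao$center_x_um)
  # impossible constraints are reported with the region name
  tight <- region_spec("AO", max_distance_um = 0.01)
  expect_error(place_region_roi(ds$frames[[1]], tight, geometry), "AO")
})

test_that("dumping phantom time series reproduce the compartment dynamics", {
  ds <- dumping_fixture()
  rs <- region_timeseries(ds, frame_stride = 5)
  ncn <- rs$normalized[rs$region == "NCN"]
  ncc <- rs$normalized[rs$region == "NCC"]
  ao <- rs$normalized[rs$region == "AO"]
  po <- rs$normalized[rs$region == "PO"]
  expect_true(all(diff(ncn) < 0))
  # NCC and AO rise then fall
  expect_gt(which.max(ncc), 1); expect_lt(which.max(ncc), length(ncc))
  expect_gt(which.max(ao), 1); expect_lt(which.max(ao), length(ao))
  # posterior accumulation peaks later than anterior
  expect_gt(which.max(po), which.max(ao))
  # NCC peaks before AO (the signal flows anterior-ward)
  expect_lte(which.max(ncc), which.max(ao))
})

test_that("static phantom gives flat normalized series", {
  ds <- simulate_dumping_series(dumping_flow_params(
    k_nuc_out = 0, k_ncc_ao = 0, k_ao_po = 0, nuclear_shrink_rate = 0,
    duration = 4, dt = 1))
  rs <- region_timeseries(ds, frame_stride = 2)
  for (rg in unique(rs$region)) {
    v <- rs$normalized[rs$region == rg]
    expect_lt(diff(range(v)), 1e-9 * max(1, mean(v)))
  }
})

test_that("nuclear concentration follows the volume/intensity rate balance", {
  t <- seq(0, 5, by = 0.5)
  tot <- 1000 * exp(-0.4 * t)
  # volume decays faster than intensity: concentration increases
  conc_up <- nuclear_concentration_series(tot, 500 * exp(-0.7 * t), t)
  expect_true(all(diff(conc_up$concentration) > 0))
  # equal rates: constant concentration
  conc_const <- nuclear_concentration_series(tot, 500 * exp(-0.4 * t), t)
  expect_equal(diff(range(conc_const$concentration)), 0, tolerance = 1e-9)
  # zero shrink: concentration tracks the total
  conc_decay <- nuclear_concentration_series(tot, rep(500, length(t)), t)
  expect_equal(conc_decay$concentration, tot / 500)
  # vanished label terminates the series with a flag
  vol <- c(500, 250, 0, 0)
  out <- nuclear_concentration_series(c(10, 5, 2, 1), vol, 1:4)
  expect_equal(nrow(out), 2L)
  expect_true(attr(out, "terminated"))
})
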