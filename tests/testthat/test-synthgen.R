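test_that("surveys are deterministic given a seed and validate their inputs", {
  p <- survey_params(n_females = 8L, seed = 5)
  s1 <- simulate_survey(p)
  s2 <- simulate_survey(p)
  expect_identical(s1$females, s2$females)
  expect_identical(s1$chambers, s2$chambers)
  s3 <- simulate_survey(survey_params(n_females = 8L, seed = 6))
  expect_false(identical(s1$chambers, s3$chambers))
  bad_f <- default_stage_frequencies() * 1.01
  expect_error(survey_params(stage_frequencies = bad_f), "sum to 1")
})

test_that("zero-noise single-stage survey puts every area on the curve", {
  f <- c(rep(0, 6), 1, rep(0, 6)); names(f) <- 2:14  # all mass on stage 8
  p <- survey_params(n_females = 4L, stage_frequencies = f,
                     area_noise_cv = 0, seed = 9)
  s <- simulate_survey(p)
  expect_true(all(s$chambers$stage == 8L))
  mid8 <- stage_midpoint_age(s$timeline, 8L)
  expect_equal(unique(s$chambers$age_h), mid8)
  expect_equal(s$chambers$midsection_area_um2,
               rep(predict(p$area_curve, mid8), nrow(s$chambers)))
})

test_that("empirical survey means match the generative means at large n", {
  s <- simulate_survey(survey_params(n_females = 10000L, seed = 13))
  expect_lt(abs(mean(s$females$ovariole_count) / 35.63 - 1), 0.02)
  expect_lt(abs(mean(s$females$eggs_24h) / 51.5 - 1), 0.02)
  chambers_per_ov <- nrow(s$chambers) / sum(s$females$ovariole_count)
  expect_lt(abs(chambers_per_ov / 5.2 - 1), 0.02)
  f <- stage_frequencies(s)
  expect_lt(max(abs(f - default_stage_frequencies())), 0.01)
})

test_that("surveys round-trip through CSV", {
  s <- simulate_survey(survey_params(n_females = 4L, seed = 2))
  dir <- withr::local_tempdir()
  write_survey(s, dir)
  s2 <- read_survey(dir)
  expect_equal(s2$females, s$females)
  expect_equal(s2$chambers, s$chambers, tolerance = 1e-12)
})

test_that("chamber phantom honors geometry ground truth", {
  ph <- chamber_fixture()
  # oocyte share of the midsection slice
  mid <- ph$mid_z
  frac <- sum(ph$masks$oocyte[mid, , ]) / sum(ph$masks$chamber[mid, , ])
  expect_equal(frac, 0.30, tolerance = 0.02)
  # labels and rendered stack share the grid
  expect_identical(dim(ph$labels$labels), dim(ph$stack$channels$histone))
  # single isolated nurse nucleus volume close to the analytic sphere
  nurse <- ph$truth[ph$truth$type == "nurse", ]
  expect_equal(nurse$volume_um3, rep(4 / 3 * pi * 5^3, nrow(nurse)),
               tolerance = 0.05)
  # determinism
  ph2 <- simulate_chamber_stack(chamber_phantom_params(
    age_h = 30, voxel_size = c(0.5, 0.5, 1), n_nurse_nuclei = 3,
    n_follicle_nuclei = 40, nurse_nucleus_radius = 5,
    follicle_nucleus_radius = 4, oocyte_fraction = 0.3,
    noise_sd = 0, seed = 101))
  expect_identical(ph2$stack$channels$histone, ph$stack$channels$histone)
  expect_identical(ph2$truth, ph$truth)
})

test_that("isolated voxelized sphere matches the analytic volume", {
  p <- chamber_phantom_params(age_h = 25, voxel_size = c(1, 1, 1),
                              n_nurse_nuclei = 1, n_follicle_nuclei = 20,
                              nurse_nucleus_radius = 5,
                              follicle_nucleus_radius = 2,
                              noise_sd = 0, seed = 4)
  ph <- simulate_chamber_stack(p)
  v <- ph$truth$volume_um3[ph$truth$type == "nurse"]
  expect_equal(v, 4 / 3 * pi * 125, tolerance = 0.05)
})

test_that("channel gains scale ground-truth integrated intensities exactly", {
  base <- chamber_phantom_params(age_h = 25, voxel_size = c(1, 1, 1),
                                 n_nurse_nuclei = 2, n_follicle_nuclei = 20,
                                 nurse_nucleus_radius = 4,
                                 follicle_nucleus_radius = 2, seed = 8)
  doubled <- base
  doubled$channel_gains <- c(histone = 2, cortex = 2, yolk = 2)
  ph1 <- simulate_chamber_stack(base)
  ph2 <- simulate_chamber_stack(doubled)
  expect_equal(ph2$truth$integrated_intensity,
               2 * ph1$truth$integrated_intensity)
  expect_equal(ph2$stack$channels$histone, 2 * ph1$stack$channels$histone)
})

test_that("impossible nurse-nucleus packing errors with the constraint named", {
  p <- chamber_phantom_params(age_h = 10, voxel_size = c(1, 1, 2),
                              n_nurse_nuclei = 15, n_follicle_nuclei = 10,
                              nurse_nucleus_radius = 6, seed = 1)
  expect_error(simulate_chamber_stack(p), "non-overlapping nurse nuclei")
})

test_that("dumping chain conserves total signal and obeys closed forms", {
  p <- dumping_flow_params(k_nuc_out = 0.8, k_ncc_ao = 0.5, k_ao_po = 0.3,
                           duration = 10, dt = 0.5)
  x <- dumping_compartment_totals(p)
  expect_equal(colSums(x), rep(p$initial_nuclear_total, ncol(x)),
               tolerance = 1e-9)
  # no flow: all totals constant
  p0 <- dumping_flow_params(k_nuc_out = 0, k_ncc_ao = 0, k_ao_po = 0,
                            duration = 5, dt = 1)
  x0 <- dumping_compartment_totals(p0)
  expect_true(all(x0["nuclei", ] == p0$initial_nuclear_total))
  expect_true(all(x0[c("ncc", "ao", "po"), ] == 0))
  # single transfer: closed-form exponential exchange
  p1 <- dumping_flow_params(k_nuc_out = 0.6, k_ncc_ao = 0, k_ao_po = 0,
                            duration = 8, dt = 0.25)
  t <- seq(0, 8, by = 0.25)
  x1 <- dumping_compartment_totals(p1)
  expect_equal(x1["nuclei", ], p1$initial_nuclear_total * exp(-0.6 * t),
               tolerance = 1e-9)
  expect_equal(x1["ncc", ], p1$initial_nuclear_total * (1 - exp(-0.6 * t)),
               tolerance = 1e-9)
})

test_that("matrix-exponential solution agrees with Euler and deSolve", {
  p <- dumping_flow_params(k_nuc_out = 0.8, k_ncc_ao = 0.5, k_ao_po = 0.3,
                           duration = 6, dt = 0.01)
  exact <- dumping_compartment_totals(p, times = c(0, 2, 4, 6))
  euler <- dumping_compartment_totals(p, times = c(0, 2, 4, 6),
                                      method = "euler")
  expect_equal(euler, exact, tolerance = 0.02)
  skip_if_not_installed("deSolve")
  A <- ovoquant:::.dumping_rate_matrix(p)
  sol <- deSolve::ode(y = c(p$initial_nuclear_total, 0, 0, 0),
                      times = c(0, 2, 4, 6),
                      func = function(t, y, parms) list(as.numeric(A %*% y)),
                      parms = NULL)
  expect_equal(unname(t(sol[, -1])), unname(exact), tolerance = 1e-6)
  # Euler stability guard
  pbad <- dumping_flow_params(k_nuc_out = 0.9, duration = 4, dt = 2)
  expect_error(dumping_compartment_totals(pbad, method = "euler"), "unstable")
})

test_that("posterior accumulation trails the anterior compartment", {
  p <- dumping_flow_params(k_nuc_out = 0.8, k_ncc_ao = 0.5, k_ao_po = 0.3,
                           duration = 12, dt = 0.1)
  x <- dumping_compartment_totals(p)
  t <- seq(0, 12, by = 0.1)
  t_ao_peak <- t[which.max(x["ao", ])]
  # the PO inflow is k * AO, so its rate peaks with AO (never earlier) and
  # the PO level itself keeps climbing well past the AO maximum
  po_rate <- diff(x["po", ]) / diff(t)
  t_po_rate_peak <- t[-1][which.max(po_rate)]
  expect_gte(t_po_rate_peak, t_ao_peak)
  expect_gt(t[which.max(x["po", ])], t_ao_peak)
  # PO lags AO at every level crossing during the rise
  expect_true(all(x["po", t <= t_ao_peak] <= x["ao", t <= t_ao_peak]))
})

test_that("rendered dumping frames are consistent with the exact truth", {
  ds <- dumping_fixture()
  tr <- ds$truth
  cons <- rowSums(tr[, c("nuclei_total", "ncc_total", "ao_total", "po_total")])
  expect_equal(cons, rep(ds$params$initial_nuclear_total, nrow(tr)),
               tolerance = 1e-6)
  expect_true(all(diff(tr$nuclei_total) < 0))
  expect_true(all(diff(tr$nuclear_volume_um3) <= 0))
  # frame intensities integrate back to the compartment totals
  g <- ds$geometry
  f10 <- stack_channel(ds$frames[[10]], "histone")
  expect_equal(sum(f10[g$ncc]), tr$ncc_total[10], tolerance = 1e-9)
  expect_equal(sum(f10[g$ao]), tr$ao_total[10], tolerance = 1e-9)
  expect_equal(sum(f10[g$nuclei_by_frame[[10]]]), tr$nuclei_total[10],
               tolerance = 1e-9)
})

test_that("rotation tracks obey the circular geometry they advertise", {
  # omega = 0: static positions
  ts0 <- simulate_rotation_track(0, 30, duration = 1, dt = 0.25, seed = 3)
  expect_equal(length(unique(round(ts0$tracks$y_um, 12))),
               length(unique(ts0$tracks$cell_id)))
  # determinism
  a <- simulate_rotation_track(28.5, 30, duration = 1, dt = 1 / 6,
                               speed_noise_sd = 0.05, seed = 21)
  b <- simulate_rotation_track(28.5, 30, duration = 1, dt = 1 / 6,
                               speed_noise_sd = 0.05, seed = 21)
  expect_identical(a$tracks, b$tracks)
  expect_error(simulate_rotation_track(28.5, -1), "> 0")
  # noise-free mean speed matches the arc-length formula
  ts <- simulate_rotation_track(28.5, 30, duration = 0.5, dt = 1 / 60)
  expect_equal(mean_speed(ts), 28.5 * pi / 180 * 30 / 60, tolerance = 0.01)
})

test_that("tracks round-trip through CSV + geometry JSON", {
  ts <- simulate_rotation_track(28.5, 25, duration = 1, dt = 0.25, seed = 17)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_tracks(ts, csv, js)
  ts2 <- read_tracks(csv, js)
  expect_equal(ts2$tracks, ts$tracks, tolerance = 1e-12)
  expect_equal(ts2$geometry$r, 25)
})
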