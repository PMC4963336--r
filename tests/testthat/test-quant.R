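test_that("decay correction matches the closed form and inverts exactly", {
  expect_identical(decay_factor(0, 360.4), 1)
  expect_equal(decay_factor(360.4, 360.4), 2)
  # mean injection-to-acquisition delay of the cohort, against an
  # independent exponential-form evaluation
  expect_equal(decay_factor(231, 360.4), exp(log(2) * 231 / 360.4),
               tolerance = 1e-12)
  for (dt in c(-100, 0, 33.7, 231, 1000)) {
    expect_equal(decay_factor(dt, 360.4) * decay_factor(-dt, 360.4), 1,
                 tolerance = 1e-12)
  }
  expect_error(decay_factor(10, 0), "half-life")
})

test_that("net injected activity decays prepared and residual terms to injection time", {
  m <- acquisition_meta(prepared_activity_MBq = 600, t_prepared_min = 0,
                        t_injection_min = 0, t_acquisition_start_min = 200,
                        body_weight_kg = 70)
  expect_equal(net_injected_activity(m), 600)
  m <- acquisition_meta(prepared_activity_MBq = 600, t_prepared_min = -360.4,
                        t_injection_min = 0, t_acquisition_start_min = 200,
                        body_weight_kg = 70)
  expect_equal(net_injected_activity(m), 300)
  # two-term formula evaluated independently
  m <- acquisition_meta(prepared_activity_MBq = 600, t_prepared_min = -30,
                        residual_activity_MBq = 20, t_residual_min = 5,
                        t_injection_min = 0, t_acquisition_start_min = 231,
                        body_weight_kg = 70)
  expected <- 600 * 2^(-30 / 360.4) - 20 * 2^(5 / 360.4)
  expect_equal(net_injected_activity(m), expected, tolerance = 1e-12)
  # residual exceeding the decayed prepared activity is impossible
  m_bad <- acquisition_meta(prepared_activity_MBq = 600, t_prepared_min = -5000,
                            residual_activity_MBq = 500, t_residual_min = 0,
                            t_injection_min = 0, t_acquisition_start_min = 10,
                            body_weight_kg = 70)
  expect_error(net_injected_activity(m_bad), "non-positive")
})

test_that("counts convert to injection-time concentration and back through the forward model", {
  g <- grid_geometry(c(4, 4, 4), 10)  # 1 mL voxels
  meta <- acquisition_meta(prepared_activity_MBq = 500, t_prepared_min = 0,
                           t_injection_min = 0, t_acquisition_start_min = 0,
                           body_weight_kg = 70, calibration_factor = 10,
                           dwell_time_s = 15)
  counts <- uptake_volume(array(150, g$shape), g, "counts")
  conc <- counts_to_concentration(counts, meta)
  expect_equal(unique(as.vector(conc$data)), 1.0)
  expect_identical(conc$units, "kBq/mL")
  zero <- counts_to_concentration(uptake_volume(array(0, g$shape), g, "counts"), meta)
  expect_true(all(zero$data == 0))
  # noiseless phantom round trip: painted 5 kBq/mL recovered to 1e-9
  meta2 <- acquisition_meta(prepared_activity_MBq = 500, t_prepared_min = 0,
                            t_injection_min = 0, t_acquisition_start_min = 231,
                            body_weight_kg = 70)
  painted <- uptake_volume(array(5, g$shape), g, "kBq/mL")
  lam <- simulate_counts(painted, meta2, noiseless = TRUE)
  back <- counts_to_concentration(lam, meta2)
  expect_equal(as.vector(back$data), rep(5, 64), tolerance = 1e-9)
})

test_that("SUV normalization follows the body-weight convention and round-trips", {
  g <- grid_geometry(c(3, 3, 3), 10)
  conc <- uptake_volume(array(5, g$shape), g, "kBq/mL")
  suv <- concentration_to_suv(conc, a_net_MBq = 500, weight_kg = 70)
  expect_equal(unique(as.vector(suv$data)), 0.7)  # 5 * 70000 g / 500000 kBq
  expect_identical(suv$units, "SUV")
  expect_true(all(concentration_to_suv(
    uptake_volume(array(0, g$shape), g, "kBq/mL"), 500, 70)$data == 0))
  # subject P001-style values: invert SUV 5.6 and re-apply
  w <- 95; a <- 656
  c_val <- 5.6 * a / w
  suv2 <- concentration_to_suv(uptake_volume(array(c_val, g$shape), g, "kBq/mL"), a, w)
  expect_equal(unique(as.vector(suv2$data)), 5.6, tolerance = 1e-12)
  expect_error(concentration_to_suv(conc, 0, 70), "positive")
  expect_error(concentration_to_suv(conc, 500, -1), "positive")
})

test_that("voi_mask matches exhaustive membership and flags degenerate VOIs", {
  g <- grid_geometry(c(11, 11, 11), 2)
  # sub-voxel ellipsoid catches exactly the central voxel
  v1 <- ellipsoid_voi("tiny", c(0, 0, 0), 0.6 * 2)
  expect_equal(sum(voi_mask(v1, g)), 1)
  # sphere vs brute-force membership loop
  set.seed(42)
  for (rep in 1:3) {
    ctr <- runif(3, -4, 4)
    ax <- runif(3, 2, 7)
    v <- ellipsoid_voi("r", ctr, ax)
    expect_identical(voi_mask(v, g), brute_voi_mask(v, g))
  }
  # fully outside the grid -> no voxel centers
  expect_error(voi_mask(ellipsoid_voi("out", c(100, 100, 100), 3), g),
               "no voxel centers")
})

test_that("VOI statistics agree with brute-force recomputation", {
  g <- grid_geometry(c(9, 9, 9), 3)
  set.seed(7)
  vol <- uptake_volume(array(runif(9^3, 0, 10), g$shape), g, "SUV")
  mask <- voi_mask(ellipsoid_voi("v", c(0, 0, 0), 9), g)
  expect_equal(suv_mean(vol, mask), mean(vol$data[mask]))
  expect_equal(suv_max(vol, mask), max(vol$data[mask]))
  u <- uptake_volume(array(2.5, g$shape), g, "SUV")
  expect_equal(suv_mean(u, mask), 2.5)
  expect_equal(suv_max(u, mask), 2.5)
  expect_error(suv_mean(vol, array(FALSE, g$shape)), "empty")
})

test_that("suv_peak equals exhaustive sphere averaging, including hot-voxel and tie cases", {
  # single hot voxel: peak = h / N_sphere with N_sphere counted by brute force
  g <- grid_geometry(c(17, 17, 17), 2.4)
  a <- array(0, g$shape); a[9, 9, 9] <- 11
  vol <- uptake_volume(a, g, "SUV")
  mask <- voi_mask(ellipsoid_voi("v", c(0, 0, 0), 10), g)
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  n_sphere <- 0
  for (i in 1:17) for (j in 1:17) for (k in 1:17) {
    if (sum(((c(i, j, k) - 9) * 2.4)^2) <= r^2) n_sphere <- n_sphere + 1
  }
  pk <- suv_peak(vol, mask)
  expect_equal(as.numeric(pk), 11 / n_sphere)
  expect_equal(attr(pk, "n_peak"), n_sphere)
  # random volumes vs the exhaustive oracle; peak never exceeds max
  set.seed(11)
  for (rep in 1:3) {
    vol <- uptake_volume(array(runif(17^3, 0, 5), g$shape), g, "SUV")
    expect_equal(as.numeric(suv_peak(vol, mask)), brute_suv_peak(vol, mask),
                 tolerance = 1e-12)
    expect_lte(as.numeric(suv_peak(vol, mask)), suv_max(vol, mask))
  }
  # homogeneous lesion larger than the sphere reports its own value
  spec <- small_phantom()
  suvmap <- build_suv_map(spec, 1)
  lmask <- voi_mask(ellipsoid_voi("l", c(0, 0, (24 - 1) / 2 * 2.4 * 0.45), 8), spec$grid)
  expect_equal(as.numeric(suv_peak(suvmap, lmask)), 20.4)
})

test_that("uptake ratio is scale-free and requires a positive reference", {
  expect_equal(uptake_ratio(20.4, 5.6), 20.4 / 5.6)
  expect_equal(uptake_ratio(20.4, 5.6), 3.643, tolerance = 1e-3)
  expect_equal(uptake_ratio(4.2, 4.2), 1.0)
  expect_equal(uptake_ratio(3 * 7.7, 3 * 2.1), uptake_ratio(7.7, 2.1))
  expect_error(uptake_ratio(5, 0), "positive")
  expect_error(uptake_ratio(5, -2), "positive")
})

test_that("SUV normalization cancels dose and weight in the full chain", {
  base <- small_phantom(n = 16L)
  alt <- small_phantom(n = 16L)
  alt$injected_activity_MBq <- c(330, 750)
  alt$subject_weight_kg <- 110
  suvs <- lapply(list(base, alt), function(sp) {
    meta <- phantom_meta(sp, 1)
    counts <- simulate_counts(build_activity_volume(sp, 1), meta, noiseless = TRUE)
    conc <- counts_to_concentration(counts, meta)
    concentration_to_suv(conc, net_injected_activity(meta), meta$body_weight_kg)$data
  })
  expect_equal(suvs[[1]], suvs[[2]], tolerance = 1e-9)
})

test_that("suv_peak never exceeds suv_max, and dominates suv_mean for unimodal uptake", {
  g <- grid_geometry(c(21, 21, 21), 2.4)
  voi <- ellipsoid_voi("big", c(0, 0, 0), 16)  # sphere r=6.2 mm fits well inside
  mask <- voi_mask(voi, g)
  set.seed(3)
  for (rep in 1:5) {
    vol <- uptake_volume(array(rexp(21^3), g$shape), g, "SUV")
    expect_lte(as.numeric(suv_peak(vol, mask)), suv_max(vol, mask))
  }
  # smooth unimodal profile: values highest around the maximum, so the
  # sphere average sits between VOI mean and max
  ctr <- c(11, 11, 11)
  prof <- array(0, g$shape)
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    prof[i, j, k] <- 10 * exp(-sum((c(i, j, k) - ctr)^2) / 40)
  }
  vol <- uptake_volume(prof, g, "SUV")
  pk <- as.numeric(suv_peak(vol, mask))
  expect_lte(pk, suv_max(vol, mask))
  expect_gte(pk, suv_mean(vol, mask))
})
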