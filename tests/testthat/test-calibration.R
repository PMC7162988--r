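test_that("crosstalk factors are recovered from single-fluorophore cells", {
  inst <- bench_inst()
  # noise-free donor-only cells: the pixel ratio is exactly alpha_BT
  sc <- generate_scene(shape = c(128, 128), n_cells = 3, stoichiometry = 1,
                       seed = 31)
  tr <- render_triplet(sc, inst, noise_free_cam())
  tr$mask <- sc$cell_label > 0
  expect_warning(ct <- crosstalk_factor(tr, "donor_only", boot_reps = 0),
                 "5 different|5 cell|recommended")
  expect_equal(ct$factor, 0.421, tolerance = 1e-12)

  # acceptor-only with shot noise at high SNR: median within 1 % of 0.110
  scs <- lapply(1:6, function(i)
    generate_scene(shape = c(96, 96), n_cells = 2, stoichiometry = 0,
                   radius_range = c(10, 14),
                   concentration_range = c(5e4, 5e5), seed = 40 + i))
  trs <- lapply(seq_along(scs), function(i) {
    tr <- render_triplet(scs[[i]], inst, camera_model(shot_noise = TRUE),
                         seed = 50 + i)
    tr$mask <- scs[[i]]$cell_label > 0
    tr
  })
  ct <- crosstalk_factor(trs, "acceptor_only", boot_reps = 50, seed = 3)
  expect_equal(ct$factor, 0.110, tolerance = 0.01)
  expect_true(is.finite(ct$sd) && ct$sd < 0.01)

  # zero sensitized emission means zero crosstalk
  tr0 <- image_triplet(matrix(100, 8, 8), matrix(0, 8, 8), matrix(1, 8, 8),
                       mask = matrix(TRUE, 8, 8))
  expect_warning(ct0 <- crosstalk_factor(tr0, "donor_only", boot_reps = 0))
  expect_equal(ct0$factor, 0)
})

test_that("the crosstalk median is invariant to per-cell intensity scaling", {
  inst <- bench_inst()
  sc <- generate_scene(shape = c(128, 128), n_cells = 5, stoichiometry = 1,
                       radius_range = c(10, 14), seed = 33)
  tr <- render_triplet(sc, inst, noise_free_cam())
  tr$mask <- sc$cell_label > 0
  # rescale each cell by a different factor
  gain <- matrix(1, 128, 128)
  for (i in 1:5) gain[sc$cell_label == i] <- i
  tr2 <- image_triplet(tr$I_DD * gain, tr$I_DA * gain, tr$I_AA * gain,
                       mask = tr$mask, labels = sc$cell_label)
  ct1 <- crosstalk_factor(tr, "donor_only", boot_reps = 0)
  ct2 <- crosstalk_factor(tr2, "donor_only", boot_reps = 0)
  expect_equal(ct1$factor, ct2$factor, tolerance = 1e-12)
})

test_that("crosstalk-corrected sensitized emission nulls pure samples", {
  tr <- image_triplet(matrix(50, 2, 2), matrix(70, 2, 2), matrix(90, 2, 2))
  expect_equal(corrected_fret_image(tr, 0, 0), tr$I_DA)

  inst <- bench_inst()
  f <- true_correction_factors(inst)
  ei <- expected_intensities(1000, 0, 0, inst)       # donor-only pixel
  expect_equal(ei$I_DA - f$alpha_BT * ei$I_DD - f$delta_DE * ei$I_AA, 0,
               tolerance = 1e-10)
  ei <- expected_intensities(0, 1000, 0, inst)       # acceptor-only pixel
  expect_equal(ei$I_DA - f$alpha_BT * ei$I_DD - f$delta_DE * ei$I_AA, 0,
               tolerance = 1e-10)
})

test_that("the plane fit recovers the generating factors exactly", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  px <- add_idacorr(make_pixels(inst, c(0.35, 0.42, 0.50), 500), f)
  fit <- fit_plane(px, S0 = 0.5)
  expect_equal(fit$gamma_M, 2.10, tolerance = 1e-10)
  expect_equal(fit$beta_X, 1.167, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # a single FRET level is a line in the 3D space: no unique plane
  one <- add_idacorr(make_pixels(inst, 0.42, 500), f)
  expect_error(fit_plane(one, 0.5), "FRET range insufficient")

  expect_error(fit_plane(px, S0 = 0), "inside \\(0, 1\\)")
  expect_error(fit_plane(px, S0 = 1), "inside \\(0, 1\\)")

  # a 2 donor : 1 acceptor standard determines the same instrument factors
  px2 <- add_idacorr(make_pixels(inst, c(0.35, 0.42, 0.50), 500, S = 2 / 3),
                     f)
  fit2 <- fit_plane(px2, S0 = 2 / 3)
  expect_equal(fit2$gamma_M, fit$gamma_M, tolerance = 1e-10)
  expect_equal(fit2$beta_X, fit$beta_X, tolerance = 1e-10)
})

test_that("plane-fit recovery holds over randomized instruments", {
  withr::with_seed(77, {
    for (i in 1:12) {
      g <- runif(1, 0.5, 4); b <- runif(1, 0.5, 4)
      inst <- instrument_from_factors(runif(1, 0, 0.5), runif(1, 0, 0.2),
                                      g, b)
      f <- true_correction_factors(inst)
      E2 <- sort(runif(2, 0.2, 0.7))
      if (diff(E2) < 0.1) E2[2] <- E2[1] + 0.1
      px <- add_idacorr(make_pixels(inst, E2, 400, seed = 100 + i), f)
      fit <- fit_plane(px, 0.5)
      expect_equal(fit$gamma_M, g, tolerance = 1e-8)
      expect_equal(fit$beta_X, b, tolerance = 1e-8)
    }
  })
})

test_that("plane fit is asymptotically unbiased under shot noise", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  # SNR >= 30 corresponds to >= 900 expected photons in the dimmest channel
  px <- add_idacorr(make_pixels(inst, c(0.35, 0.42, 0.50), 12000,
                                conc = c(2e4, 2e6), noisy = TRUE, seed = 5),
                    f)
  fit <- fit_plane(px, 0.5)
  expect_lt(abs(fit$gamma_M - 2.10) / 2.10, 0.02)
  expect_lt(abs(fit$beta_X - 1.167) / 1.167, 0.02)
})

test_that("bootstrap spread shrinks with sample size and vanishes without noise", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  clean <- add_idacorr(make_pixels(inst, c(0.35, 0.50), 2000), f)
  bt <- bootstrap_calibration(clean, 0.5, sample_sizes = c(200, 1000),
                              n_reps = 30, seed = 2)
  expect_true(all(bt$sd_beta < 1e-10) && all(bt$sd_gamma < 1e-10))

  noisy <- add_idacorr(make_pixels(inst, c(0.35, 0.50), 10000,
                                   conc = c(1e3, 1e5), noisy = TRUE,
                                   seed = 6), f)
  bt <- bootstrap_calibration(noisy, 0.5, sample_sizes = c(500, 10000),
                              n_reps = 60, seed = 3)
  expect_gt(bt$sd_gamma[1], bt$sd_gamma[2])
  expect_gt(bt$sd_beta[1], bt$sd_beta[2])
  expect_error(bootstrap_calibration(noisy, 0.5, sample_sizes = 1e7),
               "exceed")
})
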