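test_that("expected intensities match the signal model in closed form", {
  # crosstalk-free symmetric instrument: half the donor excitation goes out
  # as FRET at E = 0.5
  ei <- expected_intensities(100, 100, 0.5, unit_inst())
  expect_equal(ei$I_AA, 100)
  expect_equal(ei$I_DD, 50)
  expect_equal(ei$I_DA, 50)

  # donor-only limit: the FRET channel carries only bleedthrough
  inst_bt <- instrument_model(eta_Adet_Dem = 0.3)
  ei <- expected_intensities(100, 0, 0, inst_bt)
  expect_equal(ei$I_AA, 0)
  expect_equal(ei$I_DA, 100 * 0.3)

  # benchmark instrument, term-by-term hand evaluation of the three
  # channels at n_D = n_A = 200, E = 0.35 (frozen from an independent
  # arithmetic evaluation of the model terms)
  ei <- expected_intensities(200, 200, 0.35, bench_inst())
  expect_equal(ei$I_AA, 122.535, tolerance = 1e-12)
  expect_equal(ei$I_DD, 32.5, tolerance = 1e-12)
  expect_equal(ei$I_DA, 63.91135, tolerance = 1e-12)
})

test_that("invalid photophysical inputs are rejected", {
  expect_error(expected_intensities(100, 100, 1.2, unit_inst()), "\\[0, 1\\]")
  expect_error(expected_intensities(-1, 100, 0.5, unit_inst()),
               "non-negative")
  expect_error(instrument_model(phi_D = 0), "strictly positive")
  expect_error(instrument_model(phi_A = 1.4), "\\[0, 1\\]")
})

test_that("true correction factors are the stated ratios", {
  f <- true_correction_factors(unit_inst())
  expect_equal(unlist(f), c(alpha_BT = 0, delta_DE = 0, gamma_M = 1,
                            beta_X = 1))
  f <- true_correction_factors(instrument_model(eta_Adet_Dem = 0.4))
  expect_equal(f$alpha_BT, 0.4)
  f <- true_correction_factors(
    instrument_model(phi_A = 0.6, eta_Adet_Aem = 0.7, phi_D = 0.4,
                     eta_Ddet_Dem = 0.5))
  expect_equal(f$gamma_M, (0.6 * 0.7) / (0.4 * 0.5))  # = 2.1 by hand
})

test_that("instrument_from_factors realizes arbitrary factor sets", {
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- runif(1, 0, 0.6); d <- runif(1, 0, 0.3)
      g <- runif(1, 0.5, 3.5); b <- runif(1, 0.5, 4)
      f <- true_correction_factors(instrument_from_factors(a, d, g, b))
      expect_equal(unlist(f),
                   c(alpha_BT = a, delta_DE = d, gamma_M = g, beta_X = b),
                   tolerance = 1e-12)
    }
  })
})

test_that("scene generation honours the stoichiometry and E specification", {
  sc <- generate_scene(n_cells = 0)
  expect_true(all(sc$n_D == 0) && all(sc$n_A == 0) && all(sc$E_true == 0))

  sc <- generate_scene(shape = c(128, 128), n_cells = 2, stoichiometry = 0.5,
                       E_spec = 0.5, e_cell_sd = 0, e_pixel_sd = 0,
                       seed = 5)
  cell <- sc$cell_label > 0
  expect_true(all(sc$n_D[cell] == sc$n_A[cell]))
  expect_true(all(sc$E_true[cell] == 0.5))
  expect_true(all(sc$n_D[!cell] == 0) && all(sc$n_A[!cell] == 0))
  expect_true(all(sc$E_true >= 0 & sc$E_true <= 1))
  expect_identical(dim(sc$n_D), dim(sc$E_true))

  # three construct populations with distinct mean FRET levels
  E_levels <- c(0.503, 0.417, 0.351)
  for (E in E_levels) {
    sc <- generate_scene(shape = c(160, 160), n_cells = 3, E_spec = E,
                         seed = round(1000 * E))
    cell <- sc$cell_label > 0
    expect_equal(mean(sc$E_true[cell]), E, tolerance = 0.05)
  }

  # single-fluorophore cells cannot transfer energy
  sc <- generate_scene(n_cells = 2, stoichiometry = 1, seed = 3)
  expect_true(all(sc$E_true == 0))
  sc <- generate_scene(n_cells = 2, stoichiometry = 0, seed = 3)
  expect_true(all(sc$n_D == 0) && any(sc$n_A > 0))
})

test_that("scene generation is reproducible for a fixed seed", {
  a <- generate_scene(seed = 11)
  b <- generate_scene(seed = 11)
  expect_identical(a, b)
  sim1 <- simulate_fret_dataset(cells_per_construct = 4, seed = 9)
  sim2 <- simulate_fret_dataset(cells_per_construct = 4, seed = 9)
  expect_identical(sim1$fields[[1]]$raw$I_DA, sim2$fields[[1]]$raw$I_DA)
})

test_that("rendering with the noise model disabled equals the signal model", {
  sc <- generate_scene(shape = c(64, 64), n_cells = 2, radius_range = c(8, 12), seed = 2)
  tr <- render_triplet(sc, bench_inst(), noise_free_cam())
  ei <- expected_intensities(sc$n_D, sc$n_A, sc$E_true, bench_inst())
  expect_identical(tr$I_DD, ei$I_DD)
  expect_identical(tr$I_DA, ei$I_DA)
  expect_identical(tr$I_AA, ei$I_AA)

  # offset only: a zero scene renders as the dark level
  tr <- render_triplet(generate_scene(shape = c(16, 16), n_cells = 0),
                       unit_inst(), noise_free_cam(dark_count = 100))
  expect_true(all(tr$I_DD == 100) && all(tr$I_AA == 100))
})

test_that("shot noise follows Poisson moment identities", {
  sc <- structure(list(n_D = matrix(10000, 100, 100),
                       n_A = matrix(10000, 100, 100),
                       E_true = matrix(0, 100, 100),
                       cell_label = matrix(1L, 100, 100),
                       stoichiometry = 0.5),
                  class = "ground_truth_scene")
  tr <- render_triplet(sc, unit_inst(), camera_model(shot_noise = TRUE),
                       seed = 21)
  expect_equal(mean(tr$I_DD), 10000, tolerance = 0.01)
  expect_equal(var(as.vector(tr$I_DD)) / mean(tr$I_DD), 1, tolerance = 0.05)
})

test_that("noise-free intensities are linear in the fluorophore counts", {
  inst <- bench_inst()
  ei1 <- expected_intensities(300, 150, 0.4, inst)
  ei2 <- expected_intensities(300 * 7.5, 150 * 7.5, 0.4, inst)
  expect_equal(unlist(ei2), 7.5 * unlist(ei1), tolerance = 1e-12)
})
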