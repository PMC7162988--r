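test_that("the 1/S-vs-E fit is flat for an already-calibrated instrument", {
  inst <- unit_inst()                     # gamma = beta = 1, no crosstalk
  px <- make_pixels(inst, c(0.3, 0.45, 0.6), 500)
  fit <- lee_calibration(px, 0, 0)
  expect_equal(fit$omega, 2, tolerance = 1e-10)      # 1/S = 2 at S = 0.5
  expect_equal(fit$sigma, 0, tolerance = 1e-10)
  expect_equal(fit$gamma, 1, tolerance = 1e-8)
  expect_equal(fit$beta, 1, tolerance = 1e-8)
})

test_that("the 1/S-vs-E inversion recovers the generating instrument", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  px <- make_pixels(inst, c(0.35, 0.42, 0.50), 800)
  fit <- lee_calibration(px, f$alpha_BT, f$delta_DE)
  # oracle: the single-step plane fit on the same pixels
  plane <- fit_plane(add_idacorr(px, f), 0.5)
  expect_equal(fit$gamma, plane$gamma_M, tolerance = 1e-8)
  expect_equal(fit$beta, plane$beta_X, tolerance = 1e-8)
  expect_equal(fit$gamma, 2.10, tolerance = 1e-8)
  expect_equal(fit$beta, 1.167, tolerance = 1e-8)

  expect_error(lee_calibration(make_pixels(inst, 0.42, 500),
                               f$alpha_BT, f$delta_DE), "single FRET level")
})

test_that("the two-standard scheme matches the generating instrument", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  hi <- make_pixels(inst, 0.50, 600, seed = 2)
  lo <- make_pixels(inst, 0.35, 600, seed = 3)
  fit <- chen_calibration(list(hi, lo), rbind(hi, lo),
                          f$alpha_BT, f$delta_DE, 0.5)
  expect_equal(fit$G, 2.10, tolerance = 1e-10)
  expect_equal(1 / (fit$G * fit$k), 1.167, tolerance = 1e-10)
  expect_equal(fit$beta, 1.167, tolerance = 1e-10)

  # identical populations leave G undetermined
  expect_error(chen_calibration(list(hi, hi), NULL, f$alpha_BT, f$delta_DE),
               "indistinguishable")
  # a close pair triggers the separation warning
  mid <- make_pixels(inst, 0.48, 600, seed = 4)
  expect_warning(chen_calibration(list(hi, mid), NULL, f$alpha_BT,
                                  f$delta_DE), "FRET distance|separation")
})

test_that("close FRET pairs degrade the two-standard scheme most", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  est_sd <- function(E_pair, n_rep = 30) {
    g <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      a <- make_pixels(inst, E_pair[1], 800, conc = c(1e3, 1e4),
                       noisy = TRUE, seed = 1000 + i)
      b <- make_pixels(inst, E_pair[2], 800, conc = c(1e3, 1e4),
                       noisy = TRUE, seed = 2000 + i)
      g[i] <- suppressWarnings(
        chen_calibration(list(a, b), NULL, f$alpha_BT, f$delta_DE)$G)
    }
    sd(g)
  }
  expect_gt(est_sd(c(0.42, 0.35)), est_sd(c(0.50, 0.35)))
})

test_that("all three schemes agree exactly on noise-free data", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  pbc <- list(hi = make_pixels(inst, 0.50, 600, seed = 7),
              mid = make_pixels(inst, 0.42, 600, seed = 8),
              lo = make_pixels(inst, 0.35, 600, seed = 9))
  tab <- compare_methods(pbc, f$alpha_BT, f$delta_DE, 0.5, truth = f)
  expect_true(all(is.na(tab$error)))
  expect_true(all(abs(tab$gamma_bias) / f$gamma_M < 1e-6))
  expect_true(all(abs(tab$beta_bias) / f$beta_X < 1e-6))
  for (cn in c("E_hi", "E_mid", "E_lo"))
    expect_lt(diff(range(tab[[cn]])), 1e-6)
  expect_equal(tab$E_hi[tab$method == "plane"], 0.50, tolerance = 1e-8)
})

test_that("reduced-range refits vary per scheme as the FRET span shrinks", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  pbc <- list(hi = make_pixels(inst, 0.50, 500, seed = 11),
              mid = make_pixels(inst, 0.42, 500, seed = 12),
              lo = make_pixels(inst, 0.35, 500, seed = 13))
  rr <- reduced_range_test(pbc, alpha_BT = f$alpha_BT,
                           delta_DE = f$delta_DE)
  # noise-free: all pairs give the same factors for every scheme
  expect_true(all(rr$variation$rel_var_gamma < 1e-8))
  expect_true(all(rr$variation$rel_var_beta < 1e-8))
  expect_error(reduced_range_test(pbc, pairs = list(c("hi", "hi"))),
               "distinct")
})
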