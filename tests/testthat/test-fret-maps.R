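make_cal <- function(inst) {
  f <- true_correction_factors(inst)
  correction_factors(alpha_BT = f$alpha_BT, delta_DE = f$delta_DE,
                     gamma_M = f$gamma_M, beta_X = f$beta_X)
}

test_that("master equations give the expected values on simple pixels", {
  tr <- image_triplet(matrix(50, 1, 1), matrix(50, 1, 1), matrix(100, 1, 1))
  cal <- correction_factors(0, 0, 1, 1)
  expect_equal(fret_efficiency(tr, cal)[1, 1], 0.5)
  expect_equal(stoichiometry(tr, cal)[1, 1], 0.5)

  inst <- bench_inst()
  cal <- make_cal(inst)
  ei <- expected_intensities(1000, 0, 0, inst)       # donor-only
  tr <- image_triplet(matrix(ei$I_DD), matrix(ei$I_DA), matrix(ei$I_AA))
  expect_equal(fret_efficiency(tr, cal)[1, 1], 0, tolerance = 1e-12)
  ei <- expected_intensities(0, 1000, 0, inst)       # acceptor-only
  tr <- image_triplet(matrix(ei$I_DD), matrix(ei$I_DA), matrix(ei$I_AA))
  expect_equal(stoichiometry(tr, cal)[1, 1], 0, tolerance = 1e-12)

  ei <- expected_intensities(1000, 500, 0.4, inst)   # 2 donors : 1 acceptor
  tr <- image_triplet(matrix(ei$I_DD), matrix(ei$I_DA), matrix(ei$I_AA))
  expect_equal(stoichiometry(tr, cal)[1, 1], 2 / 3, tolerance = 1e-10)
})

test_that("noise-free maps invert the forward model exactly", {
  sc <- generate_scene(shape = c(96, 96), n_cells = 3, radius_range = c(10, 14), seed = 12)
  inst <- bench_inst()
  tr <- render_triplet(sc, inst, noise_free_cam())
  tr$mask <- sc$cell_label > 0
  cal <- make_cal(inst)
  E <- fret_efficiency(tr, cal)
  S <- stoichiometry(tr, cal)
  cell <- which(sc$cell_label > 0)
  expect_equal(E[cell], sc$E_true[cell], tolerance = 1e-10)
  expect_equal(S[cell], sc$n_D[cell] / (sc$n_D[cell] + sc$n_A[cell]),
               tolerance = 1e-10)
})

test_that("E and S are invariant under global intensity scaling", {
  inst <- bench_inst()
  cal <- make_cal(inst)
  ei <- expected_intensities(800, 400, 0.45, inst)
  tr1 <- image_triplet(matrix(ei$I_DD), matrix(ei$I_DA), matrix(ei$I_AA))
  for (c_ in c(0.01, 3, 1e4)) {
    tr2 <- image_triplet(matrix(c_ * ei$I_DD), matrix(c_ * ei$I_DA),
                         matrix(c_ * ei$I_AA))
    expect_equal(fret_efficiency(tr2, cal), fret_efficiency(tr1, cal),
                 tolerance = 1e-12)
    expect_equal(stoichiometry(tr2, cal), stoichiometry(tr1, cal),
                 tolerance = 1e-12)
  }
})

test_that("the excitation correction affects S but never E", {
  inst <- bench_inst()
  f <- true_correction_factors(inst)
  ei <- expected_intensities(800, 800, 0.45, inst)
  tr <- image_triplet(matrix(ei$I_DD), matrix(ei$I_DA), matrix(ei$I_AA))
  for (beta in c(0.3, 1, 2.5)) {
    cal <- correction_factors(f$alpha_BT, f$delta_DE, f$gamma_M, beta)
    expect_equal(fret_efficiency(tr, cal)[1, 1], 0.45, tolerance = 1e-10)
  }
  s1 <- stoichiometry(tr, correction_factors(f$alpha_BT, f$delta_DE,
                                             f$gamma_M, 0.3))[1, 1]
  s2 <- stoichiometry(tr, correction_factors(f$alpha_BT, f$delta_DE,
                                             f$gamma_M, 2.5))[1, 1]
  expect_gt(abs(s1 - s2), 0.1)
})

test_that("the E-S histogram counts valid pixels and resolves populations", {
  E <- matrix(0.42, 5, 5); S <- matrix(0.5, 5, 5)
  h <- es_histogram(E, S, bins = 70)
  expect_equal(sum(h), 25)
  expect_equal(sum(h > 0), 1)
  expect_error(es_histogram(E, S, limits = c(0, 1)), "at least")

  # two synthetic populations separated along E at common S = 0.5
  withr::with_seed(3, {
    E <- c(rnorm(5000, 0.50, 0.03), rnorm(5000, 0.35, 0.03))
    S <- rnorm(10000, 0.5, 0.02)
  })
  h <- es_histogram(E, S, bins = 100)
  brk <- attr(h, "e_breaks")
  mids <- (brk[-1] + brk[-101]) / 2
  marg_e <- rowSums(h)
  pk <- which(diff(sign(diff(marg_e))) == -2) + 1
  pk <- pk[marg_e[pk] > max(marg_e) / 4]
  expect_equal(sort(mids[pk]), c(0.35, 0.50), tolerance = 0.03)
  s_mean <- sum(colSums(h) * mids) / sum(h)
  expect_equal(s_mean, 0.5, tolerance = 0.02)
})

test_that("rank-correlation diagnostics behave at the extremes", {
  x <- seq_len(200)
  expect_equal(correlation_diagnostics(x, x^3), 1)
  withr::with_seed(9, {
    e <- rnorm(4000); r <- sample(e)
  })
  expect_lt(abs(correlation_diagnostics(e, r)), 3 / sqrt(4000))
  expect_warning(rho <- correlation_diagnostics(rep(1, 50), 1:50),
                 "constant")
  expect_true(is.na(rho))
  expect_error(correlation_diagnostics(1:5, 1:5), "10 valid")
})

test_that("per-cell summaries use medians and the SEM of medians", {
  withr::with_seed(4, {
    E <- matrix(0.42 + rnorm(900, 0, 0.05), 30, 30)
  })
  lab <- matrix(1L, 30, 30)
  tab <- per_cell_stats(E, NULL, lab)
  expect_equal(tab$median_E, 0.42, tolerance = 0.01)

  # three hand-built cells: SEM = sd(medians)/sqrt(3)
  E <- matrix(NA_real_, 3, 30)
  E[1, ] <- 0.40; E[2, ] <- 0.45; E[3, ] <- 0.50
  lab <- matrix(rep(1:3, 30), 3, 30)
  tab <- per_cell_stats(E, NULL, lab)
  sm <- summarize_cells(tab)
  expect_equal(sm$mean_E, mean(c(0.40, 0.45, 0.50)))
  expect_equal(sm$sem_E, sd(c(0.40, 0.45, 0.50)) / sqrt(3))

  # tiny cells are excluded with a warning
  lab2 <- matrix(0L, 10, 10); lab2[1, 1:3] <- 1L; lab2[5:10, ] <- 2L
  expect_warning(tab2 <- per_cell_stats(matrix(0.4, 10, 10), NULL, lab2),
                 "excluded")
  expect_equal(tab2$cell, 2L)
})
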