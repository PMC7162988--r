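# Shared fixtures. Everything is generated in code at test time.

# idealized symmetric instrument without crosstalk
unit_inst <- function() instrument_model()

# an instrument with the benchmark correction factors used throughout:
# alpha_BT = 0.421, delta_DE = 0.110, gamma_M = 2.10, beta_X = 1.167
bench_inst <- function() instrument_from_factors(0.421, 0.110, 2.10, 1.167)

noise_free_cam <- function(...) camera_model(shot_noise = FALSE, ...)

# pixel tuples (no imaging geometry) for calibration fits: 1:1 constructs
# at the given E levels, donor counts log-uniform over two decades,
# optional Poisson noise
make_pixels <- function(inst, E_levels, n_per = 2000, S = 0.5,
                        conc = c(1e3, 1e5), noisy = FALSE, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(E_levels, function(E) {
      n_D <- exp(runif(n_per, log(conc[1]), log(conc[2])))
      n_A <- n_D * (1 - S) / S
      ei <- expected_intensities(n_D, n_D * (1 - S) / S, E, inst)
      if (noisy) ei <- lapply(ei, function(m) rpois(length(m), m))
      data.frame(I_DD = ei$I_DD, I_DA = ei$I_DA, I_AA = ei$I_AA)
    })
    do.call(rbind, rows)
  })
}

# pixel tuples grouped into cells: per-cell base FRET (cell-to-cell sd)
# and per-cell brightness, Poisson shot noise — the dataset structure that
# separates population-average calibrations from whole-distribution fits
make_cell_pixels <- function(inst, E, n_cells = 26, px_per_cell = 300,
                             e_cell_sd = 0.02, conc = c(4e3, 4e5),
                             seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_cells), function(i) {
      n_D <- exp(runif(1, log(conc[1]), log(conc[2])) +
                   rnorm(px_per_cell, 0, 0.2))
      E_i <- min(max(E + rnorm(1, 0, e_cell_sd), 0), 1)
      ei <- expected_intensities(n_D, n_D, E_i, inst)
      data.frame(I_DD = rpois(px_per_cell, ei$I_DD),
                 I_DA = rpois(px_per_cell, ei$I_DA),
                 I_AA = rpois(px_per_cell, ei$I_AA))
    })
    do.call(rbind, rows)
  })
}

add_idacorr <- function(px, factors) {
  px$I_DA_corr <- px$I_DA - factors$alpha_BT * px$I_DD -
    factors$delta_DE * px$I_AA
  px
}

# a masked triplet built directly from pixel vectors (1 x n images)
triplet_from_pixels <- function(px, labels = NULL) {
  n <- nrow(px)
  as_m <- function(v) matrix(v, 1, n)
  image_triplet(as_m(px$I_DD), as_m(px$I_DA), as_m(px$I_AA),
                mask = as_m(rep(TRUE, n)),
                labels = if (is.null(labels)) NULL else as_m(labels))
}

# the full-scale simulated calibration study is shared by the acceptance
# tests; computed once per run
.study_cache <- new.env(parent = emptyenv())
get_study <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    sim <- simulate_fret_dataset(seed = seed)
    .study_cache[[key]] <- list(sim = sim, res = analyze_fret_study(sim))
  }
  .study_cache[[key]]
}
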