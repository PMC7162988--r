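# Alternative calibration schemes for the emission/excitation corrections,
# re-implemented for benchmarking against the single-step plane fit. Both
# are mathematically equivalent parameterizations: the two-standard scheme's
# (G, k) maps onto (gamma_M = G, beta_X = 1/(G*k)) and the linear 1/S-vs-E
# scheme's (gamma, beta) onto (gamma_M = gamma, beta_X = beta).

add_corrected <- function(pixels, alpha_BT, delta_DE) {
  pixels <- as.data.frame(pixels)
  pixels$I_DA_corr <- pixels$I_DA - alpha_BT * pixels$I_DD -
    delta_DE * pixels$I_AA
  pixels
}

#' Linear 1/S-vs-E calibration (ratiometric scheme)
#'
#' Calibration by first computing crosstalk-only ("raw") FRET efficiency
#' and stoichiometry with \code{gamma_M = beta_X = 1}, then fitting the
#' linear relation \code{1/S_raw = Omega + Sigma * E_raw} over all pixels
#' of a 1:1-stoichiometry dataset. For data generated with true factors
#' \code{(gamma, beta)} one has \code{Omega = 1 + beta*gamma} and
#' \code{Sigma = beta*(1 - gamma)}, so the factors are recovered as
#' \code{beta = Omega + Sigma - 1} and \code{gamma = (Omega - 1)/beta}.
#' These inversion relations are validated in the test suite against the
#' forward model (noise-free recovery of the generating instrument), not
#' trusted on faith. Pixels with \code{S_raw} below a floor are excluded:
#' \code{1/S} diverges for small S, the known fragility of this scheme.
#'
#' @param pixels data.frame with columns \code{I_DD}, \code{I_DA},
#'   \code{I_AA} (in-cell pixels of a 1:1 dataset spanning \code{>= 2}
#'   FRET levels).
#' @param alpha_BT,delta_DE crosstalk factors (measured separately).
#' @param s_floor minimum \code{S_raw} for a pixel to enter the fit.
#' @return A list with \code{gamma}, \code{beta}, \code{omega},
#'   \code{sigma}, \code{r_squared}, \code{n_pixels}, \code{n_excluded}.
#' @export
lee_calibration <- function(pixels, alpha_BT = 0, delta_DE = 0,
                            s_floor = 0.05) {
  px <- add_corrected(pixels, alpha_BT, delta_DE)
  tot <- px$I_DD + px$I_DA_corr
  S_raw <- tot / (tot + px$I_AA)
  E_raw <- px$I_DA_corr / tot
  ok <- is.finite(S_raw) & is.finite(E_raw) & S_raw >= s_floor
  n_exc <- sum(!ok)
  if (sum(ok) < 3) stop("too few pixels above the S_raw floor")
  E_raw <- E_raw[ok]; S_raw <- S_raw[ok]
  if (sd(E_raw) < 1e-10 * max(abs(E_raw), 1))
    stop("degenerate fit: the dataset shows a single FRET level")
  y <- 1 / S_raw
  fit <- lm(y ~ E_raw)
  omega <- coef(fit)[[1]]; sigma <- coef(fit)[[2]]
  beta <- omega + sigma - 1
  if (beta <= 0)
    stop("inverted beta is non-positive; dataset inconsistent with a 1:1 ",
         "stoichiometry")
  gamma <- (omega - 1) / beta
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(gamma = gamma, beta = beta, omega = omega, sigma = sigma,
       r_squared = r2, n_pixels = sum(ok), n_excluded = n_exc)
}

#' Two-step two-standard calibration
#'
#' Calibration in two separated steps. Step 1 determines the emission
#' correction \code{G} from two 1:1 constructs with well-separated FRET
#' efficiencies, using the constraint that the \code{G}-corrected total
#' donor signal per acceptor, \code{(G*I_DD + I_DA_corr)/I_AA}, must be the
#' same for both: with per-construct medians \code{R_DD = med(I_DD/I_AA)}
#' and \code{R_F = med(I_DA_corr/I_AA)},
#' \code{G = (R_F2 - R_F1)/(R_DD1 - R_DD2)}. Step 2 measures a
#' known-stoichiometry standard and computes the second parameter \code{k}
#' from the same corrected ratio:
#' \code{beta = (S0/(1-S0)) / med(I_AA / (G*I_DD + I_DA_corr))^{-1}} — i.e.
#' \code{beta = (S0/(1-S0)) / med((G*I_DD + I_DA_corr)/I_AA)} inverted —
#' and \code{k = 1/(G*beta)}. The implementation is accepted through the
#' equivalence oracle (exact recovery of the generating instrument on
#' noise-free data) in the test suite. The scheme compares only two
#' population averages, so its uncertainty grows as the FRET separation of
#' the pair shrinks; a warning is issued below 5 percentage points.
#'
#' @param pixels_pair list of two data.frames (columns \code{I_DD},
#'   \code{I_DA}, \code{I_AA}), one per 1:1 construct with distinct E.
#' @param pixels_known data.frame of the known-stoichiometry standard
#'   (defaults to the pooled pair).
#' @param alpha_BT,delta_DE crosstalk factors.
#' @param S0 stoichiometry of the known standard.
#' @return A list with \code{G}, \code{k}, the equivalent \code{gamma}
#'   (= G) and \code{beta} (= 1/(G k)), and \code{delta_E_pair} (the E
#'   separation of the pair as seen after calibration).
#' @export
chen_calibration <- function(pixels_pair, pixels_known = NULL,
                             alpha_BT = 0, delta_DE = 0, S0 = 0.5) {
  if (length(pixels_pair) != 2)
    stop("exactly two construct datasets are required for step 1")
  pp <- lapply(pixels_pair, add_corrected, alpha_BT, delta_DE)
  rat <- lapply(pp, function(px) {
    ok <- is.finite(px$I_AA) & px$I_AA > 0
    list(R_DD = median(px$I_DD[ok] / px$I_AA[ok]),
         R_F = median(px$I_DA_corr[ok] / px$I_AA[ok]))
  })
  den <- rat[[1]]$R_DD - rat[[2]]$R_DD
  if (abs(den) < 1e-12)
    stop("the two constructs have indistinguishable intensity ratios; ",
         "G is undetermined")
  G <- (rat[[2]]$R_F - rat[[1]]$R_F) / den
  if (!is.finite(G) || G <= 0)
    stop("step 1 produced a non-positive G (", signif(G, 4), ")")
  if (is.null(pixels_known)) pixels_known <- do.call(rbind, pp)
  else pixels_known <- add_corrected(pixels_known, alpha_BT, delta_DE)
  ok <- is.finite(pixels_known$I_AA) & pixels_known$I_AA > 0
  ratio <- median((G * pixels_known$I_DD[ok] + pixels_known$I_DA_corr[ok]) /
                    pixels_known$I_AA[ok])
  beta <- (S0 / (1 - S0)) / ratio
  if (beta <= 0) stop("step 2 produced a non-positive beta")
  k <- 1 / (G * beta)
  e_med <- vapply(pp, function(px) {
    den2 <- G * px$I_DD + px$I_DA_corr
    median(px$I_DA_corr[den2 > 0] / den2[den2 > 0])
  }, numeric(1))
  dE <- abs(diff(e_med))
  if (dE < 0.05)
    warning("FRET separation of the construct pair is only ",
            signif(100 * dE, 2), " percentage points; the two-standard ",
            "estimate grows unreliable as the FRET distance decreases")
  list(G = G, k = k, gamma = G, beta = beta, delta_E_pair = dE)
}

# per-construct median E given factors
construct_medians <- function(pixels_by_construct, alpha_BT, delta_DE,
                              gamma) {
  vapply(pixels_by_construct, function(px) {
    px <- add_corrected(px, alpha_BT, delta_DE)
    den <- gamma * px$I_DD + px$I_DA_corr
    ok <- is.finite(den) & den > 0
    median(px$I_DA_corr[ok] / den[ok])
  }, numeric(1))
}

#' Benchmark the three calibration schemes on one dataset
#'
#' Runs the single-step plane fit (\code{"plane"}), the linear 1/S-vs-E
#' fit (\code{"lee"}) and the two-step two-standard scheme (\code{"chen"},
#' using the two constructs with extreme raw FRET as the pair) on the same
#' per-construct pixel data, and tabulates each method's factors (mapped
#' onto the common \code{(gamma_M, beta_X)} parameterization) and
#' per-construct median FRET efficiencies. A failing method is recorded as
#' a failure and the comparison continues.
#'
#' @param pixels_by_construct named list of data.frames (columns
#'   \code{I_DD}, \code{I_DA}, \code{I_AA}), one per 1:1 construct.
#' @param alpha_BT,delta_DE crosstalk factors.
#' @param S0 stoichiometry of the constructs.
#' @param truth optional list with \code{gamma_M}, \code{beta_X} (e.g.
#'   [true_correction_factors()]) to add bias columns.
#' @return A data.frame with one row per method: \code{method},
#'   \code{gamma_like}, \code{beta_like}, one \code{E_<construct>} column
#'   per construct, \code{error} (NA or the failure message), and bias
#'   columns when \code{truth} is given.
#' @export
compare_methods <- function(pixels_by_construct, alpha_BT = 0, delta_DE = 0,
                            S0 = 0.5, truth = NULL) {
  pooled <- do.call(rbind, lapply(pixels_by_construct, as.data.frame))
  runs <- list(
    plane = function() {
      px <- add_corrected(pooled, alpha_BT, delta_DE)
      fit <- fit_plane(px, S0 = S0)
      list(gamma = fit$gamma_M, beta = fit$beta_X)
    },
    lee = function() {
      fit <- lee_calibration(pooled, alpha_BT, delta_DE)
      list(gamma = fit$gamma, beta = fit$beta)
    },
    chen = function() {
      raw_e <- construct_medians(pixels_by_construct, alpha_BT, delta_DE, 1)
      pair <- pixels_by_construct[c(which.max(raw_e), which.min(raw_e))]
      fit <- chen_calibration(pair, pooled, alpha_BT, delta_DE, S0)
      list(gamma = fit$gamma, beta = fit$beta)
    })
  rows <- lapply(names(runs), function(m) {
    res <- tryCatch(runs[[m]](), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(method = m, gamma_like = NA_real_,
                        beta_like = NA_real_, error = conditionMessage(res)))
    meds <- construct_medians(pixels_by_construct, alpha_BT, delta_DE,
                              res$gamma)
    out <- data.frame(method = m, gamma_like = res$gamma,
                      beta_like = res$beta, error = NA_character_)
    for (nm in names(pixels_by_construct))
      out[[paste0("E_", nm)]] <- meds[[nm]]
    out
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    for (nm in paste0("E_", names(pixels_by_construct)))
      if (is.null(r[[nm]])) r[[nm]] <- NA_real_
    r
  }))
  if (!is.null(truth)) {
    tab$gamma_bias <- tab$gamma_like - truth$gamma_M
    tab$beta_bias <- tab$beta_like - truth$beta_X
  }
  tab
}

#' Bootstrap comparison of calibration robustness versus sample size
#'
#' Draws random pixel subsets of each requested size from a pooled
#' multi-construct dataset and recalibrates with the plane fit and the
#' 1/S-vs-E fit on every draw, reporting the standard deviation of the
#' recovered factors per method and size — the statistical-robustness
#' benchmark of the two fitting-based schemes.
#'
#' @param pixels pooled data.frame (columns \code{I_DD}, \code{I_DA},
#'   \code{I_AA}).
#' @param alpha_BT,delta_DE crosstalk factors.
#' @param S0 assumed stoichiometry.
#' @param sample_sizes subset sizes.
#' @param n_reps repetitions per size.
#' @param seed seed for reproducible draws.
#' @return A data.frame with columns \code{method}, \code{sample_size},
#'   \code{sd_gamma}, \code{sd_beta}, \code{n_failed}.
#' @export
compare_bootstrap <- function(pixels, alpha_BT = 0, delta_DE = 0, S0 = 0.5,
                              sample_sizes = c(1e3, 1e4, 1e5),
                              n_reps = 200, seed = NULL) {
  px <- add_corrected(pixels, alpha_BT, delta_DE)
  n <- nrow(px)
  if (any(sample_sizes > n))
    stop("sample sizes must not exceed the dataset size (", n, ")")
  run <- function() {
    rows <- list()
    for (sz in sample_sizes) {
      g <- list(plane = rep(NA_real_, n_reps), lee = rep(NA_real_, n_reps))
      b <- g
      failed <- c(plane = 0L, lee = 0L)
      for (r in seq_len(n_reps)) {
        idx <- sample.int(n, sz)
        sub <- px[idx, , drop = FALSE]
        fp <- tryCatch(fit_plane(sub, S0), error = function(e) NULL)
        if (is.null(fp)) failed["plane"] <- failed["plane"] + 1L
        else { g$plane[r] <- fp$gamma_M; b$plane[r] <- fp$beta_X }
        fl <- tryCatch(lee_calibration(sub, 0, 0), error = function(e) NULL)
        if (is.null(fl)) failed["lee"] <- failed["lee"] + 1L
        else { g$lee[r] <- fl$gamma; b$lee[r] <- fl$beta }
      }
      for (m in c("plane", "lee"))
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, sample_size = sz,
          sd_gamma = sd(g[[m]], na.rm = TRUE),
          sd_beta = sd(b[[m]], na.rm = TRUE),
          n_failed = failed[[m]])
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Reduced-FRET-range robustness test
#'
#' Recalibrates with all three schemes using only pairs of constructs
#' (shrinking the FRET range of the calibration dataset) and reports, per
#' method, the factors per pair and their relative variation across pairs —
#' schemes relying on two population averages degrade fastest as the FRET
#' range shrinks.
#'
#' @param pixels_by_construct named list of per-construct pixel
#'   data.frames.
#' @param pairs list of length-2 character vectors naming the construct
#'   pairs; default: all pairs.
#' @param alpha_BT,delta_DE crosstalk factors.
#' @param S0 assumed stoichiometry.
#' @return A list with \code{per_pair} (data.frame: \code{pair},
#'   \code{method}, \code{gamma_like}, \code{beta_like}, \code{error}) and
#'   \code{variation} (data.frame: \code{method}, \code{rel_var_gamma},
#'   \code{rel_var_beta}, relative range (max-min)/mean across pairs).
#' @export
reduced_range_test <- function(pixels_by_construct, pairs = NULL,
                               alpha_BT = 0, delta_DE = 0, S0 = 0.5) {
  nms <- names(pixels_by_construct)
  if (is.null(pairs)) {
    cmb <- utils::combn(nms, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  for (p in pairs)
    if (length(unique(p)) != 2 || !all(p %in% nms))
      stop("each pair must name two distinct constructs")
  rows <- list()
  for (p in pairs) {
    tab <- suppressWarnings(
      compare_methods(pixels_by_construct[p], alpha_BT, delta_DE, S0))
    tab <- tab[, c("method", "gamma_like", "beta_like", "error")]
    tab$pair <- paste(p, collapse = "-")
    rows[[length(rows) + 1L]] <- tab
  }
  per_pair <- do.call(rbind, rows)
  relvar <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    diff(range(v)) / mean(v)
  }
  variation <- do.call(rbind, lapply(unique(per_pair$method), function(m) {
    sub <- per_pair[per_pair$method == m, ]
    data.frame(method = m, rel_var_gamma = relvar(sub$gamma_like),
               rel_var_beta = relvar(sub$beta_like))
  }))
  list(per_pair = per_pair, variation = variation)
}
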