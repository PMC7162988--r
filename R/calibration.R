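#' Correction-factor container
#'
#' Holds the four calibration constants of the three-image FRET analysis —
#' donor bleedthrough \code{alpha_BT}, acceptor direct excitation
#' \code{delta_DE}, emission correction \code{gamma_M} and excitation
#' correction \code{beta_X} — with uncertainties and fit diagnostics.
#'
#' @param alpha_BT,delta_DE crosstalk factors, \code{>= 0}.
#' @param gamma_M,beta_X emission/excitation corrections, \code{> 0}.
#' @param alpha_sd,delta_sd,gamma_sd,beta_sd uncertainties (NA if unknown).
#' @param r_squared coefficient of determination of the plane fit.
#' @param n_pixels,n_cells sample sizes behind the calibration.
#' @param S0_assumed stoichiometry assumed during the plane fit (fraction).
#' @return An object of class \code{correction_factors}.
#' @export
correction_factors <- function(alpha_BT = 0, delta_DE = 0,
                               gamma_M = 1, beta_X = 1,
                               alpha_sd = NA_real_, delta_sd = NA_real_,
                               gamma_sd = NA_real_, beta_sd = NA_real_,
                               r_squared = NA_real_,
                               n_pixels = NA_integer_, n_cells = NA_integer_,
                               S0_assumed = NA_real_) {
  stopifnot(alpha_BT >= 0, delta_DE >= 0, gamma_M > 0, beta_X > 0)
  if (is.finite(r_squared) && (r_squared < -1e-9 || r_squared > 1 + 1e-9))
    stop("r_squared must lie in [0, 1]")
  structure(list(alpha_BT = alpha_BT, delta_DE = delta_DE,
                 gamma_M = gamma_M, beta_X = beta_X,
                 alpha_sd = alpha_sd, delta_sd = delta_sd,
                 gamma_sd = gamma_sd, beta_sd = beta_sd,
                 r_squared = r_squared, n_pixels = n_pixels,
                 n_cells = n_cells, S0_assumed = S0_assumed),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  fmt <- function(v, s) if (is.finite(s)) sprintf("%.4g +/- %.2g", v, s)
                        else sprintf("%.4g", v)
  cat("<correction_factors>\n")
  cat("  alpha_BT (bleedthrough):      ", fmt(x$alpha_BT, x$alpha_sd), "\n")
  cat("  delta_DE (direct excitation): ", fmt(x$delta_DE, x$delta_sd), "\n")
  cat("  gamma_M  (emission):          ", fmt(x$gamma_M, x$gamma_sd), "\n")
  cat("  beta_X   (excitation):        ", fmt(x$beta_X, x$beta_sd), "\n")
  if (is.finite(x$r_squared))
    cat(sprintf("  plane fit R^2 = %.4g (%s px, %s cells, S0 = %g)\n",
                x$r_squared, format(x$n_pixels), format(x$n_cells),
                x$S0_assumed))
  invisible(x)
}

#' Crosstalk factor from single-fluorophore cells
#'
#' Measures one spectral crosstalk factor from cells expressing only the
#' donor or only the acceptor. For donor-only cells the bleedthrough is the
#' per-pixel ratio \code{I_DA / I_DD}; for acceptor-only cells the direct
#' excitation is \code{I_DA / I_AA}. Ratios are computed in every in-mask
#' pixel of every cell whose denominator exceeds a noise floor, pooled, and
#' summarized by the median. The uncertainty is a bootstrap over cells
#' (resample cells with replacement, recompute the pooled median).
#'
#' @param triplets a masked [image_triplet()] or list of them.
#' @param kind \code{"donor_only"} (yields \code{alpha_BT}) or
#'   \code{"acceptor_only"} (yields \code{delta_DE}).
#' @param noise_floor minimum denominator intensity for a pixel to count;
#'   default 5x the read noise implied by the darkest pixels
#'   (\code{5 * sd} of the out-of-mask background, or 0 if no background).
#' @param boot_reps bootstrap repetitions for the uncertainty (0 disables).
#' @param seed optional seed for the bootstrap.
#' @return A list with \code{factor}, \code{sd}, \code{ratios} (the pooled
#'   pixelwise ratio vector, for histogramming), \code{n_pixels},
#'   \code{n_cells}.
#' @export
crosstalk_factor <- function(triplets, kind = c("donor_only", "acceptor_only"),
                             noise_floor = NULL, boot_reps = 1000,
                             seed = NULL) {
  kind <- match.arg(kind)
  px <- gather_pixels(triplets)
  den <- if (kind == "donor_only") px$I_DD else px$I_AA
  other <- if (kind == "donor_only") px$I_AA else px$I_DD
  if (is.null(noise_floor)) {
    trs <- if (inherits(triplets, "image_triplet")) list(triplets) else triplets
    bg <- unlist(lapply(trs, function(tr) {
      ch <- if (kind == "donor_only") tr$I_DD else tr$I_AA
      ch[!tr$mask & is.finite(ch)]
    }))
    noise_floor <- if (length(bg) > 10) 5 * sd(bg) else 0
  }
  keep <- is.finite(den) & den > noise_floor & is.finite(px$I_DA)
  if (!any(keep)) stop("no usable pixels above the noise floor")
  # plausibility: a donor-only sample should be dark in the other channel
  if (median(other[keep]) > 0.5 * median(den[keep]))
    warning("substantial signal in the supposed dark channel; check 'kind' ",
            "and the sample")
  ratios <- px$I_DA[keep] / den[keep]
  cells <- px$cell[keep]
  ncell <- length(unique(cells))
  if (ncell < 5)
    warning("only ", ncell, " cell(s); at least 5 are recommended for a ",
            "reliable crosstalk estimate")
  med <- median(ratios)
  bsd <- NA_real_
  if (boot_reps > 0 && ncell > 1) {
    ids <- unique(cells)
    by_cell <- split(ratios, cells)
    boot <- function() {
      reps <- numeric(boot_reps)
      for (b in seq_len(boot_reps)) {
        pick <- sample(ids, ncell, replace = TRUE)
        reps[b] <- median(unlist(by_cell[as.character(pick)], use.names = FALSE))
      }
      sd(reps)
    }
    bsd <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  }
  list(factor = med, sd = bsd, ratios = ratios,
       n_pixels = sum(keep), n_cells = ncell)
}

#' Crosstalk-corrected sensitized-emission image
#'
#' Removes the donor bleedthrough and acceptor direct excitation from the
#' sensitized-emission channel:
#' \code{I_DA_corr = I_DA - alpha_BT * I_DD - delta_DE * I_AA}.
#' Negative values (noise) are preserved.
#'
#' @param triplet an [image_triplet()].
#' @param alpha_BT,delta_DE crosstalk factors (or a
#'   [correction_factors()] object in \code{alpha_BT}).
#' @return The corrected map, same shape as the inputs.
#' @export
corrected_fret_image <- function(triplet, alpha_BT = 0, delta_DE = 0) {
  if (inherits(alpha_BT, "correction_factors")) {
    delta_DE <- alpha_BT$delta_DE
    alpha_BT <- alpha_BT$alpha_BT
  }
  stopifnot(alpha_BT >= 0, delta_DE >= 0)
  triplet$I_DA - alpha_BT * triplet$I_DD - delta_DE * triplet$I_AA
}

#' Single-step plane fit for the emission and excitation corrections
#'
#' In the 3D intensity space \code{\{I_DD, I_DA_corr, I_AA\}}, pixels of a
#' sample with fixed stoichiometry \code{S0} lie on the plane
#' \deqn{\beta^X \gamma^M I_{DD} + \beta^X I_{DA}^{corr}
#'       = \frac{S_0}{1 - S_0} I_{AA},}
#' so one ordinary least-squares fit with no intercept determines
#' \code{beta_X * gamma_M} and \code{beta_X} simultaneously. A sample with a
#' single FRET value forms a straight line in this space, through which
#' infinitely many planes pass: the fit requires the FRET values of the
#' dataset to be sufficiently spread, and raises an error when the design is
#' (near-)collinear.
#'
#' @param pixels data.frame or matrix with columns \code{I_DD},
#'   \code{I_DA_corr}, \code{I_AA} (as from [gather_pixels()] plus
#'   [corrected_fret_image()], or build directly).
#' @param S0 assumed stoichiometry, strictly inside \code{(0, 1)}.
#' @param collinearity_tol minimum ratio of singular values of the
#'   column-normalized design below which the fit aborts.
#' @return A list with \code{beta_X}, \code{gamma_M}, \code{r_squared},
#'   \code{n_pixels}, \code{condition} (singular-value ratio).
#' @export
fit_plane <- function(pixels, S0 = 0.5, collinearity_tol = 1e-3) {
  if (S0 <= 0 || S0 >= 1)
    stop("S0 must lie strictly inside (0, 1)")
  pixels <- as.data.frame(pixels)
  need <- c("I_DD", "I_DA_corr", "I_AA")
  if (!all(need %in% names(pixels)))
    stop("pixels must have columns ", paste(need, collapse = ", "))
  ok <- is.finite(pixels$I_DD) & is.finite(pixels$I_DA_corr) &
        is.finite(pixels$I_AA)
  X <- cbind(pixels$I_DD[ok], pixels$I_DA_corr[ok])
  y <- (S0 / (1 - S0)) * pixels$I_AA[ok]
  if (nrow(X) < 2) stop("at least 2 valid pixels are required")
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) stop("degenerate design: a channel is identically zero")
  sv <- svd(sweep(X, 2, nrm, `/`), nu = 0, nv = 0)$d
  cond <- sv[2] / sv[1]
  if (!is.finite(cond) || cond < collinearity_tol)
    stop("FRET range insufficient to determine the plane ",
         "(singular-value ratio ", signif(cond, 3), "); the dataset needs ",
         "a spread of FRET values")
  coefs <- qr.solve(X, y)
  gb <- coefs[1]; b <- coefs[2]
  if (b <= 0)
    stop("plane fit produced a non-positive beta_X (", signif(b, 4),
         "); check crosstalk correction and channel order")
  res <- y - X %*% coefs
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta_X = b, gamma_M = gb / b, r_squared = r2,
       n_pixels = nrow(X), condition = cond)
}

#' Bootstrap the plane-fit uncertainty versus sample size
#'
#' Randomly subsamples the pixel dataset at each requested size, refits the
#' plane, and reports the spread of the recovered factors — the synthetic
#' analogue of splitting an experimental dataset into artificially smaller
#' ones to measure the statistical error of the calibration.
#'
#' @param pixels as in [fit_plane()].
#' @param S0 assumed stoichiometry.
#' @param sample_sizes vector of subset sizes (each \code{<=} dataset size
#'   unless \code{replace = TRUE}).
#' @param n_reps repetitions per size.
#' @param replace draw with replacement (a classical bootstrap, for
#'   uncertainties at the full dataset size) instead of plain subsampling
#'   (for the spread-versus-size study).
#' @param seed seed for reproducible draws.
#' @return A data.frame with columns \code{sample_size}, \code{sd_beta},
#'   \code{sd_gamma}, \code{n_failed} (collinear subsets skipped).
#' @export
bootstrap_calibration <- function(pixels, S0 = 0.5,
                                  sample_sizes = c(1e3, 1e4, 1e5),
                                  n_reps = 200, replace = FALSE,
                                  seed = NULL) {
  pixels <- as.data.frame(pixels)
  n <- nrow(pixels)
  if (!replace && any(sample_sizes > n))
    stop("sample sizes must not exceed the dataset size (", n, ")")
  run <- function() {
    out <- lapply(sample_sizes, function(sz) {
      betas <- gammas <- rep(NA_real_, n_reps)
      failed <- 0L
      for (r in seq_len(n_reps)) {
        idx <- sample.int(n, sz, replace = replace)
        fit <- tryCatch(fit_plane(pixels[idx, , drop = FALSE], S0),
                        error = function(e) NULL)
        if (is.null(fit)) { failed <- failed + 1L; next }
        betas[r] <- fit$beta_X; gammas[r] <- fit$gamma_M
      }
      data.frame(sample_size = sz,
                 sd_beta = sd(betas, na.rm = TRUE),
                 sd_gamma = sd(gammas, na.rm = TRUE),
                 n_failed = failed)
    })
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Full calibration from single-fluorophore and known-stoichiometry data
#'
#' Runs the complete single-step calibration: crosstalk factors from
#' donor-only and acceptor-only cells (pooled pixel medians), then the
#' plane fit for \code{gamma_M} and \code{beta_X} on the known-stoichiometry
#' dataset with the crosstalk-corrected sensitized emission. Uncertainties
#' on the plane-fit factors come from a pixel bootstrap at the full dataset
#' size.
#'
#' @param donor_only,acceptor_only masked triplets (or lists) of
#'   single-fluorophore cells.
#' @param fret_triplets masked triplets (or list) of the
#'   known-stoichiometry FRET sample.
#' @param S0 assumed stoichiometry of the FRET sample.
#' @param boot_reps bootstrap repetitions for uncertainties (0 disables).
#' @param seed seed for the bootstraps.
#' @param ... passed to [crosstalk_factor()] (e.g. \code{noise_floor}).
#' @return A [correction_factors()] object.
#' @export
calibrate_dataset <- function(donor_only, acceptor_only, fret_triplets,
                              S0 = 0.5, boot_reps = 200, seed = NULL, ...) {
  ct_a <- crosstalk_factor(donor_only, "donor_only",
                           boot_reps = boot_reps, seed = seed, ...)
  ct_d <- crosstalk_factor(acceptor_only, "acceptor_only",
                           boot_reps = boot_reps, seed = seed, ...)
  px <- gather_pixels(fret_triplets)
  px$I_DA_corr <- px$I_DA - ct_a$factor * px$I_DD - ct_d$factor * px$I_AA
  fit <- fit_plane(px, S0 = S0)
  gsd <- bsd <- NA_real_
  if (boot_reps > 0) {
    bt <- bootstrap_calibration(px, S0 = S0, sample_sizes = nrow(px),
                                n_reps = boot_reps, replace = TRUE,
                                seed = seed)
    gsd <- bt$sd_gamma[1]; bsd <- bt$sd_beta[1]
  }
  correction_factors(alpha_BT = ct_a$factor, delta_DE = ct_d$factor,
                     gamma_M = fit$gamma_M, beta_X = fit$beta_X,
                     alpha_sd = ct_a$sd, delta_sd = ct_d$sd,
                     gamma_sd = gsd, beta_sd = bsd,
                     r_squared = fit$r_squared,
                     n_pixels = fit$n_pixels,
                     n_cells = length(unique(px$cell)),
                     S0_assumed = S0)
}
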