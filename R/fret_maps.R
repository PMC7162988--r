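#' Pixelwise FRET efficiency map
#'
#' Evaluates the master equation
#' \deqn{E = \frac{I_{DA}^{corr}}{\gamma^M I_{DD} + I_{DA}^{corr}}}
#' in every pixel, with \code{I_DA_corr} the crosstalk-corrected sensitized
#' emission. Values are not clipped to \code{[0, 1]} — noise can push them
#' outside and clipping would bias medians. Pixels with a non-positive
#' denominator, non-finite inputs, or outside the triplet mask (if any) are
#' \code{NA}.
#'
#' @param triplet an [image_triplet()].
#' @param factors a [correction_factors()] object.
#' @return A numeric matrix of FRET probabilities (fractions).
#' @export
fret_efficiency <- function(triplet, factors) {
  stopifnot(inherits(triplet, "image_triplet"),
            inherits(factors, "correction_factors"))
  f <- corrected_fret_image(triplet, factors)
  den <- factors$gamma_M * triplet$I_DD + f
  E <- f / den
  E[!is.finite(E) | den <= 0] <- NA_real_
  if (!is.null(triplet$mask)) E[!triplet$mask] <- NA_real_
  E
}

#' Pixelwise stoichiometry map
#'
#' Evaluates the master equation
#' \deqn{S = \frac{\gamma^M I_{DD} + I_{DA}^{corr}}
#'            {\gamma^M I_{DD} + I_{DA}^{corr} + I_{AA}/\beta^X}}
#' in every pixel: the donor fraction of all fluorophores, 0.5 for an intact
#' 1:1 construct. Same invalidity and no-clipping conventions as
#' [fret_efficiency()].
#'
#' @inheritParams fret_efficiency
#' @return A numeric matrix of stoichiometries (fractions).
#' @export
stoichiometry <- function(triplet, factors) {
  stopifnot(inherits(triplet, "image_triplet"),
            inherits(factors, "correction_factors"))
  f <- corrected_fret_image(triplet, factors)
  num <- factors$gamma_M * triplet$I_DD + f
  den <- num + triplet$I_AA / factors$beta_X
  S <- num / den
  S[!is.finite(S) | den <= 0] <- NA_real_
  if (!is.null(triplet$mask)) S[!triplet$mask] <- NA_real_
  S
}

#' Pixelwise E and S maps with per-cell statistics
#'
#' Computes both master-equation maps for one field of view, the validity
#' mask, and (when the triplet carries cell labels) the per-cell medians.
#'
#' @inheritParams fret_efficiency
#' @param min_cell_pixels cells with fewer valid pixels are dropped from
#'   the per-cell table (with a warning).
#' @return An object of class \code{es_maps}: matrices \code{E}, \code{S},
#'   logical \code{valid}, and data.frame \code{per_cell} (columns
#'   \code{cell}, \code{n}, \code{median_E}, \code{median_S}) or NULL.
#' @export
es_maps <- function(triplet, factors, min_cell_pixels = 10) {
  E <- fret_efficiency(triplet, factors)
  S <- stoichiometry(triplet, factors)
  valid <- is.finite(E) & is.finite(S)
  per_cell <- NULL
  if (!is.null(triplet$labels))
    per_cell <- per_cell_stats(E, S, triplet$labels,
                               min_cell_pixels = min_cell_pixels)
  structure(list(E = E, S = S, valid = valid, per_cell = per_cell,
                 factors = factors),
            class = "es_maps")
}

#' @export
print.es_maps <- function(x, ...) {
  cat(sprintf("<es_maps> %d x %d px, %d valid\n",
              nrow(x$E), ncol(x$E), sum(x$valid)))
  if (sum(x$valid)) {
    cat(sprintf("  median E = %.4f, median S = %.4f\n",
                median(x$E[x$valid]), median(x$S[x$valid])))
  }
  if (!is.null(x$per_cell)) print(head(x$per_cell, 10))
  invisible(x)
}

#' Per-cell median statistics
#'
#' Summarizes E and S maps per labelled cell by the median over valid
#' pixels. The dataset-level summary of a per-cell table (mean of per-cell
#' medians, with the standard error of the mean as uncertainty) is
#' available through [summarize_cells()]; cell-to-cell variability, not
#' pixel statistics, dominates the uncertainty of such measurements.
#'
#' @param E,S maps as from [fret_efficiency()] / [stoichiometry()]
#'   (\code{S} may be NULL).
#' @param labels integer cell-label matrix (0 = background).
#' @param min_cell_pixels minimum number of valid pixels for a cell to be
#'   reported.
#' @return data.frame with columns \code{cell}, \code{n}, \code{median_E}
#'   (and \code{median_S} when given).
#' @export
per_cell_stats <- function(E, S = NULL, labels, min_cell_pixels = 10) {
  stopifnot(identical(dim(E), dim(labels)))
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  rows <- lapply(ids, function(id) {
    sel <- labels == id & is.finite(E)
    if (!is.null(S)) sel <- sel & is.finite(S)
    n <- sum(sel)
    data.frame(cell = id, n = n,
               median_E = if (n) median(E[sel]) else NA_real_,
               median_S = if (!is.null(S) && n) median(S[sel]) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(data.frame(cell = integer(), n = integer(),
                                      median_E = numeric(),
                                      median_S = numeric()))
  small <- tab$n < min_cell_pixels
  if (any(small))
    warning(sum(small), " cell(s) with fewer than ", min_cell_pixels,
            " valid pixels excluded")
  tab[!small, , drop = FALSE]
}

#' Mean-of-medians summary of a per-cell table
#'
#' @param per_cell a table from [per_cell_stats()].
#' @return A one-row data.frame: \code{n_cells}, \code{mean_E},
#'   \code{sem_E}, \code{mean_S}, \code{sem_S}.
#' @export
summarize_cells <- function(per_cell) {
  n <- nrow(per_cell)
  sem <- function(v) if (n > 1) sd(v) / sqrt(n) else NA_real_
  data.frame(n_cells = n,
             mean_E = mean(per_cell$median_E), sem_E = sem(per_cell$median_E),
             mean_S = mean(per_cell$median_S), sem_S = sem(per_cell$median_S))
}

#' Two-dimensional E-S histogram
#'
#' Bins the valid pixels of E and S maps into the 2D histogram used to
#' diagnose calibration quality and free-fluorophore contamination: a
#' well-calibrated fixed-stoichiometry sample forms horizontal clouds (S
#' independent of E).
#'
#' @param E,S maps (or vectors).
#' @param valid optional logical selector; defaults to jointly finite.
#' @param bins number of bins per axis.
#' @param limits common axis range; must cover at least \code{[-0.1, 1.1]}.
#' @return A \code{bins x bins} count matrix with attributes
#'   \code{e_breaks}, \code{s_breaks}; out-of-range pixels are dropped (the
#'   total count equals the number of valid in-range pixels).
#' @export
es_histogram <- function(E, S, valid = NULL, bins = 100,
                         limits = c(-0.2, 1.2)) {
  if (limits[1] > -0.1 || limits[2] < 1.1)
    stop("histogram limits must cover at least [-0.1, 1.1]")
  e <- as.vector(E); s <- as.vector(S)
  ok <- is.finite(e) & is.finite(s)
  if (!is.null(valid)) ok <- ok & as.vector(valid)
  e <- e[ok]; s <- s[ok]
  brk <- seq(limits[1], limits[2], length.out = bins + 1)
  ie <- findInterval(e, brk, rightmost.closed = TRUE)
  is_ <- findInterval(s, brk, rightmost.closed = TRUE)
  inr <- ie >= 1 & ie <= bins & is_ >= 1 & is_ <= bins
  h <- matrix(0L, bins, bins)
  if (any(inr)) {
    tab <- table(factor(ie[inr], levels = seq_len(bins)),
                 factor(is_[inr], levels = seq_len(bins)))
    h <- matrix(as.integer(tab), bins, bins)
  }
  attr(h, "e_breaks") <- brk
  attr(h, "s_breaks") <- brk
  h
}

#' Rank-correlation diagnostic between a FRET map and a reference
#'
#' Spearman rank correlation over valid pixels, used as a calibration
#' diagnostic: with the reference set to \code{I_AA} (the only channel
#' unaffected by FRET, a pure concentration readout) a near-zero
#' coefficient confirms concentration independence of E; with the reference
#' set to S it confirms the E-S decoupling of a fully calibrated dataset;
#' and with the reference set to the total donor intensity
#' \code{gamma_M * I_DD + I_DA_corr} it measures the residual effect of the
#' emission correction.
#'
#' @param E map (or vector) of FRET efficiencies.
#' @param reference map/vector of the same length.
#' @param valid optional logical selector.
#' @return The Spearman rho (scalar). Constant input yields \code{NA} with
#'   a warning.
#' @export
correlation_diagnostics <- function(E, reference, valid = NULL) {
  e <- as.vector(E); r <- as.vector(reference)
  stopifnot(length(e) == length(r))
  ok <- is.finite(e) & is.finite(r)
  if (!is.null(valid)) ok <- ok & as.vector(valid)
  if (sum(ok) < 10) stop("fewer than 10 valid pixels")
  if (sd(e[ok]) == 0 || sd(r[ok]) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  cor(e[ok], r[ok], method = "spearman")
}
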