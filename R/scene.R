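#' Camera model for the simulator
#'
#' Describes the detector applied on top of the expected photon intensities:
#' Poisson shot noise on the expected photon count (optional), a
#' multiplicative flat-field (pixelwise sensitivity, mean approximately 1),
#' a photons-to-counts gain, an additive dark offset and Gaussian read
#' noise. A rendered pixel value is
#' \code{gain * Poisson(expected) * flat + dark + N(0, read_noise_sd)}.
#'
#' @param dark_count additive offset (counts); scalar or matrix.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts),
#'   \code{>= 0}.
#' @param gain photons-to-counts conversion, \code{> 0}.
#' @param flat_field multiplicative sensitivity, strictly positive; scalar
#'   or matrix (see [vignette_flat_field()]).
#' @param shot_noise logical; apply Poisson noise to the expected photon
#'   counts.
#' @return An object of class \code{camera_model}.
#' @export
camera_model <- function(dark_count = 0, read_noise_sd = 0, gain = 1,
                         flat_field = 1, shot_noise = TRUE) {
  stopifnot(gain > 0, read_noise_sd >= 0, all(flat_field > 0))
  structure(list(dark_count = dark_count, read_noise_sd = read_noise_sd,
                 gain = gain, flat_field = flat_field,
                 shot_noise = isTRUE(shot_noise)),
            class = "camera_model")
}

#' Smooth radial flat-field map
#'
#' A mild centre-bright vignetting profile, \code{1 - amplitude * (r/r_max)^2},
#' rescaled to spatial mean 1 — a typical widefield illumination
#' inhomogeneity for the simulator's camera model.
#'
#' @param shape integer vector \code{c(rows, cols)}.
#' @param amplitude fractional corner-to-centre drop (default 0.08).
#' @return A matrix with mean 1.
#' @export
vignette_flat_field <- function(shape, amplitude = 0.08) {
  stopifnot(length(shape) == 2, amplitude >= 0, amplitude < 1)
  r <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
  c <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
  ff <- 1 - amplitude * (outer(r^2, c^2, `+`) / 2)
  ff / mean(ff)
}

#' Generate a ground-truth scene of synthetic cells
#'
#' Places non-overlapping elliptical "cells" on a dark background and draws,
#' for every in-cell pixel, a donor count \code{n_D}, an acceptor count
#' \code{n_A} and a true FRET probability \code{E_true}. Per-cell mean donor
#' counts are log-uniform over \code{concentration_range} (so a dataset
#' spans the full expression range); within a cell, pixel counts get
#' independent log-normal variation. The acceptor count follows the
#' stoichiometry \code{S} (donor fraction): \code{n_A = n_D (1 - S) / S};
#' \code{S = 1} gives donor-only cells and \code{S = 0} acceptor-only cells
#' (with \code{n_A} drawn in place of \code{n_D}). The FRET probability is a
#' per-cell base value (from \code{E_spec}, plus cell-to-cell variability)
#' with independent pixel-level spread, truncated to \code{[0, 1]}.
#'
#' @param shape image shape \code{c(rows, cols)}.
#' @param n_cells number of cells to place.
#' @param stoichiometry donor fraction \code{S} in \code{[0, 1]} (0.5 = 1:1
#'   construct).
#' @param E_spec per-cell base FRET probability: a scalar or a vector of
#'   length \code{n_cells}.
#' @param concentration_range range of per-cell mean donor counts (mean
#'   total counts for \code{S = 0}), sampled log-uniformly; spans two
#'   decades by default.
#' @param radius_range range of ellipse semi-axes in pixels.
#' @param e_cell_sd cell-to-cell standard deviation of the base FRET value.
#' @param e_pixel_sd pixel-level standard deviation of \code{E_true} within
#'   a cell.
#' @param count_lognorm_sd log-scale standard deviation of the pixel-level
#'   count variation within a cell.
#' @param mean_counts optional vector of per-cell mean donor counts
#'   (length \code{n_cells}), overriding the log-uniform draw — used by
#'   [simulate_fret_dataset()] to give every construct an identical,
#'   stratified expression-level distribution.
#' @param seed optional integer seed; fixed seed gives identical scenes.
#' @return An object of class \code{ground_truth_scene}: matrices \code{n_D},
#'   \code{n_A}, \code{E_true}, integer label map \code{cell_label}
#'   (0 = background), and the stoichiometry used.
#' @export
generate_scene <- function(shape = c(192, 192), n_cells = 4,
                           stoichiometry = 0.5, E_spec = 0.4,
                           concentration_range = c(4e3, 4e5),
                           radius_range = c(16, 26),
                           e_cell_sd = 0.02, e_pixel_sd = 0.1,
                           count_lognorm_sd = 0.2, mean_counts = NULL,
                           seed = NULL) {
  stopifnot(length(shape) == 2, n_cells >= 0,
            stoichiometry >= 0, stoichiometry <= 1,
            all(E_spec >= 0), all(E_spec <= 1),
            concentration_range[1] > 0,
            concentration_range[2] >= concentration_range[1])
  if (length(E_spec) == 1) E_spec <- rep(E_spec, max(n_cells, 1))
  if (n_cells > 0 && length(E_spec) != n_cells)
    stop("E_spec must be scalar or length n_cells")
  if (!is.null(mean_counts) && length(mean_counts) != n_cells)
    stop("mean_counts must have length n_cells")
  do_gen <- function() {
    nr <- shape[1]; nc <- shape[2]
    n_D <- matrix(0, nr, nc); n_A <- matrix(0, nr, nc)
    E_true <- matrix(0, nr, nc); lab <- matrix(0L, nr, nc)
    if (n_cells == 0)
      return(structure(list(n_D = n_D, n_A = n_A, E_true = E_true,
                            cell_label = lab, stoichiometry = stoichiometry),
                       class = "ground_truth_scene"))
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    centers <- matrix(NA_real_, n_cells, 2)
    radii <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      a <- runif(1, radius_range[1], radius_range[2])
      b <- runif(1, radius_range[1], radius_range[2])
      th <- runif(1, 0, pi)
      rmax <- max(a, b)
      placed <- FALSE
      for (try in 1:300) {
        cy <- runif(1, rmax + 2, nr - rmax - 2)
        cx <- runif(1, rmax + 2, nc - rmax - 2)
        if (i == 1 || all(sqrt((centers[seq_len(i - 1), 1] - cy)^2 +
                               (centers[seq_len(i - 1), 2] - cx)^2) >
                          radii[seq_len(i - 1)] + rmax + 2)) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", n_cells, " non-overlapping cells in a ",
             nr, "x", nc, " frame; enlarge the frame or reduce n_cells")
      centers[i, ] <- c(cy, cx); radii[i] <- rmax
      dy <- rowg - cy; dx <- colg - cx
      u <- (dy * cos(th) + dx * sin(th)) / a
      v <- (-dy * sin(th) + dx * cos(th)) / b
      inside <- (u^2 + v^2) <= 1
      idx <- which(inside)
      mean_count <- if (!is.null(mean_counts)) mean_counts[i] else
        exp(runif(1, log(concentration_range[1]),
                  log(concentration_range[2])))
      counts <- mean_count * exp(rnorm(length(idx), 0, count_lognorm_sd))
      e_base <- min(max(E_spec[i] + rnorm(1, 0, e_cell_sd), 0), 1)
      e_pix <- pmin(pmax(e_base + rnorm(length(idx), 0, e_pixel_sd), 0), 1)
      if (stoichiometry == 0) {            # acceptor-only cell
        n_A[idx] <- counts
      } else {
        n_D[idx] <- counts
        n_A[idx] <- counts * (1 - stoichiometry) / stoichiometry
      }
      # FRET requires both partners: single-fluorophore cells have E = 0
      E_true[idx] <- if (stoichiometry %in% c(0, 1)) 0 else e_pix
      lab[idx] <- i
    }
    structure(list(n_D = n_D, n_A = n_A, E_true = E_true, cell_label = lab,
                   stoichiometry = stoichiometry),
              class = "ground_truth_scene")
  }
  if (is.null(seed)) do_gen() else withr::with_seed(seed, do_gen())
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  d <- dim(x$n_D)
  cat(sprintf("<ground_truth_scene> %d x %d px, %d cells, S = %g\n",
              d[1], d[2],
              length(setdiff(unique(as.vector(x$cell_label)), 0L)),
              x$stoichiometry))
  invisible(x)
}

#' Render a raw image triplet from a ground-truth scene
#'
#' Applies the photophysical signal model pixelwise to obtain expected
#' photon intensities in each channel, then passes them through the camera
#' model: optional Poisson shot noise, gain, flat field, dark offset and
#' Gaussian read noise. With shot noise off, \code{read_noise_sd = 0},
#' \code{flat_field = 1} and \code{dark_count = 0}, the output equals
#' [expected_intensities()] exactly.
#'
#' @param scene a [generate_scene()] result.
#' @param inst an [instrument_model()].
#' @param cam a [camera_model()].
#' @param seed optional integer seed for the noise draws.
#' @return A raw [image_triplet()] (no mask); ground-truth labels are
#'   attached as \code{labels} for convenience in purely synthetic studies.
#' @export
render_triplet <- function(scene, inst, cam = camera_model(), seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"),
            inherits(cam, "camera_model"))
  dims <- dim(scene$n_D)
  ff <- cam$flat_field
  if (is.matrix(ff) && !identical(dim(ff), dims))
    stop("camera flat_field shape does not match the scene")
  exp_int <- expected_intensities(scene$n_D, scene$n_A, scene$E_true, inst)
  render_chan <- function(mu) {
    photons <- if (cam$shot_noise) {
      matrix(rpois(length(mu), as.vector(mu)), dims[1], dims[2])
    } else mu
    counts <- cam$gain * photons * ff + cam$dark_count
    if (cam$read_noise_sd > 0)
      counts <- counts + matrix(rnorm(length(mu), 0, cam$read_noise_sd),
                                dims[1], dims[2])
    counts
  }
  do_render <- function() {
    image_triplet(I_DD = render_chan(exp_int$I_DD),
                  I_DA = render_chan(exp_int$I_DA),
                  I_AA = render_chan(exp_int$I_AA),
                  labels = scene$cell_label,
                  provenance = list(rendered = TRUE,
                                    shot_noise = cam$shot_noise))
  }
  if (is.null(seed)) do_render() else withr::with_seed(seed, do_render())
}

#' Simulate a complete multi-construct FRET calibration study
#'
#' Generates the full synthetic counterpart of a FRET-standard calibration
#' experiment: several fields of view of cells for each FRET construct
#' (defaults: three 1:1 donor:acceptor standards with mean FRET
#' probabilities 0.503, 0.417 and 0.351, emulating short/medium/long linker
#' constructs), plus donor-only and acceptor-only fields for the crosstalk
#' calibration, all rendered through one instrument and camera. Per-cell
#' mean expression spans two decades.
#'
#' @param constructs named numeric vector of per-construct mean FRET
#'   probabilities.
#' @param cells_per_construct number of cells per construct (default 26).
#' @param cells_per_field how many cells share a field of view.
#' @param shape field-of-view shape in pixels.
#' @param stoichiometry donor fraction of the constructs (0.5 = 1:1).
#' @param donor_only_cells,acceptor_only_cells number of single-fluorophore
#'   calibration cells (defaults 10 and 12).
#' @param concentration_range per-cell mean donor count range (log-uniform).
#' @param inst an [instrument_model()]; the default realizes crosstalks
#'   0.421 / 0.110 and correction factors \code{gamma_M = 2.10},
#'   \code{beta_X = 1.167}.
#' @param cam a [camera_model()]; default has shot noise, dark offset 100,
#'   read noise 3 and a mild vignetting flat field.
#' @param seed integer seed making the whole dataset reproducible.
#' @param ... passed to [generate_scene()] (e.g. \code{e_pixel_sd}).
#' @return A list of class \code{fret_simulation} with elements
#'   \code{fields} (per-field list of \code{construct}, \code{scene},
#'   \code{raw}), \code{donor_only}, \code{acceptor_only} (same structure),
#'   \code{constructs}, \code{inst}, \code{cam}, \code{dark}, \code{flat}
#'   (the reference maps a user would acquire), and \code{stoichiometry}.
#' @export
simulate_fret_dataset <- function(constructs = c(hiE = 0.503, midE = 0.417,
                                                 loE = 0.351),
                                  cells_per_construct = 26,
                                  cells_per_field = 4,
                                  shape = c(192, 192),
                                  stoichiometry = 0.5,
                                  donor_only_cells = 10,
                                  acceptor_only_cells = 12,
                                  concentration_range = c(4e3, 4e5),
                                  inst = instrument_from_factors(),
                                  cam = NULL,
                                  seed = 1, ...) {
  if (is.null(cam))
    cam <- camera_model(dark_count = 100, read_noise_sd = 3, gain = 1,
                        flat_field = vignette_flat_field(shape),
                        shot_noise = TRUE)
  gen_group <- function(n_cells, S, E, seed0) {
    n_fields <- ceiling(n_cells / cells_per_field)
    out <- vector("list", n_fields)
    # stratified expression levels: every group of cells covers the same
    # log-spaced concentration grid (with jitter), as a shared expression
    # protocol does, so no construct is brighter than another by sampling
    # accident
    counts <- exp(seq(log(concentration_range[1]),
                      log(concentration_range[2]),
                      length.out = max(n_cells, 2)))[seq_len(n_cells)]
    counts <- withr::with_seed(seed0 + 7L,
                               sample(counts * exp(rnorm(n_cells, 0, 0.05))))
    left <- n_cells
    for (f in seq_len(n_fields)) {
      k <- min(cells_per_field, left); left <- left - k
      scene <- generate_scene(shape = shape, n_cells = k, stoichiometry = S,
                              E_spec = E,
                              concentration_range = concentration_range,
                              mean_counts = counts[(n_cells - left - k + 1):
                                                     (n_cells - left)],
                              seed = seed0 + 2L * f, ...)
      raw <- render_triplet(scene, inst, cam, seed = seed0 + 2L * f + 1L)
      out[[f]] <- list(scene = scene, raw = raw)
    }
    out
  }
  base <- as.integer(seed) * 101L
  fields <- list()
  for (ci in seq_along(constructs)) {
    grp <- gen_group(cells_per_construct, stoichiometry, constructs[ci],
                     base + 1000L * ci)
    for (g in grp) {
      g$construct <- names(constructs)[ci]
      fields[[length(fields) + 1L]] <- g
    }
  }
  donor_only <- gen_group(donor_only_cells, 1, 0, base + 50000L)
  acceptor_only <- gen_group(acceptor_only_cells, 0, 0, base + 60000L)
  dims <- shape
  dark <- matrix(cam$dark_count, dims[1], dims[2])
  flat <- if (is.matrix(cam$flat_field)) cam$flat_field else
    matrix(cam$flat_field, dims[1], dims[2])
  structure(list(fields = fields, donor_only = donor_only,
                 acceptor_only = acceptor_only, constructs = constructs,
                 inst = inst, cam = cam, dark = dark, flat = flat,
                 stoichiometry = stoichiometry, seed = seed),
            class = "fret_simulation")
}
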