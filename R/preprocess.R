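#' Camera correction: dark subtraction and flat-field division
#'
#' Applies the standard detector correction to one raw frame: subtract the
#' dark reference, then divide by the mean-normalized flat field. The flat
#' reference is itself dark-subtracted (if \code{flat_dark} is given) and
#' divided by its spatial mean, so the correction preserves the overall
#' intensity scale. Small negative values (read noise around zero) are
#' preserved, not clipped — clipping would bias downstream medians and fits.
#'
#' @param raw raw 2D intensity map (camera counts).
#' @param dark dark reference (scalar or matrix).
#' @param flat flat-field reference (scalar or matrix); strictly positive
#'   after its own dark subtraction.
#' @param flat_dark optional dark reference to subtract from \code{flat}
#'   before normalization.
#' @return Corrected map, \code{(raw - dark) / flat_normalized}.
#' @export
correct_camera <- function(raw, dark = 0, flat = 1, flat_dark = 0) {
  if (is.matrix(dark) && !identical(dim(dark), dim(raw)))
    stop("dark reference shape does not match the image")
  if (is.matrix(flat) && !identical(dim(flat), dim(raw)))
    stop("flat reference shape does not match the image")
  fl <- flat - flat_dark
  nbad <- sum(fl <= 0)
  if (nbad > 0)
    stop("flat field has ", nbad, " non-positive pixel(s) after dark subtraction")
  fl <- fl / mean(fl)
  (raw - dark) / fl
}

#' Affine channel transform
#'
#' A 2x3 affine map between channel coordinate frames,
#' \code{(row', col') = M \%*\% (row, col) + t}, with the RMS residual of the
#' registration fit attached. Coordinates are 1-based pixel centres.
#'
#' @param matrix 2x2 linear part (rotation, shear, magnification).
#' @param offset length-2 translation (pixels).
#' @param residual RMS residual of the displacement fit (pixels).
#' @return An object of class \code{channel_transform}.
#' @export
channel_transform <- function(matrix = diag(2), offset = c(0, 0),
                              residual = NA_real_) {
  stopifnot(identical(dim(matrix), c(2L, 2L)), length(offset) == 2)
  if (abs(det(matrix)) < 1e-12) stop("transform is not invertible")
  structure(list(matrix = matrix, offset = as.numeric(offset),
                 residual = residual),
            class = "channel_transform")
}

#' @export
print.channel_transform <- function(x, ...) {
  cat("<channel_transform>\n  linear part:\n")
  print(round(x$matrix, 6))
  cat(sprintf("  offset: (%.4f, %.4f) px, residual: %.4g px\n",
              x$offset[1], x$offset[2], x$residual))
  invisible(x)
}

#' Invert an affine channel transform
#' @param tr a [channel_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(tr) {
  stopifnot(inherits(tr, "channel_transform"))
  Mi <- solve(tr$matrix)
  channel_transform(Mi, -as.vector(Mi %*% tr$offset), tr$residual)
}

# Map 1-based (row, col) coordinate matrix (n x 2) through a transform.
transform_coords <- function(tr, rc) {
  t(tr$matrix %*% t(rc)) + matrix(tr$offset, nrow(rc), 2, byrow = TRUE)
}

#' Synthetic bead field for registration tests
#'
#' Random sub-pixel-positioned Gaussian spots on a flat background — the
#' synthetic analogue of a brightfield/fluorescent bead slide used to
#' calibrate the geometric mapping between detection channels.
#'
#' @param shape image shape.
#' @param n_beads number of beads.
#' @param sigma bead Gaussian radius (px).
#' @param amplitude peak intensity.
#' @param seed optional seed.
#' @return A matrix.
#' @export
make_bead_image <- function(shape = c(256, 256), n_beads = 300, sigma = 1.5,
                            amplitude = 1000, seed = NULL) {
  gen <- function() {
    img <- matrix(0, shape[1], shape[2])
    cy <- runif(n_beads, 4, shape[1] - 3)
    cx <- runif(n_beads, 4, shape[2] - 3)
    half <- ceiling(4 * sigma)
    for (i in seq_len(n_beads)) {
      r0 <- max(1, floor(cy[i]) - half); r1 <- min(shape[1], floor(cy[i]) + half)
      c0 <- max(1, floor(cx[i]) - half); c1 <- min(shape[2], floor(cx[i]) + half)
      rr <- r0:r1; cc <- c0:c1
      img[rr, cc] <- img[rr, cc] + amplitude *
        exp(-(outer((rr - cy[i])^2, (cc - cx[i])^2, `+`)) / (2 * sigma^2))
    }
    img
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Cross-correlation displacement of one block pair with sub-pixel
# (parabolic) peak interpolation. Returns c(dy, dx) such that
# moving(x + d) ~ ref(x), or NULL when no usable peak.
block_displacement <- function(ref, mov, max_shift) {
  a <- ref - mean(ref); b <- mov - mean(mov)
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NULL)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  n <- dim(cc)
  # restrict to plausible shifts
  wrap <- function(k, N) ifelse(k > N / 2, k - N, k)
  iy <- wrap(seq_len(n[1]) - 1, n[1]); ix <- wrap(seq_len(n[2]) - 1, n[2])
  ok <- outer(abs(iy) <= max_shift, abs(ix) <= max_shift)
  cc_ok <- cc; cc_ok[!ok] <- -Inf
  pk <- arrayInd(which.max(cc_ok), n)
  peak_val <- cc[pk]
  if (!is.finite(peak_val)) return(NULL)
  subpix <- function(idx, dimlen, along) {
    get <- function(off) {
      j <- pk
      j[along] <- ((j[along] - 1 + off) %% dimlen) + 1
      cc[j[1], j[2]]
    }
    cm <- get(-1); c0 <- get(0); cp <- get(1)
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }
  dy <- wrap(pk[1] - 1, n[1]) + subpix(pk[1], n[1], 1)
  dx <- wrap(pk[2] - 1, n[2]) + subpix(pk[2], n[2], 2)
  c(dy, dx)
}

#' Estimate the affine transform between two channels from a bead field
#'
#' Computes local cross-correlations between corresponding blocks of the
#' reference and moving images; each block yields one sub-pixel displacement
#' vector at its centre, and a 2D affine transform (translation, rotation,
#' shear, magnification) is fitted to the displacement map by least squares.
#'
#' @param ref_image reference-channel image (e.g. acceptor channel).
#' @param moving_image image of the same bead field in the other channel.
#' @param block_size side of the square correlation blocks (px).
#' @param max_shift largest displacement considered inside a block (px).
#' @return A [channel_transform()] \code{T} such that
#'   \code{moving(T(x)) ~ ref(x)}; apply it with [apply_registration()] to
#'   resample the moving channel onto the reference grid. The RMS residual
#'   of the affine fit is reported in the transform.
#' @export
estimate_registration <- function(ref_image, moving_image, block_size = 64,
                                  max_shift = 15) {
  stopifnot(identical(dim(ref_image), dim(moving_image)))
  n <- dim(ref_image)
  nby <- n[1] %/% block_size; nbx <- n[2] %/% block_size
  pts <- NULL; disp <- NULL
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      rr <- ((by - 1) * block_size + 1):(by * block_size)
      cc <- ((bx - 1) * block_size + 1):(bx * block_size)
      d <- block_displacement(ref_image[rr, cc], moving_image[rr, cc],
                              max_shift)
      if (is.null(d)) next
      pts <- rbind(pts, c(mean(rr), mean(cc)))
      disp <- rbind(disp, d)
    }
  }
  if (is.null(pts) || nrow(pts) < 3)
    stop("insufficient registration features: fewer than 3 usable blocks")
  # displacement model: d = (M - I) x + t, fitted per component
  X <- cbind(pts, 1)
  fit <- qr.solve(X, disp)                  # 3 x 2: rows (row-coef, col-coef, t)
  M <- diag(2) + t(fit[1:2, ])
  tvec <- fit[3, ]
  res <- disp - X %*% fit
  channel_transform(M, tvec,
                    residual = sqrt(mean(rowSums(res^2))))
}

#' Resample an image through an affine channel transform
#'
#' Produces \code{out(x) = image(T(x))} on the reference grid, with bilinear
#' (default) or nearest-neighbour interpolation. Pixels mapping outside the
#' source frame are returned as \code{NA} and must be excluded from masks —
#' zero-filling them would bias the calibration fits.
#'
#' @param image 2D map to resample (the moving channel).
#' @param transform a [channel_transform()] from [estimate_registration()].
#' @param interpolation \code{"bilinear"} or \code{"nearest"}.
#' @return The resampled matrix, same shape, with \code{NA} where invalid.
#' @export
apply_registration <- function(image, transform,
                               interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(transform, "channel_transform"))
  n <- dim(image)
  grid <- cbind(rep(seq_len(n[1]), n[2]), rep(seq_len(n[2]), each = n[1]))
  src <- transform_coords(transform, grid)
  y <- src[, 1]; x <- src[, 2]
  out <- rep(NA_real_, nrow(grid))
  if (interpolation == "nearest") {
    yi <- round(y); xi <- round(x)
    ok <- yi >= 1 & yi <= n[1] & xi >= 1 & xi <= n[2]
    out[ok] <- image[cbind(yi[ok], xi[ok])]
  } else {
    y0 <- floor(y); x0 <- floor(x)
    ok <- y0 >= 1 & y0 + 1 <= n[1] & x0 >= 1 & x0 + 1 <= n[2]
    fy <- y[ok] - y0[ok]; fx <- x[ok] - x0[ok]
    i00 <- cbind(y0[ok], x0[ok]); i10 <- cbind(y0[ok] + 1, x0[ok])
    i01 <- cbind(y0[ok], x0[ok] + 1); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- image[i00] * (1 - fy) * (1 - fx) + image[i10] * fy * (1 - fx) +
               image[i01] * (1 - fy) * fx + image[i11] * fy * fx
  }
  matrix(out, n[1], n[2])
}

#' Segment cells from an image triplet
#'
#' Builds the in-cell mask gating which pixels enter calibration and
#' statistics: Otsu threshold on the Gaussian-smoothed, log-compressed sum
#' image \code{log(1 + I_DD + I_AA)}, holes filled, connected components
#' below a minimum area removed. The log compression keeps dim cells above
#' threshold when expression levels span decades. Pixels invalidated by
#' registration (\code{NA} in any channel) are excluded. The method is
#' deliberately simple — the mask only selects pixels, all quantification
#' happens downstream.
#'
#' @param triplet a camera-corrected [image_triplet()].
#' @param smooth_sigma Gaussian smoothing sd before thresholding (px).
#' @param min_area minimum connected-component area (px).
#' @return The input triplet with \code{mask} and integer \code{labels}
#'   filled in. An empty mask triggers a warning.
#' @export
segment_cells <- function(triplet, smooth_sigma = 2, min_area = 100) {
  stopifnot(inherits(triplet, "image_triplet"))
  s <- triplet$I_DD + triplet$I_AA
  valid <- is.finite(s)
  s[!valid] <- 0
  s <- log1p(pmax(s, 0))
  sm <- EBImage::gblur(EBImage::Image(s), sigma = smooth_sigma)
  sm <- EBImage::imageData(sm)
  rng <- range(sm)
  if (diff(rng) <= 0) {
    mask <- matrix(FALSE, nrow(s), ncol(s))
  } else {
    s01 <- (sm - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(s01))
    mask <- s01 > th
  }
  mask <- mask & valid
  lab <- EBImage::imageData(EBImage::bwlabel(
    EBImage::fillHull(EBImage::Image(mask))))
  lab[!valid] <- 0
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0
  lab <- matrix(match(lab, c(0, keep)) - 1L, nrow(lab), ncol(lab))
  mask <- lab > 0
  if (!any(mask))
    warning("segmentation produced an empty mask")
  triplet$mask <- mask
  triplet$labels <- lab
  triplet$provenance$segmentation <- list(method = "otsu_sum",
                                          smooth_sigma = smooth_sigma,
                                          min_area = min_area)
  triplet
}

#' Camera-correct and segment one raw field
#'
#' Convenience wrapper for synthetic or pre-registered data: applies
#' [correct_camera()] to the three channels with shared references, then
#' [segment_cells()].
#'
#' @param raw a raw [image_triplet()].
#' @param dark,flat camera references (scalar or matrix).
#' @param ... passed to [segment_cells()].
#' @return A corrected, masked, labelled [image_triplet()].
#' @export
preprocess_field <- function(raw, dark = 0, flat = 1, ...) {
  stopifnot(inherits(raw, "image_triplet"))
  tr <- image_triplet(correct_camera(raw$I_DD, dark, flat),
                      correct_camera(raw$I_DA, dark, flat),
                      correct_camera(raw$I_AA, dark, flat),
                      provenance = c(raw$provenance,
                                     list(camera_corrected = TRUE)))
  segment_cells(tr, ...)
}
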