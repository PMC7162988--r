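#' Stoichiometry-filter configuration
#'
#' Parameters of the confidence weighting and the weighted Gaussian filter.
#' The defaults are the typical working point for a 1:1 construct:
#' expected stoichiometry 0.5, sensitivity \code{sigma_S = 0.1} (pixels
#' with S outside roughly \code{[0.4, 0.6]} are strongly down-weighted), a
#' Gaussian kernel of sd 1.5 px truncated to 7x7, and a weight threshold
#' of 0.5 on the pixel's own confidence.
#'
#' @param S0 expected stoichiometry (fraction).
#' @param sigma_S width of the confidence Gaussian (fraction), \code{> 0}.
#' @param sigma_gauss spatial Gaussian kernel sd (px), \code{> 0}.
#' @param kernel_size odd kernel side length \code{>= 3} (px).
#' @param W_th weight threshold in \code{[0, 1]}; output pixels whose own
#'   raw weight falls below it are invalidated.
#' @return An object of class \code{filter_config}.
#' @export
filter_config <- function(S0 = 0.5, sigma_S = 0.1, sigma_gauss = 1.5,
                          kernel_size = 7, W_th = 0.5) {
  stopifnot(sigma_S > 0, sigma_gauss > 0,
            kernel_size >= 3, kernel_size %% 2 == 1,
            W_th >= 0, W_th <= 1)
  structure(list(S0 = S0, sigma_S = sigma_S, sigma_gauss = sigma_gauss,
                 kernel_size = as.integer(kernel_size), W_th = W_th),
            class = "filter_config")
}

#' Confidence weights from the stoichiometry map
#'
#' Scores every pixel by how far its measured stoichiometry deviates from
#' the expected value:
#' \deqn{W = \exp\left(-\frac{(S - S_0)^2}{2\sigma_S^2}\right),}
#' a Gaussian score in \code{(0, 1]} reaching 1 exactly at \code{S = S_0}.
#' Invalid (NA) stoichiometry pixels get weight 0, so background and
#' aberrant pixels drop out of any weighted statistic.
#'
#' @param S stoichiometry map.
#' @param S0 expected stoichiometry.
#' @param sigma_S sensitivity (fraction), \code{> 0}.
#' @return A weight matrix in \code{[0, 1]}.
#' @export
confidence_weights <- function(S, S0 = 0.5, sigma_S = 0.1) {
  stopifnot(sigma_S > 0)
  W <- exp(-(S - S0)^2 / (2 * sigma_S^2))
  W[!is.finite(W)] <- 0
  W
}

#' Truncated 2D Gaussian kernel
#'
#' @param sigma kernel standard deviation (px).
#' @param size odd side length (px).
#' @return A \code{size x size} matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma = 1.5, size = 7) {
  stopifnot(size %% 2 == 1, size >= 1, sigma > 0)
  h <- (size - 1) / 2
  g1 <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# 2D convolution with zero padding (kernel must have odd dimensions).
conv2_zero <- function(x, k) {
  n <- dim(x); kk <- dim(k)
  hy <- (kk[1] - 1) / 2; hx <- (kk[2] - 1) / 2
  pad <- matrix(0, n[1] + 2 * hy, n[2] + 2 * hx)
  pad[(hy + 1):(hy + n[1]), (hx + 1):(hx + n[2])] <- x
  out <- matrix(0, n[1], n[2])
  for (i in seq_len(kk[1])) {
    for (j in seq_len(kk[2])) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[i:(i + n[1] - 1), j:(j + n[2] - 1)]
    }
  }
  out
}

#' Stoichiometry-weighted Gaussian filter
#'
#' Spatially smooths a FRET map while excluding low-confidence pixels, via
#' the normalized convolution
#' \deqn{E_{filt} = \frac{(W \circ E) * G}{W * G},}
#' where \code{G} is a truncated Gaussian kernel, \code{*} convolution and
#' \code{\circ} the elementwise product. A pixel with weight zero
#' contributes nothing to any neighbour; the output at each pixel is a
#' convex combination of the E values under the kernel support with
#' positive weight. Because the Gaussian confidence score never reaches
#' zero, an additional threshold is applied on the pixel's own raw weight:
#' pixels with \code{W < W_th} are invalidated (\code{NA}) in the output,
#' which removes background and anomalous-stoichiometry structures
#' entirely. Outside the image, weights are taken as zero (kernel
#' renormalization over the in-image support).
#'
#' @param E FRET map (NA = invalid).
#' @param W weight map, same shape, e.g. from [confidence_weights()].
#' @param config a [filter_config()].
#' @return The filtered map \code{E_filt} with \code{NA} at invalidated
#'   pixels.
#' @export
weighted_gaussian_filter <- function(E, W, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"), identical(dim(E), dim(W)))
  W <- ifelse(is.finite(W) & is.finite(E), W, 0)
  E0 <- ifelse(is.finite(E), E, 0)
  G <- gaussian_kernel(config$sigma_gauss, config$kernel_size)
  num <- conv2_zero(W * E0, G)
  den <- conv2_zero(W, G)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out[W < config$W_th] <- NA_real_
  out
}
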