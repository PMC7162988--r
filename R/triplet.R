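#' Image triplet container
#'
#' Holds the three intensity images of one field of view — \code{I_DD}
#' (donor excitation / donor emission), \code{I_DA} (donor excitation /
#' acceptor emission) and \code{I_AA} (acceptor excitation / acceptor
#' emission) — together with an optional boolean in-cell mask and a
#' provenance record of the corrections applied. Pixels invalidated by
#' resampling (out-of-frame after registration) are \code{NA} in the images
#' and excluded from masks.
#'
#' @param I_DD,I_DA,I_AA numeric matrices of identical dimensions.
#' @param mask optional logical matrix of the same dimensions (TRUE =
#'   in-cell).
#' @param labels optional integer matrix of connected-component labels
#'   (0 = background).
#' @param provenance a list recording applied corrections.
#' @return An object of class \code{image_triplet}.
#' @export
image_triplet <- function(I_DD, I_DA, I_AA, mask = NULL, labels = NULL,
                          provenance = list()) {
  dims <- dim(I_DD)
  if (is.null(dims) || length(dims) != 2)
    stop("channel images must be 2D matrices")
  if (!identical(dim(I_DA), dims) || !identical(dim(I_AA), dims))
    stop("the three channel images must share one shape")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims)) stop("mask shape must match the images")
    mask <- mask & !is.na(I_DD) & !is.na(I_DA) & !is.na(I_AA)
  }
  if (!is.null(labels) && !identical(dim(labels), dims))
    stop("label map shape must match the images")
  structure(list(I_DD = I_DD, I_DA = I_DA, I_AA = I_AA,
                 mask = mask, labels = labels, provenance = provenance),
            class = "image_triplet")
}

#' @export
print.image_triplet <- function(x, ...) {
  d <- dim(x$I_DD)
  cat(sprintf("<image_triplet> %d x %d px", d[1], d[2]))
  if (!is.null(x$mask))
    cat(sprintf(", %d in-cell px", sum(x$mask, na.rm = TRUE)))
  if (!is.null(x$labels))
    cat(sprintf(", %d cells", length(setdiff(unique(as.vector(x$labels)), 0L))))
  cat("\n")
  if (length(x$provenance))
    cat("  corrections:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' Gather masked pixel tuples from one or more triplets
#'
#' Pools the in-mask pixel values of a list of triplets into one matrix of
#' \code{(I_DD, I_DA, I_AA)} tuples, tagging each pixel with a dataset-wide
#' cell identifier (labelled triplets) or a per-triplet identifier
#' otherwise. This is the form consumed by the calibration fits.
#'
#' @param triplets an \code{image_triplet} or list of them; each must carry
#'   a mask (or labels, from which the mask is taken as \code{labels > 0}).
#' @return A data.frame with columns \code{I_DD}, \code{I_DA}, \code{I_AA},
#'   \code{cell}.
#' @export
gather_pixels <- function(triplets) {
  if (inherits(triplets, "image_triplet")) triplets <- list(triplets)
  out <- vector("list", length(triplets))
  offset <- 0L
  for (i in seq_along(triplets)) {
    tr <- triplets[[i]]
    stopifnot(inherits(tr, "image_triplet"))
    lab <- tr$labels
    msk <- tr$mask
    if (is.null(msk) && !is.null(lab)) msk <- lab > 0
    if (is.null(msk))
      stop("triplet ", i, " has neither mask nor labels")
    msk <- msk & is.finite(tr$I_DD) & is.finite(tr$I_DA) & is.finite(tr$I_AA)
    keep <- which(msk)
    cell <- if (!is.null(lab)) as.integer(lab[keep]) else rep(1L, length(keep))
    out[[i]] <- data.frame(I_DD = tr$I_DD[keep], I_DA = tr$I_DA[keep],
                           I_AA = tr$I_AA[keep], cell = cell + offset)
    offset <- offset + if (length(cell)) max(cell) else 0L
  }
  do.call(rbind, out)
}
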