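# File formats: image triplets and float maps as 32-bit TIFF with a JSON
# sidecar recording channel order and a power-of-two intensity scale (the
# TIFF layer stores values normalized to [0, 1] at 2^-32 resolution, i.e.
# a relative quantization of ~5e-10 of the image maximum); calibration
# results and diagnostics as JSON; tables as CSV.

scale_pow2 <- function(x) {
  m <- max(abs(x[is.finite(x)]), 1)
  2^ceiling(log2(m))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image triplet as a 3-page 32-bit TIFF
#'
#' Channels are stored in the declared order with intensities divided by a
#' power-of-two scale factor (exact in binary floating point; the 32-bit
#' TIFF quantization is then ~5e-10 of the scale); the channel order and
#' scale are recorded in a JSON sidecar \code{<path>.json}, never guessed
#' at read time.
#'
#' @param triplet an [image_triplet()].
#' @param path output TIFF path.
#' @param channel_order permutation of \code{c("DD", "DA", "AA")}.
#' @return \code{path}, invisibly.
#' @export
write_triplet <- function(triplet, path,
                          channel_order = c("DD", "DA", "AA")) {
  stopifnot(inherits(triplet, "image_triplet"),
            setequal(channel_order, c("DD", "DA", "AA")))
  imgs <- list(DD = triplet$I_DD, DA = triplet$I_DA, AA = triplet$I_AA)
  imgs <- imgs[channel_order]
  sc <- scale_pow2(unlist(imgs, use.names = FALSE))
  pages <- lapply(imgs, function(m) m / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(channel_order = channel_order, scale = sc,
                            shape = dim(triplet$I_DD)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image triplet from TIFF
#'
#' Accepts a 3-page TIFF (with its JSON sidecar, or an explicit
#' \code{channel_order}) or three single-page TIFF paths given in
#' \code{channel_order}. The channel order is mandatory configuration — a
#' silent channel swap is the most dangerous failure mode of three-image
#' FRET — so it must come from the sidecar or the caller, never a guess.
#'
#' @param path one 3-page TIFF path, or a character vector of three paths.
#' @param channel_order order of the pages/files as permutation of
#'   \code{c("DD", "DA", "AA")}; defaults to the sidecar's record.
#' @param scale intensity scale to undo; defaults to the sidecar's record
#'   (or 1 without a sidecar).
#' @return An [image_triplet()].
#' @export
read_triplet <- function(path, channel_order = NULL, scale = NULL) {
  if (length(path) == 1) {
    meta <- if (file.exists(sidecar_path(path)))
      jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    else NULL
    if (is.null(channel_order)) channel_order <- meta$channel_order
    if (is.null(scale)) scale <- if (is.null(meta)) 1 else meta$scale
    if (is.null(channel_order))
      stop("channel_order must be given (no sidecar found for ", path, ")")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (length(pages) != 3)
      stop("expected a 3-page TIFF, found ", length(pages), " page(s) in ",
           path)
  } else if (length(path) == 3) {
    if (is.null(channel_order))
      stop("channel_order must be given for three single-page files")
    if (is.null(scale)) scale <- 1
    pages <- lapply(path, tiff::readTIFF)
  } else stop("path must be one 3-page TIFF or three single-page TIFFs")
  stopifnot(setequal(channel_order, c("DD", "DA", "AA")))
  shapes <- lapply(pages, dim)
  if (length(unique(vapply(shapes, paste, collapse = "x", ""))) != 1)
    stop("channel shapes differ: ",
         paste(vapply(shapes, paste, collapse = "x", ""), collapse = ", "))
  pages <- lapply(pages, function(m) { m[is.nan(m)] <- NA; m * scale })
  names(pages) <- channel_order
  image_triplet(pages[["DD"]], pages[["DA"]], pages[["AA"]],
                provenance = list(source = path))
}

#' Write a single value map (E, S, W, ...) as TIFF
#'
#' Stored with the same power-of-two scaling convention and JSON sidecar as
#' [write_triplet()]. Negative values (noise) are handled by an offset
#' recorded in the sidecar, and invalid (\code{NA}) pixels by a validity
#' mask stored as a second TIFF page.
#'
#' @param map numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  sc <- scale_pow2(map)
  m <- map / sc
  # negatives (noise) are offset into [0, 1] and the offset recorded
  off <- 0
  if (any(m < 0, na.rm = TRUE)) { off <- 1; m <- (m + 1) / 2 }
  valid <- is.finite(m) * 1
  m[!is.finite(m)] <- 0
  tiff::writeTIFF(list(m, valid), path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = sc, offset_half = off),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a value map written by [write_map()]
#' @param path TIFF path.
#' @return A numeric matrix with \code{NA} at invalid pixels.
#' @export
read_map <- function(path) {
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list(scale = 1, offset_half = 0)
  pages <- tiff::readTIFF(path, all = TRUE)
  m <- pages[[1]]
  if (length(pages) > 1) m[pages[[2]] < 0.5] <- NA
  if (isTRUE(meta$offset_half == 1)) m <- 2 * m - 1
  m * meta$scale
}

#' Save calibration factors as JSON
#'
#' @param factors a [correction_factors()] object.
#' @param path output JSON path.
#' @param inputs optional character vector of input files; their MD5
#'   digests are recorded for provenance.
#' @return \code{path}, invisibly.
#' @export
save_calibration <- function(factors, path, inputs = NULL) {
  stopifnot(inherits(factors, "correction_factors"))
  rec <- unclass(factors)
  rec$software <- paste0("fretq ",
                         as.character(utils::packageVersion("fretq")))
  if (!is.null(inputs))
    rec$input_digests <- as.list(tools::md5sum(inputs))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Load calibration factors from JSON
#' @param path JSON path written by [save_calibration()].
#' @return A [correction_factors()] object.
#' @export
load_calibration <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v) || length(v) == 0) NA_real_ else
    as.numeric(v)
  correction_factors(alpha_BT = num(rec$alpha_BT), delta_DE = num(rec$delta_DE),
                     gamma_M = num(rec$gamma_M), beta_X = num(rec$beta_X),
                     alpha_sd = num(rec$alpha_sd), delta_sd = num(rec$delta_sd),
                     gamma_sd = num(rec$gamma_sd), beta_sd = num(rec$beta_sd),
                     r_squared = num(rec$r_squared),
                     n_pixels = num(rec$n_pixels), n_cells = num(rec$n_cells),
                     S0_assumed = num(rec$S0_assumed))
}

#' Save a registration transform as JSON
#' @param transform a [channel_transform()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
save_transform <- function(transform, path) {
  stopifnot(inherits(transform, "channel_transform"))
  jsonlite::write_json(list(matrix = transform$matrix,
                            offset = transform$offset,
                            residual = transform$residual),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load a registration transform from JSON
#' @param path JSON path written by [save_transform()].
#' @return A [channel_transform()].
#' @export
load_transform <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_transform(matrix(unlist(rec$matrix), 2, 2), rec$offset,
                    if (is.null(rec$residual)) NA_real_ else rec$residual)
}
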