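#' Analyze a simulated calibration study end to end (in memory)
#'
#' Runs the complete analysis chain on a [simulate_fret_dataset()] result,
#' exactly as it would run on microscope data: camera correction and
#' segmentation of every field, crosstalk calibration from the
#' single-fluorophore fields, the single-step plane fit on the pooled
#' construct pixels, pixelwise E/S maps, per-cell medians grouped by
#' construct, and the rank-correlation diagnostics of calibration quality.
#'
#' @param sim a \code{fret_simulation} from [simulate_fret_dataset()].
#' @param S0 stoichiometry assumed in the plane fit.
#' @param boot_reps bootstrap repetitions for calibration uncertainties
#'   (0 disables, the default here; see [calibrate_dataset()]).
#' @param min_area segmentation minimum cell area (px).
#' @param seed seed for the calibration bootstraps.
#' @return A list with \code{calibration} (a [correction_factors()]),
#'   \code{pixels} (data.frame of pooled in-cell pixels: \code{E}, \code{S},
#'   \code{I_AA}, \code{total_donor}, \code{construct}, \code{cell}),
#'   \code{per_cell} (per-cell medians with construct tags),
#'   \code{per_construct} (mean-of-medians +/- SEM per construct), and
#'   \code{diagnostics} (Spearman rho of E vs I_AA, E vs S, E vs total
#'   donor intensity; pixel count).
#' @export
analyze_fret_study <- function(sim, S0 = 0.5, boot_reps = 0,
                               min_area = 100, seed = NULL) {
  stopifnot(inherits(sim, "fret_simulation"))
  prep <- function(entries) lapply(entries, function(e)
    preprocess_field(e$raw, sim$dark, sim$flat, min_area = min_area))
  donor <- prep(sim$donor_only)
  acceptor <- prep(sim$acceptor_only)
  fret <- prep(sim$fields)
  cal <- calibrate_dataset(donor, acceptor, fret, S0 = S0,
                           boot_reps = boot_reps, seed = seed)
  rows <- list(); cells <- list()
  cell_offset <- 0L
  for (i in seq_along(fret)) {
    tr <- fret[[i]]
    maps <- es_maps(tr, cal)
    keep <- which(maps$valid & tr$mask)
    f <- corrected_fret_image(tr, cal)
    rows[[i]] <- data.frame(
      E = maps$E[keep], S = maps$S[keep], I_AA = tr$I_AA[keep],
      total_donor = cal$gamma_M * tr$I_DD[keep] + f[keep],
      construct = sim$fields[[i]]$construct,
      cell = as.integer(tr$labels[keep]) + cell_offset)
    if (!is.null(maps$per_cell) && nrow(maps$per_cell)) {
      pc <- maps$per_cell
      pc$cell <- pc$cell + cell_offset
      pc$construct <- sim$fields[[i]]$construct
      cells[[i]] <- pc
    }
    cell_offset <- cell_offset + max(0L, as.integer(max(tr$labels)))
  }
  pixels <- do.call(rbind, rows)
  per_cell <- do.call(rbind, cells)
  per_construct <- do.call(rbind, lapply(names(sim$constructs), function(cn) {
    sub <- per_cell[per_cell$construct == cn, , drop = FALSE]
    out <- summarize_cells(sub)
    out$construct <- cn
    out$E_generative <- unname(sim$constructs[cn])
    out
  }))
  diagnostics <- list(
    rho_E_IAA = correlation_diagnostics(pixels$E, pixels$I_AA),
    rho_E_S = correlation_diagnostics(pixels$E, pixels$S),
    rho_E_total_donor = correlation_diagnostics(pixels$E,
                                                pixels$total_donor),
    n_pixels = nrow(pixels))
  list(calibration = cal, pixels = pixels, per_cell = per_cell,
       per_construct = per_construct, diagnostics = diagnostics)
}

#' Pipeline run configuration
#'
#' Paths and options for the file-based end-to-end pipeline. The channel
#' order of every triplet TIFF is taken from its JSON sidecar or must be
#' supplied explicitly — it is never inferred from the data.
#'
#' @param fret character vector of FRET-sample triplet TIFFs.
#' @param donor_only,acceptor_only triplet TIFFs of the single-fluorophore
#'   calibration samples (may be empty when \code{calibration} is given).
#' @param dark,flat optional reference TIFF paths (single page).
#' @param calibration optional path to an existing calibration JSON; when
#'   given, the crosstalk and plane-fit stages are skipped.
#' @param channel_order triplet page order, or NULL to require sidecars.
#' @param S0 assumed stoichiometry for the plane fit.
#' @param filter a [filter_config()] for the confidence-weighted output
#'   maps, or NULL to skip filtering.
#' @param min_area segmentation minimum cell area.
#' @param seed seed for the calibration bootstraps.
#' @param out_dir output directory (created if needed).
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(fret, donor_only = character(),
                       acceptor_only = character(),
                       dark = NULL, flat = NULL, calibration = NULL,
                       channel_order = NULL, S0 = 0.5,
                       filter = filter_config(), min_area = 100,
                       seed = 1, out_dir = ".") {
  structure(list(fret = fret, donor_only = donor_only,
                 acceptor_only = acceptor_only, dark = dark, flat = flat,
                 calibration = calibration, channel_order = channel_order,
                 S0 = S0, filter = filter, min_area = min_area,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the file-based analysis pipeline
#'
#' End-to-end run over TIFF inputs: read and camera-correct every triplet,
#' segment cells, calibrate (crosstalk factors from the single-fluorophore
#' samples, then the single-step plane fit — or load a supplied calibration
#' JSON), compute pixelwise E/S/W maps and the confidence-filtered FRET
#' map, and write all outputs under \code{out_dir}: \code{calibration.json},
#' per-field \code{E_*.tif}, \code{S_*.tif}, \code{W_*.tif},
#' \code{E_filt_*.tif} and \code{mask_*.tif}, \code{per_cell.csv}, and
#' \code{diagnostics.json} (Spearman diagnostics, plane-fit R^2, pixel
#' counts, software version and input digests). Every reported number is
#' recomputable from the saved intermediates.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the calibration, diagnostics and output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dark <- if (is.null(config$dark)) 0 else
    stage("references", tiff::readTIFF(config$dark) * {
      meta <- sidecar_path(config$dark)
      if (file.exists(meta)) jsonlite::read_json(meta)$scale else 1
    })
  flat <- if (is.null(config$flat)) 1 else stage("references", {
    meta <- sidecar_path(config$flat)
    sc <- if (file.exists(meta)) jsonlite::read_json(meta)$scale else 1
    tiff::readTIFF(config$flat) * sc
  })
  load_group <- function(paths) stage("preprocess", lapply(paths, function(p)
    preprocess_field(read_triplet(p, config$channel_order), dark, flat,
                     min_area = config$min_area)))
  fret <- load_group(config$fret)
  if (!is.null(config$calibration)) {
    cal <- stage("calibration", load_calibration(config$calibration))
  } else {
    donor <- load_group(config$donor_only)
    acceptor <- load_group(config$acceptor_only)
    cal <- stage("calibration",
                 calibrate_dataset(donor, acceptor, fret, S0 = config$S0,
                                   boot_reps = 200, seed = config$seed))
  }
  cal_path <- file.path(config$out_dir, "calibration.json")
  save_calibration(cal, cal_path,
                   inputs = c(config$fret, config$donor_only,
                              config$acceptor_only))
  pooled_E <- pooled_S <- pooled_AA <- list()
  per_cell <- list()
  paths <- c(calibration = cal_path)
  for (i in seq_along(fret)) {
    tr <- fret[[i]]
    maps <- es_maps(tr, cal)
    W <- confidence_weights(maps$S, config$S0,
                            if (is.null(config$filter)) 0.1
                            else config$filter$sigma_S)
    tag <- sprintf("%03d", i)
    p <- c(E = file.path(config$out_dir, paste0("E_", tag, ".tif")),
           S = file.path(config$out_dir, paste0("S_", tag, ".tif")),
           W = file.path(config$out_dir, paste0("W_", tag, ".tif")),
           mask = file.path(config$out_dir, paste0("mask_", tag, ".tif")))
    write_map(maps$E, p[["E"]]); write_map(maps$S, p[["S"]])
    write_map(W, p[["W"]])
    tiff::writeTIFF((tr$labels > 0) * 1, p[["mask"]], bits.per.sample = 8L)
    if (!is.null(config$filter)) {
      ef <- weighted_gaussian_filter(maps$E, W, config$filter)
      p[["E_filt"]] <- file.path(config$out_dir,
                                 paste0("E_filt_", tag, ".tif"))
      write_map(ef, p[["E_filt"]])
    }
    paths <- c(paths, p)
    keep <- which(maps$valid & tr$mask)
    pooled_E[[i]] <- maps$E[keep]; pooled_S[[i]] <- maps$S[keep]
    pooled_AA[[i]] <- tr$I_AA[keep]
    if (!is.null(maps$per_cell) && nrow(maps$per_cell)) {
      pc <- maps$per_cell; pc$field <- i
      per_cell[[i]] <- pc
    }
  }
  per_cell <- do.call(rbind, per_cell)
  pc_path <- file.path(config$out_dir, "per_cell.csv")
  write.csv(per_cell, pc_path, row.names = FALSE)
  E <- unlist(pooled_E); S <- unlist(pooled_S); AA <- unlist(pooled_AA)
  diagnostics <- list(
    rho_E_IAA = if (length(E) >= 10) correlation_diagnostics(E, AA)
                else NA_real_,
    rho_E_S = if (length(E) >= 10) correlation_diagnostics(E, S)
              else NA_real_,
    n_pixels = length(E),
    r_squared = cal$r_squared,
    software = paste0("fretq ",
                      as.character(utils::packageVersion("fretq"))),
    seed = config$seed,
    input_digests = as.list(tools::md5sum(c(config$fret, config$donor_only,
                                            config$acceptor_only))))
  diag_path <- file.path(config$out_dir, "diagnostics.json")
  jsonlite::write_json(diagnostics, diag_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(list(calibration = cal, diagnostics = diagnostics,
                 per_cell = per_cell,
                 paths = c(paths, per_cell = pc_path,
                           diagnostics = diag_path)))
}
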