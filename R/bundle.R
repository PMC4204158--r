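#' Shape-library bundles on disk
#'
#' A library bundle is a directory holding one 32-bit float TIFF per
#' aligned training SDF plus `manifest.json` recording the format version,
#' grid size, kernel width, pairwise distances, file names and MD5
#' checksums.  Bundles are produced by `build-prior` and consumed by
#' `segment`.
#'
#' @name bundle
NULL

BUNDLE_FORMAT_VERSION <- 1L

#' Write a shape library to a bundle directory
#'
#' @param lib A [build_library()] object.
#' @param dir Output directory (created if missing).
#' @return The manifest (invisibly).
#' @export
write_shape_library <- function(lib, dir) {
  stopifnot(inherits(lib, "shape_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("shape_%03d.tif", seq_along(lib$phi))
  for (i in seq_along(lib$phi))
    write_raster_tiff(lib$phi[[i]], file.path(dir, files[i]))
  sums <- unname(tools::md5sum(file.path(dir, files)))
  manifest <- list(format_version = BUNDLE_FORMAT_VERSION,
                   grid = as.integer(lib$dim), n = length(lib$phi),
                   sigma2 = lib$sigma2, eps = lib$eps,
                   pairwise_d2 = lib$pairwise_d2,
                   files = files, md5 = sums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a shape library from a bundle directory
#'
#' Verifies the format version, file count, grid sizes and checksums.
#'
#' @param dir Bundle directory written by [write_shape_library()].
#' @return A `"shape_library"` object.
#' @export
read_shape_library <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop("not a library bundle (no manifest.json): ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (mf$format_version != BUNDLE_FORMAT_VERSION)
    stop("unsupported bundle format version: ", mf$format_version,
         call. = FALSE)
  if (length(mf$files) != mf$n)
    stop("bundle manifest lists ", mf$n, " shapes but ", length(mf$files),
         " files", call. = FALSE)
  paths <- file.path(dir, mf$files)
  sums <- unname(tools::md5sum(paths))
  bad <- which(sums != mf$md5)
  if (length(bad))
    stop("bundle checksum mismatch for: ",
         paste(mf$files[bad], collapse = ", "), call. = FALSE)
  phis <- lapply(paths, function(p) {
    m <- read_raster(p)
    if (!identical(dim(m), as.integer(mf$grid)))
      stop("bundle grid mismatch in ", p, call. = FALSE)
    m
  })
  d2 <- matrix(unlist(mf$pairwise_d2), mf$n, mf$n)
  structure(list(phi = phis, H = lapply(phis, heaviside_eps, eps = mf$eps),
                 sigma2 = mf$sigma2, pairwise_d2 = d2, eps = mf$eps,
                 dim = as.integer(mf$grid)),
            class = "shape_library")
}

#' Write segmentation artifacts to a directory
#'
#' Writes the final mask (PNG), phi (float TIFF), contour polylines and
#' iteration trace (CSV), the resolved configuration (YAML, including the
#' numeric value an `"auto"` nu resolved to), a run log, and a manifest
#' with MD5 checksums of every artifact.
#'
#' @param result A [evolve()] result.
#' @param dir Output directory (created if missing).
#' @param log_lines Optional character vector appended to the run log.
#' @return The manifest (invisibly).
#' @export
write_outputs <- function(result, dir, log_lines = character()) {
  stopifnot(inherits(result, "gpf_segmentation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask_png(result$mask, file.path(dir, "mask.png"))
  write_raster_tiff(result$phi, file.path(dir, "phi.tif"))
  cont <- if (length(result$contour))
    do.call(rbind, lapply(seq_along(result$contour), function(i)
      cbind(contour_id = i, result$contour[[i]][, c("y", "x")])))
  else data.frame(contour_id = integer(), y = numeric(), x = numeric())
  utils::write.csv(cont, file.path(dir, "contour.csv"), row.names = FALSE)
  utils::write.csv(result$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  write_config(result$config, file.path(dir, "config.yaml"),
               extra = list(nu = result$nu, iterations = result$iterations,
                            status = result$status))
  log <- c(sprintf("gpfseg %s", as.character(utils::packageVersion("gpfseg"))),
           sprintf("iterations: %d (%s)", result$iterations, result$status),
           sprintf("resolved nu: %.8g", result$nu),
           log_lines)
  writeLines(log, file.path(dir, "run.log"))
  files <- c("mask.png", "phi.tif", "contour.csv", "trace.csv",
             "config.yaml", "run.log")
  manifest <- list(files = files,
                   md5 = unname(tools::md5sum(file.path(dir, files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
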