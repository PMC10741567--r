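# File-format plumbing: 8-bit grayscale PNG/TIFF frames, CSV manifests and
# a JSON sidecar for the optical configuration.

#' Write a shadow frame to PNG or TIFF
#'
#' @param frame a [ShadowFrame-class] or integer matrix of counts.
#' @param path output path ending in .png or .tif/.tiff.
#' @param bit_depth bit depth used for scaling (taken from the frame's
#'   config when available).
#' @return the path, invisibly.
#' @export
writeFrame <- function(frame, path, bit_depth = NULL) {
  img <- asFrameMatrix(frame)
  if (is.null(bit_depth))
    bit_depth <- if (is(frame, "ShadowFrame")) frame@config@bit_depth else 8
  sc <- img / (2^bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(sc, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(sc, path,
                                                      bits.per.sample = 8L)
  else stop("unsupported frame format: .", ext)
  invisible(path)
}

#' Read a grayscale frame from PNG or TIFF
#'
#' @param path input path.
#' @param bit_depth bit depth for rescaling to counts (default 8).
#' @return an integer matrix of pixel counts.
#' @export
readFrame <- function(path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported frame format: .", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * (2^bit_depth - 1))), nrow(img), ncol(img))
}

#' Write a synthetic cohort to disk
#'
#' Frames as 8-bit grayscale PNG, ground truth as a CSV manifest and the
#' optical configuration as a JSON sidecar.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if missing).
#' @param config the [OpticalConfig-class] used for generation.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$frames))
  for (i in seq_along(cohort$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    writeFrame(cohort$frames[[i]], paths[i])
  }
  man <- cohort$manifest
  man$frame_path <- paths[man$frame_id]
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    wavelength_um = config@wavelength_um,
    pixel_pitch_um = config@pixel_pitch_um,
    distance_um = config@distance_um,
    frame_shape = config@frame_shape,
    bit_depth = config@bit_depth,
    background_level = config@background_level,
    noise_sigma = config@noise_sigma),
    file.path(dir, "optical_config.json"), auto_unbox = TRUE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read an optical configuration from a JSON sidecar
#'
#' @param path path to `optical_config.json`.
#' @return an [OpticalConfig-class].
#' @export
readOpticalConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  opticalConfig(wavelength_um = j$wavelength_um,
                pixel_pitch_um = j$pixel_pitch_um,
                distance_um = j$distance_um,
                frame_shape = j$frame_shape,
                bit_depth = j$bit_depth,
                background_level = j$background_level,
                noise_sigma = j$noise_sigma)
}
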