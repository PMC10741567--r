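# Synthetic lens-free shadow imaging: scalar angular-spectrum propagation of
# circular phase/amplitude objects under plane-wave illumination, composited
# onto a full sensor frame with Gaussian read noise and quantization.

#' Construct an optical configuration
#'
#' Defaults describe a blue-LED lens-free imager: 470 nm illumination on a
#' 2592 x 1944 px, 8-bit CMOS sensor. The pixel pitch (2.2 um) and the
#' chip-to-sensor distance (1 mm) are simulator choices that place the PPD
#' statistic of rendered cells on the 20-80 count scale observed for real
#' mononuclear cells; both are freely configurable.
#'
#' @param wavelength_um illumination wavelength, micrometres.
#' @param pixel_pitch_um sensor pixel pitch, micrometres.
#' @param distance_um object-to-sensor distance, micrometres.
#' @param frame_shape integer (rows, cols) of the sensor frame.
#' @param bit_depth sensor bit depth.
#' @param background_level background intensity, counts.
#' @param noise_sigma additive Gaussian read noise SD, counts.
#' @return an [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' cfg
#' @export
opticalConfig <- function(wavelength_um = 0.470, pixel_pitch_um = 2.2,
                          distance_um = 1000, frame_shape = c(1944L, 2592L),
                          bit_depth = 8L, background_level = 100,
                          noise_sigma = 2) {
  new("OpticalConfig", wavelength_um = wavelength_um,
      pixel_pitch_um = pixel_pitch_um, distance_um = distance_um,
      frame_shape = as.integer(frame_shape), bit_depth = as.integer(bit_depth),
      background_level = background_level, noise_sigma = noise_sigma)
}

#' Build a ground-truth cell table
#'
#' @param row,col cell centre positions, 1-based pixels.
#' @param radius_um cell radii, micrometres.
#' @param phase_rad optical phase shift imparted by each cell, radians.
#' @param amplitude amplitude transmittance in (0, 1].
#' @param class_label "CD34_POS" or "RESIDUAL".
#' @return a data.frame suitable for [renderFrame()].
#' @export
cellTable <- function(row, col, radius_um, phase_rad,
                      amplitude = 1, class_label = "CD34_POS") {
  n <- length(row)
  df <- data.frame(row = row, col = col, radius_um = radius_um,
                   phase_rad = phase_rad,
                   amplitude = rep(amplitude, length.out = n),
                   class_label = rep(class_label, length.out = n),
                   stringsAsFactors = FALSE)
  if (any(df$radius_um <= 0)) stop("cell radius must be > 0")
  if (any(df$amplitude <= 0 | df$amplitude > 1))
    stop("amplitude transmittance must lie in (0, 1]")
  if (!all(df$class_label %in% c("CD34_POS", "RESIDUAL")))
    stop("class_label must be CD34_POS or RESIDUAL")
  df
}

# radius (um) of the n-th dark Fresnel ring for the configured geometry;
# used for window sizing and the sampling guard
ringRadius <- function(config, n = 1) {
  sqrt(n * config@wavelength_um * config@distance_um)
}

# guard against undersampled fringes: the local fringe spacing at the second
# ring must span at least 2 sensor pixels
checkSampling <- function(config) {
  r2 <- ringRadius(config, 2)
  spacing <- config@wavelength_um * config@distance_um / (2 * r2)
  if (spacing < 2 * config@pixel_pitch_um)
    stop(sprintf(paste0(
      "sampling violation: fringe spacing %.2f um at the second ring is ",
      "below 2 pixels (pitch %.2f um); increase distance_um or decrease ",
      "pixel_pitch_um (wavelength %.3f um, distance %.0f um)"),
      spacing, config@pixel_pitch_um, config@wavelength_um,
      config@distance_um))
  invisible(spacing)
}

#' Render the diffraction pattern of a single cell
#'
#' Propagates a plane wave through a circular phase/amplitude object
#' (complex transmittance `amplitude * exp(1i * phase)` inside the disk,
#' unity outside) to the sensor plane with the scalar angular-spectrum
#' kernel, and returns the intensity patch scaled so the undisturbed
#' background equals `background_level`. The patch window always contains
#' the first two diffraction rings.
#'
#' @param config an [OpticalConfig-class].
#' @param radius_um cell radius, micrometres.
#' @param phase_rad phase shift, radians.
#' @param amplitude amplitude transmittance in (0, 1].
#' @param offset optional fractional (row, col) sub-pixel centre offset.
#' @param patch_size odd patch edge length in pixels; sized automatically to
#'   contain the first two rings when `NULL`.
#' @return a numeric `patch_size x patch_size` matrix of intensity counts
#'   (not quantized), centred on the cell.
#' @examples
#' cfg <- opticalConfig()
#' p <- renderCellPattern(cfg, radius_um = 5, phase_rad = 0.8)
#' dim(p)
#' @export
renderCellPattern <- function(config, radius_um, phase_rad, amplitude = 1,
                              offset = c(0, 0), patch_size = NULL) {
  stopifnot(is(config, "OpticalConfig"))
  if (radius_um <= 0) stop("cell radius must be > 0")
  if (amplitude <= 0 || amplitude > 1)
    stop("amplitude transmittance must lie in (0, 1]")
  checkSampling(config)
  pitch <- config@pixel_pitch_um
  if (is.null(patch_size)) {
    # half width: two rings plus the geometric shadow plus a small guard
    # band; compact support keeps composited components within the
    # detector's size rule
    half <- ceiling((ringRadius(config, 2) + radius_um) / pitch) + 2
    patch_size <- 2 * half + 1
  }
  if (patch_size %% 2 == 0) patch_size <- patch_size + 1
  half <- (patch_size - 1) / 2
  # FFT grid: padded to the next power of two to keep wrap-around far away
  N <- 2^ceiling(log2(max(2 * patch_size, 64)))
  ctr <- N %/% 2 + 1
  x <- (seq_len(N) - ctr) * pitch
  rr <- x - offset[1] * pitch
  cc <- x - offset[2] * pitch
  d2 <- outer(rr^2, cc^2, "+")
  t <- matrix(1 + 0i, N, N)
  t[d2 <= radius_um^2] <- amplitude * exp(1i * phase_rad)
  fx <- c(seq(0, N / 2 - 1), seq(-N / 2, -1)) / (N * pitch)
  f2 <- outer(fx^2, fx^2, "+")
  arg <- 1 - config@wavelength_um^2 * f2
  H <- matrix(0 + 0i, N, N)
  prop <- arg > 0
  H[prop] <- exp(2i * pi * config@distance_um / config@wavelength_um *
                   sqrt(arg[prop]))
  U <- fft(fft(t) * H, inverse = TRUE) / (N * N)
  I <- Mod(U)^2
  patch <- config@background_level *
    I[(ctr - half):(ctr + half), (ctr - half):(ctr + half)]
  # raised-cosine apodization to circular compact support: the pattern
  # decays to the background level at the window edge, so composited
  # frames contain a disk of signal rather than a square with ring arcs
  # truncated at the corners
  px <- seq_len(patch_size) - (half + 1)
  d <- sqrt(outer(px^2, px^2, "+"))
  w <- 0.5 * (1 + cos(pi * pmin(pmax((d - (half - 4)) / 3, 0), 1)))
  config@background_level + (patch - config@background_level) * w
}

#' Render a full synthetic shadow frame
#'
#' Composites per-cell diffraction patches additively onto a uniform
#' background, adds Gaussian read noise, clips and quantizes to the sensor
#' bit depth. Cell centres must stay pairwise separated by at least twice
#' the second-ring radius; overlapping placements are rejected.
#'
#' @param config an [OpticalConfig-class].
#' @param cells a data.frame from [cellTable()] (may have zero rows).
#' @param noise logical; add read noise (uses the current RNG state).
#' @return a [ShadowFrame-class].
#' @examples
#' cfg <- opticalConfig(frame_shape = c(256L, 256L))
#' fr <- renderFrame(cfg, cellTable(128, 128, 5, 0.8))
#' fr
#' @export
renderFrame <- function(config, cells = cellTable(numeric(0), numeric(0),
                                                  numeric(0), numeric(0)),
                        noise = TRUE) {
  stopifnot(is(config, "OpticalConfig"))
  nr <- config@frame_shape[1]; nc <- config@frame_shape[2]
  img <- matrix(config@background_level, nr, nc)
  if (nrow(cells) > 0) {
    bad <- which(cells$row < 1 | cells$row > nr | cells$col < 1 |
                   cells$col > nc)
    if (length(bad))
      stop("cell centre out of frame bounds at index: ",
           paste(bad, collapse = ", "))
    r2px <- ringRadius(config, 2) / config@pixel_pitch_um
    if (nrow(cells) > 1) {
      dmin <- min(dist(cbind(cells$row, cells$col)))
      if (dmin < 2 * r2px)
        stop(sprintf(paste0("cells closer than twice the second-ring radius ",
                            "(%.1f px): minimum separation %.1f px"),
                     2 * r2px, dmin))
    }
    for (i in seq_len(nrow(cells))) {
      ri <- cells$row[i]; ci <- cells$col[i]
      off <- c(ri - round(ri), ci - round(ci))
      patch <- renderCellPattern(config, cells$radius_um[i],
                                 cells$phase_rad[i], cells$amplitude[i],
                                 offset = off)
      half <- (nrow(patch) - 1) / 2
      pr <- round(ri); pc <- round(ci)
      rows <- (pr - half):(pr + half); cols <- (pc - half):(pc + half)
      keep_r <- rows >= 1 & rows <= nr; keep_c <- cols >= 1 & cols <= nc
      img[rows[keep_r], cols[keep_c]] <-
        img[rows[keep_r], cols[keep_c]] +
        (patch[keep_r, keep_c, drop = FALSE] - config@background_level)
    }
  }
  if (noise && config@noise_sigma > 0)
    img <- img + rnorm(length(img), 0, config@noise_sigma)
  maxv <- 2^config@bit_depth - 1
  img <- matrix(as.integer(pmax(0, pmin(maxv, round(img)))), nr, nc)
  new("ShadowFrame", image = img, cells = cells, config = config)
}

#' Default class-conditional cell parameter regimes
#'
#' Two parameter regimes that statistically separate the classes the way
#' CD34+ cells and residual mononuclear cells separate on the PPD statistic:
#' the CD34_POS regime (small, optically thin cells) concentrates its PPD in
#' the 40-60 count gate, while the RESIDUAL regime (larger, denser cells)
#' sits well above it.
#'
#' @return a named list with per-class normal distributions over radius (um)
#'   and phase shift (rad).
#' @export
defaultClassParams <- function() {
  list(
    CD34_POS = list(radius_mean = 5.0, radius_sd = 0.30,
                    phase_mean = 0.80, phase_sd = 0.10),
    RESIDUAL = list(radius_mean = 6.5, radius_sd = 0.50,
                    phase_mean = 1.40, phase_sd = 0.15)
  )
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-cell radii and phase shifts from the class-conditional regimes,
#' places cells on a jittered grid that respects the non-overlap constraint,
#' renders frames, and returns both the frames and a manifest carrying the
#' generating parameters and class labels. Reproducible under a fixed seed.
#'
#' @param config an [OpticalConfig-class].
#' @param class_params per-class parameter regimes as in
#'   [defaultClassParams()].
#' @param n_per_class cells to generate per class (default 10000, the size
#'   used to assemble the full training corpus).
#' @param seed integer seed.
#' @param noise logical; add read noise to the rendered frames.
#' @param cells_per_frame cells placed on each frame. The default, one cell
#'   per ~25000 px (about 200 on a full 2592 x 1944 frame), matches the
#'   sparse single-cell occupancy of a diluted sample, keeping shadow
#'   patterns isolated.
#' @return a list with `frames` (list of [ShadowFrame-class]) and `manifest`
#'   (data.frame: frame_id, cell_id, row, col, radius_um, phase_rad,
#'   class_label).
#' @examples
#' cfg <- opticalConfig(frame_shape = c(486L, 648L))
#' cohort <- generateCohort(cfg, n_per_class = 8, seed = 1)
#' table(cohort$manifest$class_label)
#' @export
generateCohort <- function(config, class_params = defaultClassParams(),
                           n_per_class = 10000, seed = 1, noise = TRUE,
                           cells_per_frame = NULL) {
  stopifnot(is(config, "OpticalConfig"), n_per_class >= 0)
  set.seed(seed)
  empty <- data.frame(frame_id = integer(0), cell_id = integer(0),
                      row = numeric(0), col = numeric(0),
                      radius_um = numeric(0), phase_rad = numeric(0),
                      class_label = character(0), stringsAsFactors = FALSE)
  if (n_per_class == 0) return(list(frames = list(), manifest = empty))
  # placement grid: never closer than twice the second-ring radius (plus
  # jitter head-room), and no denser than the requested occupancy — the
  # grid pitch widens so the cells spread over the whole frame
  r2px <- ringRadius(config, 2) / config@pixel_pitch_um
  min_step <- ceiling(2 * r2px + 10)
  margin <- ceiling(r2px + 20)
  if (is.null(cells_per_frame))
    cells_per_frame <- max(1, prod(config@frame_shape) %/% 25000)
  usable <- pmax(config@frame_shape - 2 * margin, 1)
  step <- max(min_step, floor(sqrt(prod(usable) / cells_per_frame)))
  rows_avail <- floor(usable[1] / step) + 1
  cols_avail <- floor(usable[2] / step) + 1
  per_frame <- rows_avail * cols_avail
  if (per_frame < 1) stop("frame too small for the non-overlap grid")
  per_frame <- min(per_frame, cells_per_frame)
  total <- 2 * n_per_class
  labels <- sample(rep(c("CD34_POS", "RESIDUAL"), each = n_per_class))
  draw <- function(lbl) {
    p <- class_params[[lbl]]
    c(max(2, rnorm(1, p$radius_mean, p$radius_sd)),
      max(0.05, rnorm(1, p$phase_mean, p$phase_sd)))
  }
  frames <- list(); manifest <- NULL
  i <- 1; fid <- 0
  while (i <= total) {
    fid <- fid + 1
    n_here <- min(per_frame, total - i + 1)
    slots <- head(sample(per_frame), n_here)
    gr <- (slots - 1) %/% cols_avail
    gc <- (slots - 1) %% cols_avail
    jit <- matrix(runif(2 * n_here, -3, 3), ncol = 2)
    rows <- margin + gr * step + jit[, 1]
    cols <- margin + gc * step + jit[, 2]
    lbl <- labels[i:(i + n_here - 1)]
    pars <- t(vapply(lbl, draw, numeric(2)))
    cells <- cellTable(rows, cols, pars[, 1], pars[, 2], 1, lbl)
    frames[[fid]] <- renderFrame(config, cells, noise = noise)
    manifest <- rbind(manifest, data.frame(
      frame_id = fid, cell_id = i:(i + n_here - 1),
      row = rows, col = cols, radius_um = pars[, 1], phase_rad = pars[, 2],
      class_label = lbl, stringsAsFactors = FALSE))
    i <- i + n_here
  }
  list(frames = frames, manifest = manifest)
}
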