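# Object recognition on full shadow frames: global-mean background removal,
# sigma thresholding with one pass of 3x3 morphological closing (the
# neighbour gap-filling rule), 8-connected component extraction with the
# 8-40 px size filter, and 30x30 cropping around the component centres.

#' Remove the frame background
#'
#' Subtracts the global mean pixel value of the frame, returning the signed
#' deviation image. The residual always sums to zero.
#'
#' @param frame a [ShadowFrame-class] or a numeric matrix.
#' @return a numeric matrix of signed deviations.
#' @export
removeBackground <- function(frame) {
  img <- asFrameMatrix(frame)
  if (length(img) == 0) stop("frame is empty")
  img - mean(img)
}

# accept either a ShadowFrame or a bare matrix everywhere downstream
asFrameMatrix <- function(frame) {
  if (is(frame, "ShadowFrame")) frame@image
  else if (is.matrix(frame)) frame
  else stop("expected a ShadowFrame or a matrix")
}

#' Binarize a background-removed frame
#'
#' Marks pixels whose absolute deviation exceeds `k_sigma` standard
#' deviations of the residual, then applies one pass of 3x3 binary closing
#' (dilation followed by erosion), which realises the rule of filling
#' single-pixel gaps between adjacent foreground pixels. A constant frame
#' (zero variance) yields an all-zero mask.
#'
#' @param residual numeric matrix from [removeBackground()].
#' @param k_sigma threshold multiplier (default 3).
#' @return an integer 0/1 matrix of the same shape.
#' @export
segmentShadows <- function(residual, k_sigma = 3) {
  stopifnot(is.matrix(residual))
  s <- sd(residual)
  if (!is.finite(s) || s == 0)
    return(matrix(0L, nrow(residual), ncol(residual)))
  mask <- abs(residual) > k_sigma * s
  closed <- EBImage::closing(mask * 1, EBImage::makeBrush(3, "box"))
  matrix(as.integer(closed > 0.5), nrow(residual), ncol(residual))
}

#' Extract candidate cell objects from a binary mask
#'
#' Labels 8-connected components, computes each component's bounding box and
#' centroid (rounded to the nearest pixel), and keeps components whose
#' bounding-box height AND width both lie in `size_range` (default 8 to 40
#' pixels). Results are ordered by (min_row, min_col).
#'
#' A shadow pattern is concentric — a bright centre surrounded by dark and
#' bright rings — so after thresholding one cell can fragment into several
#' nested components (the centre blob and ring annuli) whose centroids all
#' but coincide. With `merge_radius > 0`, components whose centroids lie
#' within that distance are agglomerated (single linkage) into one object
#' before the size filter is applied; [detectCells()] enables this.
#'
#' @param mask integer 0/1 matrix.
#' @param size_range closed interval of admissible bbox dimensions, pixels.
#' @param merge_radius centroid distance (pixels) below which components are
#'   merged; 0 (default) disables merging.
#' @return a data.frame with one row per detection: `row`, `col` (centre,
#'   1-based), `min_row`, `min_col`, `height`, `width`, `size` (pixel count).
#' @export
extractObjects <- function(mask, size_range = c(8, 40), merge_radius = 0) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  lab <- .label8(matrix(as.integer(mask), nrow(mask)))
  K <- max(lab)
  out <- data.frame(row = integer(0), col = integer(0), min_row = integer(0),
                    min_col = integer(0), height = integer(0),
                    width = integer(0), size = integer(0))
  if (K == 0) return(out)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  st <- data.frame(
    size = as.integer(tapply(l, l, length)),
    crow = as.numeric(tapply(idx[, 1], l, mean)),
    ccol = as.numeric(tapply(idx[, 2], l, mean)),
    sumr = as.numeric(tapply(idx[, 1], l, sum)),
    sumc = as.numeric(tapply(idx[, 2], l, sum)),
    min_row = as.integer(tapply(idx[, 1], l, min)),
    max_row = as.integer(tapply(idx[, 1], l, max)),
    min_col = as.integer(tapply(idx[, 2], l, min)),
    max_col = as.integer(tapply(idx[, 2], l, max)))
  if (merge_radius > 0 && nrow(st) > 1) {
    # single-linkage agglomeration of near-coincident centroids
    grp <- seq_len(nrow(st))
    find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
    d <- as.matrix(dist(st[, c("crow", "ccol")]))
    for (i in seq_len(nrow(st) - 1))
      for (j in (i + 1):nrow(st))
        if (d[i, j] <= merge_radius) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
        }
    roots <- vapply(seq_len(nrow(st)), find, integer(1))
    st <- do.call(rbind, lapply(split(st, roots), function(g)
      data.frame(size = sum(g$size),
                 crow = sum(g$sumr) / sum(g$size),
                 ccol = sum(g$sumc) / sum(g$size),
                 sumr = sum(g$sumr), sumc = sum(g$sumc),
                 min_row = min(g$min_row), max_row = max(g$max_row),
                 min_col = min(g$min_col), max_col = max(g$max_col))))
  }
  h <- st$max_row - st$min_row + 1L
  w <- st$max_col - st$min_col + 1L
  keep <- h >= size_range[1] & h <= size_range[2] &
          w >= size_range[1] & w <= size_range[2]
  st <- st[keep, , drop = FALSE]
  out <- data.frame(
    row = as.integer(floor(st$crow + 0.5)),
    col = as.integer(floor(st$ccol + 0.5)),
    min_row = st$min_row, min_col = st$min_col,
    height = h[keep], width = w[keep], size = st$size)
  out <- out[order(out$min_row, out$min_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop fixed-size cell windows from the original frame
#'
#' Takes a 30x30 window around each detection centre from the ORIGINAL
#' (pre-background-removal) frame. The centre pixel sits at position
#' (15, 15) of the crop. Detections whose window would cross the frame
#' boundary are dropped with a warning.
#'
#' @param frame a [ShadowFrame-class] or matrix (the original intensities).
#' @param detections data.frame from [extractObjects()].
#' @param size crop edge length (default 30).
#' @return a list with `crops` (list of `size x size` matrices) and `meta`
#'   (data.frame of the retained detections).
#' @export
cropCells <- function(frame, detections, size = 30) {
  img <- asFrameMatrix(frame)
  lo <- size %/% 2 - 1          # 14 for size 30: centre at offset 15
  hi <- size - lo - 1           # 15
  ok <- detections$row - lo >= 1 & detections$row + hi <= nrow(img) &
        detections$col - lo >= 1 & detections$col + hi <= ncol(img)
  if (any(!ok))
    warning(sum(!ok), " detection(s) dropped: crop window crosses the ",
            "frame boundary")
  kept <- detections[ok, , drop = FALSE]
  crops <- lapply(seq_len(nrow(kept)), function(i)
    img[(kept$row[i] - lo):(kept$row[i] + hi),
        (kept$col[i] - lo):(kept$col[i] + hi)])
  list(crops = crops, meta = kept)
}

#' Detect and crop all cells in a frame
#'
#' Convenience pipeline: background removal, thresholding + closing,
#' component extraction with the size filter, and 30x30 cropping.
#'
#' @inheritParams segmentShadows
#' @inheritParams cropCells
#' @param frame a [ShadowFrame-class] or matrix.
#' @param merge_radius centroid merge distance for concentric ring
#'   fragments of one pattern (see [extractObjects()]).
#' @return as [cropCells()].
#' @examples
#' cfg <- opticalConfig(frame_shape = c(256L, 256L))
#' fr <- renderFrame(cfg, cellTable(128, 128, 5, 0.8), noise = FALSE)
#' det <- detectCells(fr)
#' det$meta
#' @export
detectCells <- function(frame, k_sigma = 3, size = 30, merge_radius = 15) {
  res <- removeBackground(frame)
  mask <- segmentShadows(res, k_sigma)
  det <- extractObjects(mask, merge_radius = merge_radius)
  cropCells(frame, det, size)
}
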