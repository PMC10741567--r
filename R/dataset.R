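# Labelled dataset assembly: the PPD gate applied to the positive class,
# the 8:1:1 train/validation/test split, and model-input preprocessing.

#' Assemble a labelled dataset manifest from crops
#'
#' Builds one record per crop carrying its label, PPD and source. Because
#' the positive class of the real corpus originates from enriched samples of
#' only ~70% purity, CD34_POS records are restricted to crops passing the
#' PPD gate; RESIDUAL records are kept unrestricted.
#'
#' @param crop_ids character vector of unique crop identifiers/paths.
#' @param labels "CD34_POS" / "RESIDUAL", parallel to `crop_ids`.
#' @param params data.frame with `ppd` and `valid` columns, parallel rows.
#' @param gate numeric (lo, hi) PPD gate applied to the positive class.
#' @param source_id optional source annotation (recycled).
#' @return a data.frame manifest: `crop_id`, `label`, `split`
#'   ("unassigned"), `ppd`, `source_id`.
#' @examples
#' p <- data.frame(ppd = c(39, 45, 61), valid = TRUE)
#' buildManifest(c("a", "b", "c"), rep("CD34_POS", 3), p)
#' @export
buildManifest <- function(crop_ids, labels, params, gate = c(40, 60),
                          source_id = "sample") {
  stopifnot(length(crop_ids) == length(labels),
            length(crop_ids) == nrow(params))
  if (anyDuplicated(crop_ids)) stop("duplicate crop identifiers")
  if (!all(labels %in% c("CD34_POS", "RESIDUAL")))
    stop("labels must be CD34_POS or RESIDUAL")
  source_id <- rep(source_id, length.out = length(crop_ids))
  m <- data.frame(crop_id = as.character(crop_ids), label = labels,
                  split = rep("unassigned", length(crop_ids)),
                  ppd = params$ppd,
                  valid = params$valid,
                  source_id = source_id, stringsAsFactors = FALSE)
  keep <- m$label == "RESIDUAL" |
    (m$valid & m$ppd >= gate[1] & m$ppd <= gate[2])
  m <- m[keep, setdiff(names(m), "valid"), drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Assign train/validation/test splits
#'
#' Randomly partitions manifest records at the given ratios (default 8:1:1).
#' Sizes are floor allocations of the ratio fractions with the remainder
#' going to train; the partition is disjoint and exhaustive, reproducible
#' under the seed, and invariant to the input row order (records are sorted
#' by `crop_id` before the seeded shuffle). With `stratified = TRUE` the
#' allocation is performed within each label.
#'
#' @param manifest data.frame from [buildManifest()].
#' @param ratios positive numeric triple (train, val, test).
#' @param seed integer seed.
#' @param stratified allocate within label strata (default TRUE).
#' @return the manifest with the `split` column filled.
#' @export
assignSplits <- function(manifest, ratios = c(8, 1, 1), seed = 1,
                         stratified = TRUE) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  manifest <- manifest[order(manifest$crop_id), , drop = FALSE]
  set.seed(seed)
  assign_block <- function(n) {
    frac <- ratios / sum(ratios)
    n_val <- floor(n * frac[2]); n_test <- floor(n * frac[3])
    n_train <- n - n_val - n_test
    sample(rep(c("train", "val", "test"), c(n_train, n_val, n_test)))
  }
  if (stratified && nrow(manifest) > 0) {
    for (lbl in sort(unique(manifest$label))) {
      sel <- manifest$label == lbl
      manifest$split[sel] <- assign_block(sum(sel))
    }
  } else if (nrow(manifest) > 0) {
    manifest$split <- assign_block(nrow(manifest))
  }
  rownames(manifest) <- NULL
  manifest
}

#' Preprocess a crop into a model input
#'
#' Bilinear resize of the 30x30 crop to 50x50 and intensity scaling to
#' [0, 1] by division by the sensor maximum (2^bit_depth - 1). No per-image
#' standardisation is applied, preserving the absolute shadow contrast the
#' PPD statistic relies on.
#'
#' @param crop a 30x30 intensity matrix.
#' @param bit_depth sensor bit depth (default 8).
#' @param out_size output edge length (default 50).
#' @return a `out_size x out_size` numeric matrix in [0, 1].
#' @export
preprocessCrop <- function(crop, bit_depth = 8, out_size = 50) {
  if (!is.matrix(crop) || nrow(crop) != 30 || ncol(crop) != 30)
    stop("expected a 30x30 crop, got ",
         paste(dim(crop), collapse = "x"))
  scaled <- crop / (2^bit_depth - 1)
  res <- EBImage::resize(EBImage::Image(scaled), out_size, out_size)
  matrix(EBImage::imageData(res), out_size, out_size)
}

# stack a list of crops into the (50, 50, N) array the classifier consumes
stackInputs <- function(crops, bit_depth = 8, out_size = 50) {
  n <- length(crops)
  x <- array(0, dim = c(out_size, out_size, max(n, 1)))
  for (i in seq_len(n))
    x[, , i] <- preprocessCrop(crops[[i]], bit_depth, out_size)
  if (n == 0) x <- x[, , 0, drop = FALSE]
  x
}
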