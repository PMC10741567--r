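#' Optical configuration of the lens-free imaging geometry
#'
#' Describes the device geometry and sensor model used both to render
#' synthetic shadow frames and to interpret real ones: illumination
#' wavelength, sensor pixel pitch, object-to-sensor propagation distance,
#' frame dimensions, bit depth, background illumination level and additive
#' read-noise level.
#'
#' @slot wavelength_um illumination wavelength in micrometres (default
#'   0.470, a blue LED).
#' @slot pixel_pitch_um sensor pixel pitch in micrometres.
#' @slot distance_um object-to-sensor propagation distance in micrometres.
#' @slot frame_shape integer vector (rows, cols) of the full sensor frame.
#' @slot bit_depth integer sensor bit depth.
#' @slot background_level background intensity in sensor counts.
#' @slot noise_sigma additive Gaussian read-noise standard deviation, counts.
#'
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  representation(
    wavelength_um = "numeric",
    pixel_pitch_um = "numeric",
    distance_um = "numeric",
    frame_shape = "integer",
    bit_depth = "integer",
    background_level = "numeric",
    noise_sigma = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (object@wavelength_um <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@pixel_pitch_um <= 0) msg <- c(msg, "pixel pitch must be > 0")
  if (object@distance_um <= 0) msg <- c(msg, "propagation distance must be > 0")
  if (length(object@frame_shape) != 2 || any(object@frame_shape < 64))
    msg <- c(msg, "frame dimensions must be a pair, each >= 64")
  if (object@bit_depth < 1) msg <- c(msg, "bit depth must be >= 1")
  if (object@background_level < 0 ||
      object@background_level >= 2^object@bit_depth)
    msg <- c(msg, "background level must lie in [0, 2^bit_depth)")
  if (object@noise_sigma < 0) msg <- c(msg, "noise sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A synthetic full-sensor shadow frame with ground truth
#'
#' Holds the rendered 8-bit (or other bit depth) intensity image together
#' with the ground-truth table of rendered cells and the optical
#' configuration that produced it.
#'
#' @slot image integer matrix of pixel counts, dimensions `frame_shape`.
#' @slot cells data.frame of ground truth, one row per rendered cell:
#'   `row`, `col` (centre, 1-based pixels), `radius_um`, `phase_rad`,
#'   `amplitude`, `class_label`.
#' @slot config the [OpticalConfig-class] used for rendering.
#'
#' @exportClass ShadowFrame
setClass("ShadowFrame",
  representation(image = "matrix", cells = "data.frame",
                 config = "OpticalConfig")
)

setValidity("ShadowFrame", function(object) {
  msg <- character()
  maxv <- 2^object@config@bit_depth - 1
  if (any(object@image < 0) || any(object@image > maxv))
    msg <- c(msg, sprintf("pixel values must lie in [0, %d]", maxv))
  if (!all(dim(object@image) == object@config@frame_shape))
    msg <- c(msg, "image dimensions do not match config frame_shape")
  need <- c("row", "col", "radius_um", "phase_rad", "amplitude", "class_label")
  if (nrow(object@cells) > 0 && !all(need %in% names(object@cells)))
    msg <- c(msg, "ground-truth table is missing required columns")
  if (length(msg)) msg else TRUE
})

#' Architecture of the SELU convolutional classifier
#'
#' An AlexNet-style stack: eight 3x3 / stride-1 / pad-1 convolutions with
#' 2x2 max pooling after convolutions 1, 2, 4, 6 and 8, followed by three
#' fully connected layers ending in two class scores. All hidden layers use
#' the scaled exponential linear unit (SELU) activation.
#'
#' @slot conv_channels integer vector of output channels for the eight
#'   convolutional layers.
#' @slot pool_after integer vector of the (1-based) convolution indices that
#'   are followed by max pooling.
#' @slot fc_widths integer vector of the three fully connected widths; the
#'   last entry is the number of classes.
#' @slot input_size integer spatial size of the (square) model input.
#' @slot selu_lambda,selu_alpha the SELU scale parameters.
#'
#' @exportClass ArchitectureSpec
setClass("ArchitectureSpec",
  representation(
    conv_channels = "integer", pool_after = "integer",
    fc_widths = "integer", input_size = "integer",
    selu_lambda = "numeric", selu_alpha = "numeric"
  )
)

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (length(object@conv_channels) != 8)
    msg <- c(msg, "exactly 8 convolutional layers are required")
  if (length(object@pool_after) != 5)
    msg <- c(msg, "exactly 5 pooling positions are required")
  if (any(object@pool_after < 1 | object@pool_after > 8))
    msg <- c(msg, "pooling positions must reference conv layers 1..8")
  if (length(object@fc_widths) != 3)
    msg <- c(msg, "exactly 3 fully connected layers are required")
  if (length(object@fc_widths) == 3 && object@fc_widths[3] != 2)
    msg <- c(msg, "the final fully connected width must equal 2 classes")
  if (object@input_size < 4) msg <- c(msg, "input size too small")
  s <- object@input_size
  for (i in seq_len(8)) if (i %in% object@pool_after) s <- s %/% 2
  if (s < 1) msg <- c(msg, "pooling collapses the input below 1 pixel")
  if (length(msg)) msg else TRUE
})

#' Training configuration for the classifier
#'
#' @slot batch_size minibatch size (default 16).
#' @slot learning_rate Adam learning rate (default 0.0005).
#' @slot epochs number of training epochs (default 500).
#' @slot optimizer optimizer name (only "adam" is implemented).
#' @slot loss loss name (only "cross_entropy" is implemented).
#' @slot seed integer seed controlling shuffling.
#'
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batch_size = "integer", learning_rate = "numeric",
                 epochs = "integer", optimizer = "character",
                 loss = "character", seed = "integer")
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batch_size < 1) msg <- c(msg, "batch_size must be >= 1")
  if (object@learning_rate <= 0) msg <- c(msg, "learning_rate must be > 0")
  if (object@epochs < 0) msg <- c(msg, "epochs must be >= 0")
  if (!identical(object@optimizer, "adam"))
    msg <- c(msg, "only the adam optimizer is implemented")
  if (!identical(object@loss, "cross_entropy"))
    msg <- c(msg, "only the cross_entropy loss is implemented")
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) SELU convolutional classifier
#'
#' @slot spec the [ArchitectureSpec-class].
#' @slot weights list of layer weights (`conv` and `fc` sublists, each layer
#'   a list with elements `W` and `b`).
#' @slot history data.frame with one row per trained epoch: `epoch`,
#'   `train_acc`, `val_acc`, `train_loss`, `val_loss`.
#' @slot best_epoch epoch whose validation accuracy selected the stored
#'   weights (0 for an untrained model).
#' @slot classes character vector of class labels; the first is the positive
#'   class.
#'
#' @exportClass ShadowNet
setClass("ShadowNet",
  representation(spec = "ArchitectureSpec", weights = "list",
                 history = "data.frame", best_epoch = "integer",
                 classes = "character")
)

#' Method-agreement report for paired percentage measurements
#'
#' Bland-Altman agreement of a measured CD34+ percentage against a reference
#' method, plus the coefficient of determination of the paired values.
#'
#' @slot n_pairs number of sample pairs.
#' @slot r_squared coefficient of determination of measured vs reference
#'   (NA when the reference has zero variance).
#' @slot mean_abs_diff mean absolute difference, percentage points.
#' @slot bias mean of (measured - reference), percentage points.
#' @slot loa_lower,loa_upper 95% limits of agreement, bias +/- 1.96 SD.
#' @slot differences the per-pair differences (measured - reference).
#'
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(n_pairs = "integer", r_squared = "numeric",
                 mean_abs_diff = "numeric", bias = "numeric",
                 loa_lower = "numeric", loa_upper = "numeric",
                 differences = "numeric")
)

setValidity("AgreementReport", function(object) {
  if (!is.na(object@loa_lower) &&
      !(object@loa_lower <= object@bias && object@bias <= object@loa_upper))
    "limits of agreement must bracket the bias" else TRUE
})

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  wavelength: %.3f um   pixel pitch: %.2f um   distance: %.0f um\n",
              object@wavelength_um, object@pixel_pitch_um, object@distance_um))
  cat(sprintf("  frame: %d x %d px   bit depth: %d   background: %.1f   noise sd: %.2f\n",
              object@frame_shape[1], object@frame_shape[2], object@bit_depth,
              object@background_level, object@noise_sigma))
})

setMethod("show", "ShadowFrame", function(object) {
  cat(sprintf("ShadowFrame: %d x %d px, %d ground-truth cell(s)\n",
              nrow(object@image), ncol(object@image), nrow(object@cells)))
  if (nrow(object@cells) > 0)
    print(head(object@cells, 5))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat("ArchitectureSpec: 8 conv (3x3) + 5 maxpool + 3 fully connected\n")
  cat("  channels:", paste(object@conv_channels, collapse = ", "), "\n")
  cat("  pool after conv:", paste(object@pool_after, collapse = ", "), "\n")
  cat("  fc widths:", paste(object@fc_widths, collapse = ", "),
      "  input:", object@input_size, "x", object@input_size, "\n")
  cat(sprintf("  SELU lambda = %.4f, alpha = %.4f\n",
              object@selu_lambda, object@selu_alpha))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: batch %d, lr %g, %d epochs, %s + %s, seed %d\n",
              object@batch_size, object@learning_rate, object@epochs,
              object@optimizer, object@loss, object@seed))
})

setMethod("show", "ShadowNet", function(object) {
  trained <- nrow(object@history) > 0
  cat(sprintf("ShadowNet (%s)\n", if (trained) "trained" else "untrained"))
  show(object@spec)
  if (trained) {
    h <- object@history
    cat(sprintf("  %d epoch(s); best epoch %d (val acc %.3f)\n",
                nrow(h), object@best_epoch,
                h$val_acc[object@best_epoch]))
  }
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport on %d pairs\n", object@n_pairs))
  cat(sprintf("  R^2 = %s, mean |diff| = %.2f\n",
              format(object@r_squared, digits = 3), object@mean_abs_diff))
  cat(sprintf("  bias = %.2f, 95%% limits of agreement [%.2f, %.2f]\n",
              object@bias, object@loa_lower, object@loa_upper))
})
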