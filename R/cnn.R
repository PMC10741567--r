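# The SELU convolutional classifier: AlexNet-style 8-conv / 5-pool / 3-FC
# binary network trained with Adam on softmax cross-entropy, plus Grad-CAM.
# The numerical core lives in compiled code; this file owns construction,
# initialisation, the R-facing training/evaluation API and Grad-CAM
# post-processing.

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x >= 0` and
#' `lambda * alpha * (exp(x) - 1)` for `x < 0`, with the standard
#' self-normalising constants `lambda = 1.0507`, `alpha = 1.6732`.
#'
#' @param x numeric vector.
#' @param lambda,alpha the SELU constants.
#' @return numeric vector of the same length.
#' @examples
#' selu(1)    # 1.0507
#' selu(0)    # 0
#' @export
selu <- function(x, lambda = 1.0507, alpha = 1.6732) {
  ifelse(x >= 0, lambda * x, lambda * alpha * (exp(x) - 1))
}

#' Construct the classifier architecture
#'
#' @param conv_channels output channels of the eight 3x3 convolutions.
#' @param pool_after conv indices followed by 2x2 max pooling.
#' @param fc_widths widths of the three fully connected layers (last = 2).
#' @param input_size square input size (default 50).
#' @param selu_lambda,selu_alpha SELU constants.
#' @return an [ArchitectureSpec-class].
#' @examples
#' architectureSpec()
#' @export
architectureSpec <- function(conv_channels = c(32L, 32L, 64L, 64L, 128L,
                                               128L, 256L, 256L),
                             pool_after = c(1L, 2L, 4L, 6L, 8L),
                             fc_widths = c(512L, 128L, 2L),
                             input_size = 50L,
                             selu_lambda = 1.0507, selu_alpha = 1.6732) {
  new("ArchitectureSpec", conv_channels = as.integer(conv_channels),
      pool_after = as.integer(pool_after), fc_widths = as.integer(fc_widths),
      input_size = as.integer(input_size), selu_lambda = selu_lambda,
      selu_alpha = selu_alpha)
}

#' Construct a training configuration
#'
#' Defaults are the reference training recipe: batch size 16, learning rate
#' 0.0005, 500 epochs, Adam on softmax cross-entropy.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param seed shuffle seed.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(batch_size = 16L, learning_rate = 0.0005,
                        epochs = 500L, seed = 1L) {
  new("TrainConfig", batch_size = as.integer(batch_size),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      optimizer = "adam", loss = "cross_entropy", seed = as.integer(seed))
}

# spatial sizes entering each conv layer plus the final pooled size
spatialTrace <- function(spec) {
  s <- spec@input_size
  tr <- integer(0)
  for (i in seq_along(spec@conv_channels)) {
    tr <- c(tr, s)
    if (i %in% spec@pool_after) s <- s %/% 2L
  }
  c(tr, s)
}

# compiled-core view of the architecture
specAsList <- function(spec) {
  list(conv_channels = spec@conv_channels,
       pool_after = seq_along(spec@conv_channels) %in% spec@pool_after,
       fc_widths = spec@fc_widths,
       input_size = spec@input_size)
}

#' Build an untrained classifier
#'
#' Initialises all weights with LeCun-normal draws (SD `1/sqrt(fan_in)`),
#' the initialisation under which SELU networks self-normalise; biases start
#' at zero. Reproducible under the seed.
#'
#' @param spec an [ArchitectureSpec-class].
#' @param seed integer seed for the weight draws.
#' @return an untrained [ShadowNet-class].
#' @examples
#' net <- buildModel(architectureSpec(), seed = 1)
#' net
#' @export
buildModel <- function(spec = architectureSpec(), seed = 1) {
  validObject(spec)
  set.seed(seed)
  tr <- spatialTrace(spec)
  n_conv <- length(spec@conv_channels)
  conv <- vector("list", n_conv)
  cin <- 1L
  for (l in seq_len(n_conv)) {
    cout <- spec@conv_channels[l]
    fan_in <- cin * 9
    conv[[l]] <- list(
      W = matrix(rnorm(cout * fan_in, 0, 1 / sqrt(fan_in)), cout, fan_in),
      b = numeric(cout))
    cin <- cout
  }
  fc <- vector("list", 3)
  fin <- spec@conv_channels[n_conv] * tr[n_conv + 1]^2
  for (l in seq_len(3)) {
    fout <- spec@fc_widths[l]
    fc[[l]] <- list(
      W = matrix(rnorm(fout * fin, 0, 1 / sqrt(fin)), fout, fin),
      b = numeric(fout))
    fin <- fout
  }
  new("ShadowNet", spec = spec, weights = list(conv = conv, fc = fc),
      history = data.frame(), best_epoch = 0L,
      classes = c("CD34_POS", "RESIDUAL"))
}

# map labels to 0/1 class indices (positive class first)
labelsToIndex <- function(labels, classes) {
  idx <- match(labels, classes) - 1L
  if (anyNA(idx)) stop("labels outside the model's class set")
  idx
}

#' Train the classifier
#'
#' Minimises softmax cross-entropy with Adam, shuffling each epoch under the
#' configured seed, recording per-epoch training/validation accuracy and
#' loss, and keeping the weights of the epoch with the highest validation
#' accuracy (ties resolved to the earlier epoch).
#'
#' @param model an untrained or trained [ShadowNet-class].
#' @param x_train,x_val arrays (50, 50, N) of preprocessed inputs.
#' @param y_train,y_val label vectors ("CD34_POS"/"RESIDUAL").
#' @param config a [TrainConfig-class].
#' @param verbose print per-epoch progress.
#' @return the trained [ShadowNet-class].
#' @export
trainModel <- function(model, x_train, y_train, x_val, y_val,
                       config = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "ShadowNet"), is(config, "TrainConfig"))
  validObject(config)
  if (length(y_train) == 0) stop("empty training set")
  if (dim(x_train)[3] != length(y_train))
    stop("x_train / y_train size mismatch")
  if (config@epochs == 0L) return(model)
  ytr <- labelsToIndex(y_train, model@classes)
  yva <- labelsToIndex(y_val, model@classes)
  fit <- .cnn_train(specAsList(model@spec), model@weights,
                    x_train, ytr, x_val, yva,
                    config@epochs, config@batch_size, config@learning_rate,
                    config@seed, verbose)
  model@weights <- fit$weights
  model@history <- data.frame(
    epoch = seq_len(config@epochs),
    train_acc = as.numeric(fit$train_acc),
    val_acc = as.numeric(fit$val_acc),
    train_loss = as.numeric(fit$train_loss),
    val_loss = as.numeric(fit$val_loss))
  model@best_epoch <- as.integer(fit$best_epoch)
  model
}

#' Predict class labels and scores
#'
#' @param model a [ShadowNet-class].
#' @param x array (50, 50, N) of preprocessed inputs.
#' @return a data.frame with per-item class scores (logits) and the argmax
#'   `label`.
#' @export
predictModel <- function(model, x) {
  stopifnot(is(model, "ShadowNet"))
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  logits <- .cnn_forward(specAsList(model@spec), model@weights, x)
  lab <- model@classes[max.col(logits, ties.method = "first")]
  data.frame(score_pos = logits[, 1], score_neg = logits[, 2],
             label = lab, stringsAsFactors = FALSE)
}

#' Evaluate the classifier on a labelled set
#'
#' Argmax prediction per item; returns the 2x2 confusion matrix (CD34_POS
#' as the positive class) and derived accuracy, precision and recall.
#'
#' @param model a [ShadowNet-class].
#' @param x array (50, 50, N).
#' @param y true labels.
#' @return a list: `confusion` (2x2 matrix with TP/FP/FN/TN layout),
#'   `accuracy`, `precision`, `recall`, `n`.
#' @export
evaluateModel <- function(model, x, y) {
  if (length(y) == 0) stop("empty evaluation set")
  pred <- predictModel(model, x)$label
  pos <- model@classes[1]
  tp <- sum(pred == pos & y == pos)
  fp <- sum(pred == pos & y != pos)
  fn <- sum(pred != pos & y == pos)
  tn <- sum(pred != pos & y != pos)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(truth = c(pos, "RESIDUAL"),
                                 predicted = c(pos, "RESIDUAL")))
  list(confusion = conf,
       accuracy = (tp + tn) / length(y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       n = length(y))
}

#' Grad-CAM heatmap for one input
#'
#' Gradient-weighted class activation map of the last convolutional layer:
#' channel weights are the spatially averaged gradients of the target class
#' score, the weighted activation sum is rectified, bilinearly upsampled to
#' the input size and min-max normalised to [0, 1]. A degenerate (all-zero)
#' map is returned as uniform zeros with a warning.
#'
#' @param model a trained [ShadowNet-class].
#' @param x one preprocessed input (50x50 matrix).
#' @param target_class class of interest (default the positive class).
#' @return a 50x50 matrix in [0, 1].
#' @export
gradCAM <- function(model, x, target_class = "CD34_POS") {
  stopifnot(is(model, "ShadowNet"), is.matrix(x))
  ti <- labelsToIndex(target_class, model@classes)
  cam <- .cnn_gradcam(specAsList(model@spec), model@weights, x, ti)
  up <- EBImage::resize(EBImage::Image(cam), nrow(x), ncol(x))
  up <- matrix(EBImage::imageData(up), nrow(x), ncol(x))
  up[up < 0] <- 0
  rng <- range(up)
  if (rng[2] - rng[1] <= 0) {
    warning("degenerate Grad-CAM: all-zero gradients, returning zeros")
    return(matrix(0, nrow(x), ncol(x)))
  }
  (up - rng[1]) / (rng[2] - rng[1])
}
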