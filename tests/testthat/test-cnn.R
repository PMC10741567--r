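test_that("selu matches its closed form and stated constants", {
  expect_equal(selu(0), 0)
  expect_equal(selu(1), 1.0507)
  expect_equal(selu(-10), 1.0507 * 1.6732 * (exp(-10) - 1), tolerance = 1e-3)
  expect_equal(selu(2.5), 1.0507 * 2.5)
  # continuity at the origin and monotonicity
  eps <- 1e-8
  expect_lt(abs(selu(eps) - selu(-eps)), 1e-7)
  x <- seq(-6, 6, length.out = 400)
  expect_true(all(diff(selu(x)) > 0))
  # slope ratio approaches lambda for large positive inputs
  expect_equal(selu(100) / 100, 1.0507)
})

test_that("architecture invariants are enforced", {
  expect_error(architectureSpec(conv_channels = rep(8L, 7)), "8 conv")
  expect_error(architectureSpec(pool_after = c(1L, 2L, 4L, 6L)), "5 pool")
  expect_error(architectureSpec(fc_widths = c(512L, 128L, 3L)), "2 classes")
  sp <- architectureSpec()
  expect_length(sp@conv_channels, 8)
  expect_length(sp@pool_after, 5)
  expect_length(sp@fc_widths, 3)
})

test_that("pooling trace follows floor division from 50 down to 1", {
  sp <- architectureSpec()
  tr <- shadowcyte:::spatialTrace(sp)
  # sizes entering each conv layer, then the final pooled size
  expect_equal(tr, c(50, 25, 12, 12, 6, 6, 3, 3, 1))
  oracle <- 50
  sizes <- c()
  for (i in 1:8) {
    if (i %in% c(1, 2, 4, 6, 8)) oracle <- floor(oracle / 2)
    sizes <- c(sizes, oracle)
  }
  expect_equal(sizes, c(25, 12, 12, 6, 6, 3, 3, 1))
})

test_that("an untrained model maps inputs to two class scores", {
  net <- buildModel(architectureSpec(), seed = 2)
  expect_length(net@weights$conv, 8)
  expect_length(net@weights$fc, 3)
  x <- array(runif(2500), dim = c(50, 50, 1))
  pr <- predictModel(net, x)
  expect_equal(nrow(pr), 1)
  expect_true(all(c("score_pos", "score_neg", "label") %in% names(pr)))
  # deterministic forward pass, reproducible initialisation
  pr2 <- predictModel(net, x)
  expect_identical(pr, pr2)
  net2 <- buildModel(architectureSpec(), seed = 2)
  expect_equal(net@weights, net2@weights)
})

test_that("zero epochs leave the model untouched", {
  sp <- architectureSpec(conv_channels = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
                         fc_widths = c(4L, 4L, 2L))
  net <- buildModel(sp, seed = 1)
  x <- array(runif(5000), dim = c(50, 50, 2))
  out <- trainModel(net, x, c("CD34_POS", "RESIDUAL"), x,
                    c("CD34_POS", "RESIDUAL"),
                    trainConfig(epochs = 0L))
  expect_identical(out@weights, net@weights)
  expect_equal(nrow(out@history), 0)
  expect_error(trainModel(net, x[, , 0, drop = FALSE], character(0), x,
                          c("CD34_POS", "RESIDUAL"), trainConfig()),
               "empty")
})

test_that("training defaults echo the reference recipe", {
  tc <- trainConfig()
  expect_equal(tc@batch_size, 16L)
  expect_equal(tc@learning_rate, 0.0005)
  expect_equal(tc@epochs, 500L)
})

test_that("analytic gradients agree with finite differences", {
  sp <- architectureSpec(conv_channels = c(2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L),
                         fc_widths = c(8L, 6L, 2L))
  net <- buildModel(sp, seed = 3)
  set.seed(4)
  x <- array(runif(50 * 50 * 4), dim = c(50, 50, 4))
  y <- c(0L, 1L, 1L, 0L)
  spl <- shadowcyte:::specAsList(sp)
  g <- shadowcyte:::.cnn_grad(spl, net@weights, x, y)
  eps <- 1e-3
  for (ck in list(c("conv", 1), c("conv", 5), c("conv", 8),
                  c("fc", 1), c("fc", 3))) {
    part <- ck[1]; l <- as.integer(ck[2])
    W <- net@weights[[part]][[l]]$W
    set.seed(l)
    ij <- cbind(sample(nrow(W), 3, replace = TRUE),
                sample(ncol(W), 3, replace = TRUE))
    for (k in 1:3) {
      wp <- net@weights; wm <- net@weights
      wp[[part]][[l]]$W[ij[k, 1], ij[k, 2]] <- W[ij[k, 1], ij[k, 2]] + eps
      wm[[part]][[l]]$W[ij[k, 1], ij[k, 2]] <- W[ij[k, 1], ij[k, 2]] - eps
      fd <- (shadowcyte:::.cnn_loss(spl, wp, x, y) -
               shadowcyte:::.cnn_loss(spl, wm, x, y)) / (2 * eps)
      an <- g[[part]][[l]]$W[ij[k, 1], ij[k, 2]]
      # float32 forward passes bound the attainable agreement
      expect_lt(abs(fd - an), max(6e-4, 0.1 * abs(fd)))
    }
  }
})

test_that("evaluation counts match an independent tally", {
  tn <- trainedNet()
  ite <- tn$ite
  ev <- evaluateModel(tn$net, tn$x[, , ite, drop = FALSE], tn$labels[ite])
  expect_equal(sum(ev$confusion), length(ite))
  # independent tally from raw predictions
  pred <- predictModel(tn$net, tn$x[, , ite, drop = FALSE])$label
  truth <- tn$labels[ite]
  expect_equal(ev$confusion["CD34_POS", "CD34_POS"],
               sum(pred == "CD34_POS" & truth == "CD34_POS"),
               ignore_attr = TRUE)
  expect_equal(ev$accuracy, mean(pred == truth))
  tp <- sum(pred == "CD34_POS" & truth == "CD34_POS")
  fp <- sum(pred == "CD34_POS" & truth == "RESIDUAL")
  fn <- sum(pred == "RESIDUAL" & truth == "CD34_POS")
  expect_equal(ev$precision, tp / (tp + fp))
  expect_equal(ev$recall, tp / (tp + fn))
  # an all-correct prediction set gives unit metrics
  perfect <- evaluateModel(tn$net, tn$x[, , ite, drop = FALSE], pred)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$confusion["CD34_POS", "RESIDUAL"], 0,
               ignore_attr = TRUE)
})

test_that("the classifier does not underperform the PPD-gate baseline", {
  tn <- trainedNet()
  ite <- tn$ite
  ev <- evaluateModel(tn$net, tn$x[, , ite, drop = FALSE], tn$labels[ite])
  base <- mean(ppdBaseline(tn$crops[ite]) == tn$labels[ite])
  expect_gte(ev$accuracy, base - 0.02)
})

test_that("Grad-CAM highlights the centre-to-first-ring annulus", {
  tn <- trainedNet()
  pos <- which(tn$labels == "CD34_POS")
  hits <- 0
  for (i in pos[1:5]) {
    crop <- tn$crops[[i]]
    pp <- computeShadowParams(crop)
    cam <- gradCAM(tn$net, tn$x[, , i])
    expect_identical(dim(cam), c(50L, 50L))
    expect_equal(min(cam), 0)
    expect_equal(max(cam), 1)
    rin <- (pp$mmd + 2) * 50 / 30   # ring radius on the resized grid
    ctr <- 25.5
    dd <- sqrt(outer((1:50 - ctr)^2, (1:50 - ctr)^2, "+"))
    if (mean(cam[dd <= rin]) > mean(cam[dd > rin])) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
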