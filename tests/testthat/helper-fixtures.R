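# Shared fixtures, generated in code and memoised for the test run.
# Fixed seeds define the study conditions; the cache only avoids paying the
# generation/training cost more than once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, fn(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a quarter-scale sensor keeps rendering cheap while preserving density
testConfig <- function(noise_sigma = 2) {
  opticalConfig(frame_shape = c(486L, 648L), noise_sigma = noise_sigma)
}

# match detections back to planted ground truth by nearest neighbour
matchDetections <- function(cohort, tol = 2, k_sigma = 3) {
  crops <- list(); labs <- character(0); err <- numeric(0); fp <- 0
  for (f in seq_along(cohort$frames)) {
    d <- suppressWarnings(detectCells(cohort$frames[[f]], k_sigma = k_sigma))
    tr <- cohort$manifest[cohort$manifest$frame_id == f, ]
    for (i in seq_len(nrow(d$meta))) {
      dd <- sqrt((tr$row - d$meta$row[i])^2 + (tr$col - d$meta$col[i])^2)
      j <- which.min(dd)
      if (length(dd) && dd[j] <= tol) {
        crops <- c(crops, list(d$crops[[i]]))
        labs <- c(labs, tr$class_label[j])
        err <- c(err, dd[j])
      } else {
        fp <- fp + 1
      }
    }
  }
  list(crops = crops, labels = labs, errors = err, false_pos = fp,
       n_truth = nrow(cohort$manifest))
}

# moderate labelled cohort reused across module tests
smallCohort <- function() memo("small_cohort", function() {
  co <- generateCohort(testConfig(), n_per_class = 150, seed = 101)
  m <- matchDetections(co)
  m$params <- do.call(rbind, lapply(m$crops, computeShadowParams))
  m
})

# a compact separable training problem and a briefly trained network;
# enough epochs for the classifier to dominate the PPD baseline
trainedNet <- function() memo("trained_net", function() {
  m <- smallCohort()
  x <- shadowcyte:::stackInputs(m$crops)
  n <- length(m$labels)
  set.seed(55)
  idx <- sample(n)
  ntr <- floor(0.8 * n); nva <- floor(0.1 * n)
  itr <- idx[seq_len(ntr)]
  iva <- idx[(ntr + 1):(ntr + nva)]
  ite <- idx[(ntr + nva + 1):n]
  net <- buildModel(architectureSpec(), seed = 7)
  net <- trainModel(net, x[, , itr, drop = FALSE], m$labels[itr],
                    x[, , iva, drop = FALSE], m$labels[iva],
                    trainConfig(epochs = 10L, seed = 7L))
  list(net = net, x = x, labels = m$labels, crops = m$crops,
       itr = itr, iva = iva, ite = ite)
})
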