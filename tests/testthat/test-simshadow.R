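test_that("an object with no optical contrast renders a flat background", {
  cfg <- opticalConfig()
  p <- renderCellPattern(cfg, radius_um = 5, phase_rad = 0, amplitude = 1)
  expect_equal(max(abs(p - cfg@background_level)), 0, tolerance = 1e-8)
})

test_that("a centred cell pattern is invariant under 90-degree rotation", {
  cfg <- opticalConfig()
  p <- renderCellPattern(cfg, radius_um = 5, phase_rad = 0.8)
  rot <- t(p[nrow(p):1, ])
  expect_equal(p, rot, tolerance = 1e-6)
})

test_that("undersampled fringe geometry is rejected with a clear error", {
  cfg <- opticalConfig(distance_um = 150)
  expect_error(renderCellPattern(cfg, 5, 0.8), "sampling violation")
  expect_error(renderCellPattern(cfg, 5, 0.8), "distance_um")
})

test_that("an empty frame is pure background plus read noise", {
  cfg <- opticalConfig(frame_shape = c(128L, 128L))
  set.seed(1)
  fr <- renderFrame(cfg)
  expect_s4_class(fr, "ShadowFrame")
  n <- length(frameImage(fr))
  expect_lt(abs(mean(frameImage(fr)) - cfg@background_level),
            3 * cfg@noise_sigma / sqrt(n) + 0.5)  # 0.5 = quantization
  expect_equal(nrow(frameCells(fr)), 0)
})

test_that("the default sensor frame is 1944 x 2592 pixels", {
  cfg <- opticalConfig()
  expect_identical(cfg@frame_shape, c(1944L, 2592L))
  sf <- new("ShadowFrame",
            image = matrix(100L, 1944, 2592),
            cells = cellTable(numeric(0), numeric(0), numeric(0),
                              numeric(0)),
            config = cfg)
  expect_identical(dim(frameImage(sf)), c(1944L, 2592L))
})

test_that("out-of-bounds cell centres are reported by index", {
  cfg <- opticalConfig(frame_shape = c(128L, 128L))
  cells <- cellTable(c(64, 500), c(64, 64), c(5, 5), c(0.8, 0.8))
  expect_error(renderFrame(cfg, cells), "index: 2")
})

test_that("frames are bit-identical under identical configuration and seed", {
  cfg <- opticalConfig(frame_shape = c(128L, 128L))
  cells <- cellTable(64, 64, 5, 0.8)
  set.seed(42); f1 <- renderFrame(cfg, cells)
  set.seed(42); f2 <- renderFrame(cfg, cells)
  expect_identical(frameImage(f1), frameImage(f2))
})

test_that("noiseless compositing is additive over the background", {
  cfg <- opticalConfig(frame_shape = c(128L, 128L))
  cells <- cellTable(64, 64, 5, 0.8)
  fr <- renderFrame(cfg, cells, noise = FALSE)
  bg <- renderFrame(cfg, noise = FALSE)
  patch <- renderCellPattern(cfg, 5, 0.8)
  half <- (nrow(patch) - 1) / 2
  delta <- matrix(0, 128, 128)
  delta[(64 - half):(64 + half), (64 - half):(64 + half)] <-
    patch - cfg@background_level
  expect_lt(max(abs(frameImage(fr) - (frameImage(bg) + delta))), 1)
})

test_that("planted noiseless cells are recovered at their true positions", {
  cfg <- opticalConfig(frame_shape = c(486L, 648L))
  rows <- c(100, 100, 250, 380, 380)
  cols <- c(120, 420, 270, 150, 500)
  cells <- cellTable(rows, cols, rep(5.5, 5), rep(1.0, 5))
  fr <- renderFrame(cfg, cells, noise = FALSE)
  det <- detectCells(fr)
  expect_equal(nrow(det$meta), 5)
  for (i in seq_len(5)) {
    d <- min(sqrt((det$meta$row - rows[i])^2 + (det$meta$col - cols[i])^2))
    expect_lte(d, 2)
  }
})

test_that("cells closer than the overlap limit are rejected", {
  cfg <- opticalConfig(frame_shape = c(256L, 256L))
  cells <- cellTable(c(128, 138), c(128, 128), c(5, 5), c(0.8, 0.8))
  expect_error(renderFrame(cfg, cells), "separation")
})

test_that("an empty cohort yields an empty manifest", {
  co <- generateCohort(testConfig(), n_per_class = 0, seed = 1)
  expect_length(co$frames, 0)
  expect_equal(nrow(co$manifest), 0)
})

test_that("cohort generation is reproducible and balanced", {
  cfg <- testConfig()
  c1 <- generateCohort(cfg, n_per_class = 12, seed = 9)
  c2 <- generateCohort(cfg, n_per_class = 12, seed = 9)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(frameImage(c1$frames[[1]]), frameImage(c2$frames[[1]]))
  expect_equal(unname(table(c1$manifest$class_label)["CD34_POS"]), 12,
               ignore_attr = TRUE)
  expect_equal(nrow(c1$manifest), 24)
})

test_that("the two class regimes separate by at least 20 PPD counts", {
  m <- smallCohort()
  med <- tapply(m$params$ppd, m$labels, median)
  expect_gte(med[["RESIDUAL"]] - med[["CD34_POS"]], 20)
})

test_that("the first dark ring of default-regime patterns is resolvable", {
  # first-ring radius must exceed 2 px for every default parameter draw
  cfg <- opticalConfig()
  r1_px <- sqrt(cfg@wavelength_um * cfg@distance_um) / cfg@pixel_pitch_um
  expect_gte(r1_px, 2)
  m <- smallCohort()
  expect_true(all(m$params$mmd[m$params$valid] >= 2))
})
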