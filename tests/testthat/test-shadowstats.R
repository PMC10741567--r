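test_that("the radial profile bins pixels by rounded centre distance", {
  prof <- radialProfile(matrix(42, 30, 30))
  expect_equal(nrow(prof), 15)
  expect_equal(prof$radius, 0:14)
  expect_true(all(prof$intensity == 42))
  # centre pixel only contributes to bin 0
  m <- matrix(100, 30, 30)
  m[15, 15] <- 200
  prof <- radialProfile(m)
  expect_equal(prof$intensity[1], 200)
  expect_true(all(prof$intensity[-1] == 100))
})

test_that("shadow parameters reproduce the worked CD34+ example", {
  prof <- data.frame(radius = 0:14,
                     intensity = c(156.8, 150, 140, 128, 118, 112.5,
                                   116, 122, 128, 132, 134, 135, 135,
                                   135, 135))
  p <- computeShadowParams(prof)
  expect_true(p$valid)
  expect_equal(p$cmv, 156.8)
  expect_equal(p$mmd, 5)
  expect_equal(p$ppd, 44.3)
})

test_that("a monotone or flat profile is flagged invalid with zero PPD", {
  flat <- data.frame(radius = 0:14, intensity = rep(80, 15))
  p <- computeShadowParams(flat)
  expect_false(p$valid)
  expect_equal(p$ppd, 0)
  expect_true(is.na(p$mmd))
  inc <- data.frame(radius = 0:14, intensity = seq(10, 150, by = 10))
  expect_false(computeShadowParams(inc)$valid)
})

test_that("a cosine-ring profile localises the first minimum exactly", {
  prof <- data.frame(radius = 0:14,
                     intensity = 100 + 50 * cos((0:14) * pi / 5))
  p <- computeShadowParams(prof)
  expect_equal(p$mmd, 5)
  expect_equal(p$ppd, 100)
})

test_that("PPD is shift-invariant and scales with multiplicative gain", {
  m <- smallCohort()
  crop <- m$crops[[which(m$params$valid)[1]]]
  p0 <- computeShadowParams(crop)
  expect_equal(computeShadowParams(crop + 25)$ppd, p0$ppd)
  expect_equal(computeShadowParams(crop * 1.7)$ppd, 1.7 * p0$ppd,
               tolerance = 1e-9)
})

test_that("the PPD gate keeps the closed interval and matches brute force", {
  params <- data.frame(ppd = c(44.3, 96.3), valid = TRUE)
  expect_equal(ppdGate(params)$ppd, 44.3)
  expect_equal(nrow(ppdGate(data.frame(ppd = numeric(0),
                                       valid = logical(0)))), 0)
  # boundary values are kept
  edges <- data.frame(ppd = c(39.999, 40, 60, 60.001), valid = TRUE)
  expect_equal(ppdGate(edges)$ppd, c(40, 60))
  set.seed(8)
  rand <- data.frame(ppd = runif(1000, 0, 120),
                     valid = sample(c(TRUE, FALSE), 1000, TRUE))
  expect_equal(ppdGate(rand)$ppd,
               rand$ppd[rand$valid & rand$ppd >= 40 & rand$ppd <= 60])
})

test_that("gated fraction is higher for the CD34+ regime than residuals", {
  m <- smallCohort()
  gated <- m$params$valid & m$params$ppd >= 40 & m$params$ppd <= 60
  frac <- tapply(gated, m$labels, mean)
  expect_gt(frac[["CD34_POS"]], frac[["RESIDUAL"]])
})

test_that("boxplot summaries use interpolated quartiles and Tukey fences", {
  s <- boxplotSummary(5)
  expect_equal(c(s$q1, s$median, s$q3, s$iqr), c(5, 5, 5, 0))
  expect_length(s$outliers, 0)
  s <- boxplotSummary(1:8)
  expect_equal(s$q1, 2.75)
  expect_equal(s$q3, 6.25)
  expect_equal(s$iqr, 3.5)
  expect_error(boxplotSummary(numeric(0)), "at least one")
})

test_that("kept values and outliers always partition the input", {
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(sample(5:50, 1), sd = sample(1:10, 1))
    v <- c(v, sample(c(-100, 100), sample(0:2, 1), replace = TRUE))
    s <- boxplotSummary(v)
    expect_equal(length(s$kept) + length(s$outliers), length(v))
  }
})

test_that("sector dispersion of the ring radius is small for round cells", {
  cfg <- opticalConfig()
  patch <- renderCellPattern(cfg, 5, 0.8)
  ctr <- (nrow(patch) + 1) / 2
  crop <- round(patch[(ctr - 14):(ctr + 15), (ctr - 14):(ctr + 15)])
  p <- computeShadowParams(crop)
  expect_true(p$valid)
  expect_lt(p$smd, 2)  # rotationally symmetric pattern: sectors agree
})
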