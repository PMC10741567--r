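test_that("background removal subtracts the global mean exactly", {
  expect_equal(removeBackground(matrix(7, 10, 10)), matrix(0, 10, 10))
  m <- matrix(50, 8, 8)
  m[3, 4] <- 100
  res <- removeBackground(m)
  n <- length(m)
  expect_equal(res[3, 4], 50 - 50 / n)
  expect_equal(res[1, 1], -50 / n)
  expect_equal(sum(res), 0, tolerance = 1e-9)
  set.seed(1)
  r <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(sum(removeBackground(r)), 0, tolerance = 1e-7)
})

test_that("segmentation handles degenerate and isolated-pixel cases", {
  expect_equal(segmentShadows(matrix(0, 10, 10)),
               matrix(0L, 10, 10))
  # constant frame: zero variance, all-zero mask without error
  expect_equal(segmentShadows(removeBackground(matrix(5, 10, 10))),
               matrix(0L, 10, 10))
  # a single strong pixel survives thresholding and closing leaves it alone
  r <- matrix(0, 9, 9)
  r[5, 5] <- 100
  r <- r - mean(r)
  mask <- segmentShadows(r, k_sigma = 3)
  expect_equal(mask[5, 5], 1L)
  expect_equal(sum(mask), 1L)
})

test_that("closing fills a one-pixel gap between neighbouring pixels", {
  r <- matrix(0, 9, 11)
  r[5, 5] <- 100; r[5, 7] <- 100
  r <- r - mean(r)
  mask <- segmentShadows(r, k_sigma = 2)
  expect_equal(mask[5, 6], 1L)
})

test_that("components obey the 8-40 pixel size rule on both dimensions", {
  mk <- function(h, w, at = c(10, 10), nr = 60, nc = 60) {
    m <- matrix(0L, nr, nc)
    m[at[1]:(at[1] + h - 1), at[2]:(at[2] + w - 1)] <- 1L
    m
  }
  expect_equal(nrow(extractObjects(mk(7, 7))), 0)     # below minimum
  expect_equal(nrow(extractObjects(mk(41, 10))), 0)   # above maximum
  one <- extractObjects(mk(8, 8))
  expect_equal(nrow(one), 1)
  # centroid of rows 10..17 is 13.5; floor(13.5 + 0.5) = 14
  expect_equal(one$row, 14L)
  expect_equal(one$col, 14L)
  expect_equal(one$height, 8L)
  edge <- extractObjects(mk(40, 40))
  expect_equal(nrow(edge), 1)                          # inclusive upper end
})

test_that("disjoint components are found and ordered by top-left corner", {
  m <- matrix(0L, 80, 80)
  m[40:49, 50:59] <- 1L
  m[10:19, 10:19] <- 1L
  det <- extractObjects(m)
  expect_equal(nrow(det), 2)
  expect_equal(det$min_row, c(10L, 40L))
  expect_equal(det$row, c(15L, 45L))    # centroid of 10..19 is 14.5 -> 15
})

test_that("diagonal adjacency joins pixels into one component", {
  m <- matrix(0L, 40, 40)
  # a diagonal staircase plus a block: 8-connectivity keeps it together
  for (i in 0:9) m[10 + i, 10 + i] <- 1L
  m[10:17, 10:17] <- 1L
  det <- extractObjects(m)
  expect_equal(nrow(det), 1)
})

test_that("nearby concentric fragments merge only when requested", {
  m <- matrix(0L, 60, 60)
  m[26:34, 26:34] <- 1L          # centre blob 9x9
  m[20, 22:38] <- 1L             # detached arc above it
  plain <- extractObjects(m)
  merged <- extractObjects(m, merge_radius = 15)
  expect_equal(nrow(plain), 1)   # the arc alone fails the height rule
  expect_equal(nrow(merged), 1)  # merged object passes as one
  expect_gt(merged$height, plain$height)
})

test_that("detections shift with the frame and ignore constant offsets", {
  cfg <- opticalConfig(frame_shape = c(200L, 200L))
  fr <- renderFrame(cfg, cellTable(90, 90, 5.5, 1.0), noise = FALSE)
  img <- frameImage(fr)
  base <- extractObjects(segmentShadows(removeBackground(img)),
                         merge_radius = 15)
  # translation equivariance
  sh <- matrix(as.integer(cfg@background_level), 200, 200)
  sh[31:200, 21:200] <- img[1:170, 1:180]
  shifted <- extractObjects(segmentShadows(removeBackground(sh)),
                            merge_radius = 15)
  expect_equal(shifted$row, base$row + 30L)
  expect_equal(shifted$col, base$col + 20L)
  # constant offset invariance
  off <- extractObjects(segmentShadows(removeBackground(img + 17)),
                        merge_radius = 15)
  expect_equal(off, base)
})

test_that("crops are exact 30x30 windows of the original frame", {
  set.seed(3)
  img <- matrix(sample(0:255, 200 * 200, replace = TRUE), 200, 200)
  det <- data.frame(row = 100L, col = 120L)
  cr <- cropCells(img, det)
  expect_length(cr$crops, 1)
  expect_identical(dim(cr$crops[[1]]), c(30L, 30L))
  expect_identical(cr$crops[[1]], img[86:115, 106:135])
  # the detection centre lands on crop position (15, 15)
  expect_identical(cr$crops[[1]][15, 15], img[100, 120])
})

test_that("crops crossing the frame boundary are dropped with a warning", {
  img <- matrix(0L, 100, 100)
  det <- data.frame(row = c(5L, 50L, 98L), col = c(50L, 50L, 50L))
  expect_warning(cr <- cropCells(img, det), "dropped")
  expect_length(cr$crops, 1)
  expect_equal(cr$meta$row, 50L)
})

test_that("every in-bounds detection yields one 30x30 crop", {
  set.seed(4)
  img <- matrix(sample(0:255, 300 * 300, replace = TRUE), 300, 300)
  det <- data.frame(row = sample(20:280, 25), col = sample(20:280, 25))
  cr <- cropCells(img, det)
  expect_length(cr$crops, 25)
  expect_true(all(vapply(cr$crops, function(p) all(dim(p) == 30),
                         logical(1))))
})
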