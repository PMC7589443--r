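test_that("HSI conversion reproduces closed-form colour anchors", {
  px <- array(0L, c(16, 16, 3))
  mk <- function(r, g, b) {
    p <- px; p[, , 1] <- r; p[, , 2] <- g; p[, , 3] <- b
    rgbToHSI(RGBFrame(p, "side"))
  }
  red <- mk(255, 0, 0)
  expect_equal(red$h[1, 1], 0)
  expect_equal(red$s[1, 1], 1)
  expect_equal(red$i[1, 1], 1 / 3)
  green <- mk(0, 255, 0)
  expect_equal(green$h[1, 1], 120)
  blue <- mk(0, 0, 255)
  expect_equal(blue$h[1, 1], 240)
  grey <- mk(100, 100, 100)
  expect_equal(grey$s[1, 1], 0)
  expect_equal(grey$h[1, 1], 0)    # achromatic hue convention
  black <- mk(0, 0, 0)
  expect_equal(black$s[1, 1], 0)
  expect_equal(black$i[1, 1], 0)
})

test_that("excess-green index is 2G - R - B with documented range", {
  px <- array(0L, c(16, 16, 3))
  px[, , 1] <- 10L; px[, , 2] <- 200L; px[, , 3] <- 30L
  eg <- excessGreen(RGBFrame(px, "top"))
  expect_true(all(eg == 2 * 200 - 10 - 30))
  px[, , 1] <- 255L; px[, , 2] <- 0L; px[, , 3] <- 255L
  expect_true(all(excessGreen(RGBFrame(px, "top")) == -510))
})

test_that("side-view segmentation applies hue, saturation and intensity gates", {
  px <- array(0L, c(16, 16, 3))
  px[, , 1] <- 50L; px[, , 2] <- 160L; px[, , 3] <- 55L  # vegetation green
  f <- RGBFrame(px, "side")
  expect_true(all(framePixels(segmentSideView(f))))
  # very dark pixel fails the intensity gate (lo bound is open)
  cfg <- SegmentationConfig(intRange = c(0.35, 0.98))  # pixel i = 0.3464
  expect_warning(m <- segmentSideView(f, cfg), "empty mask")
  expect_false(any(framePixels(m)))
  # saturated but out-of-hue (blue) background fails the hue gate
  px2 <- array(0L, c(16, 16, 3))
  px2[, , 3] <- 200L
  expect_warning(m2 <- segmentSideView(RGBFrame(px2, "side")), "empty mask")
  expect_false(any(framePixels(m2)))
})

test_that("top-view segmentation thresholds the excess-green index strictly", {
  px <- array(100L, c(16, 16, 3))
  px[1:8, , 2] <- 111L           # EG = 22 > 20 on the top half
  px[9:16, , 2] <- 110L          # EG = 20, not > 20
  m <- segmentTopView(RGBFrame(px, "top"))
  expect_true(all(framePixels(m)[1:8, ]))
  expect_false(any(framePixels(m)[9:16, ]))
})

test_that("cropFrame uses 1-based inclusive bounds and validates them", {
  px <- array(0L, c(40, 30, 3))
  px[10, 5, 1] <- 99L
  f <- RGBFrame(px, "side")
  g <- cropFrame(f, SegmentationConfig(cropRegion = c(10, 25, 5, 20)))
  expect_equal(dim(framePixels(g))[1:2], c(16L, 16L))
  expect_equal(framePixels(g)[1, 1, 1], 99L)
  expect_error(cropFrame(f, SegmentationConfig(cropRegion = c(1, 41, 1, 30))),
               "exceeds frame height")
  expect_error(cropFrame(f, SegmentationConfig(cropRegion = c(1, 40, 1, 31))),
               "exceeds frame width")
  expect_identical(framePixels(cropFrame(f, SegmentationConfig())),
                   framePixels(f))
})

test_that("component labelling is 8-connected and matches the flood-fill oracle", {
  # two pixels touching only diagonally form one component
  m <- matrix(FALSE, 16, 16)
  m[5, 5] <- TRUE; m[6, 6] <- TRUE
  lab <- labelComponents(BinaryMask(m, "side"))
  expect_equal(max(lab), 1L)
  # random masks agree with the reference flood fill up to label permutation
  for (s in 1:5) {
    set.seed(100 + s)
    px <- matrix(runif(40 * 40) < 0.35, 40, 40)
    a <- labelComponents(BinaryMask(px, "side"))
    b <- napusPheno:::refLabelComponents(px)
    expect_equal(max(a), max(b))
    # identical partitions: each label pair occurs consistently
    expect_equal(length(unique(paste(a[px], b[px]))), max(a))
  }
})

test_that("cleanMask removes only sub-threshold components and keeps pixels", {
  m <- matrix(FALSE, 64, 64)
  m[10:30, 10:30] <- TRUE       # 441 px, kept
  m[50, 50] <- TRUE             # speck, removed
  m[60:62, 60:62] <- TRUE       # 9 px, removed at default min area 64
  out <- framePixels(cleanMask(BinaryMask(m, "side")))
  expect_equal(sum(out), 441)
  expect_true(all(m[out]))      # no pixel invented
  # with a permissive threshold everything survives
  out2 <- cleanMask(BinaryMask(m, "side"),
                    SegmentationConfig(minComponentArea = 1))
  expect_identical(framePixels(out2), m)
})

test_that("maskedGrey restricts the channel to the mask and rejects empty masks", {
  px <- array(0L, c(16, 16, 3))
  px[, , 1] <- 30L; px[, , 2] <- 60L; px[, , 3] <- 90L
  f <- RGBFrame(px, "side")
  m <- matrix(FALSE, 16, 16); m[1:4, 1:4] <- TRUE
  g <- maskedGrey(f, BinaryMask(m, "side"))
  expect_true(all(g[m] == 60L))
  expect_true(all(is.na(g[!m])))
  gg <- maskedGrey(f, BinaryMask(m, "side"), channel = "green")
  expect_true(all(gg[m] == 60L))
  err <- tryCatch(maskedGrey(f, BinaryMask(matrix(FALSE, 16, 16), "side")),
                  condition = function(c) c)
  expect_s3_class(err, "emptyForegroundError")
})

test_that("frame, mask and segmentation-config round trips are lossless", {
  dir <- tempfile("io-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  f <- randomFrame(3, view = "top")
  fp <- file.path(dir, "f.png")
  writeFrame(f, fp)
  f2 <- readFrame(fp, "top")
  expect_identical(framePixels(f2), framePixels(f))
  m <- BinaryMask(randomPolyomino(4), "top")
  mp <- file.path(dir, "m.png")
  writeMask(m, mp)
  expect_identical(framePixels(readMask(mp, "top")), framePixels(m))
  cfg <- SegmentationConfig(cropRegion = c(2, 30, 3, 38), hueRange = c(70, 170),
                            satMin = 0.2, intRange = c(0.05, 0.9),
                            egThreshold = 25, minComponentArea = 32)
  cp <- file.path(dir, "cfg.yaml")
  writeSegmentationConfig(cfg, cp)
  cfg2 <- readSegmentationConfig(cp)
  expect_equal(cfg2@cropRegion, cfg@cropRegion)
  expect_equal(cfg2@hueRange, cfg@hueRange)
  expect_equal(cfg2@satMin, cfg@satMin)
  expect_equal(cfg2@intRange, cfg@intRange)
  expect_equal(cfg2@egThreshold, cfg@egThreshold)
  expect_equal(cfg2@minComponentArea, cfg@minComponentArea)
  expect_error(readFrame(file.path(dir, "nope.png"), "side"), "not found")
})

test_that("class validity rejects malformed frames, masks and configs", {
  expect_error(RGBFrame(array(0L, c(8, 8, 3)), "side"), "16 x 16")
  expect_error(RGBFrame(array(300L, c(16, 16, 3)), "side"), "\\[0, 255\\]")
  expect_error(RGBFrame(array(0L, c(16, 16, 3)), "oblique"), "side")
  expect_error(BinaryMask(matrix(1, 4, 4), "side"), "logical")
  expect_error(SegmentationConfig(cropRegion = c(5, 2, 1, 4)), "cropRegion")
  expect_error(SegmentationConfig(hueRange = c(180, 60)), "hueRange")
  expect_error(SegmentationConfig(minComponentArea = 0), "minComponentArea")
})
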