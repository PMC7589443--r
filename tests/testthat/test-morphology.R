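test_that("rectangle morphology matches closed forms", {
  m <- matrix(FALSE, 60, 60)
  m[11:50, 21:40] <- TRUE        # 40 x 20 axis-aligned rectangle
  v <- morphologicalTraits(BinaryMask(m, "side"))
  expect_equal(v[["TPA"]], 800)
  expect_equal(v[["H"]], 40)
  expect_equal(v[["W"]], 20)
  expect_equal(v[["HWR"]], 2)
  expect_equal(v[["HA"]], 800)   # corner-point hull area equals pixel area
  expect_equal(v[["PC1"]], 1)
  expect_equal(v[["PC2"]], 1)
  expect_equal(v[["AC"]], 1)
  expect_equal(v[["PC3"]], 1)    # rectangle contour equals its centre hull
})

test_that("rasterised disk has near-unit roundness and Feret compactness", {
  m <- matrix(FALSE, 128, 128)
  for (r in 1:128) for (c in 1:128)
    if ((r - 64.5)^2 + (c - 64.5)^2 <= 50^2) m[r, c] <- TRUE
  v <- morphologicalTraits(BinaryMask(m, "top"))
  # the Moore contour overestimates a circle's perimeter by ~5%, so the
  # roundness of an ideal disk sits a little below 1
  expect_gt(v[["R"]], 0.88);   expect_lt(v[["R"]], 1.05)
  expect_gt(v[["PC6"]], 0.95); expect_lt(v[["PC6"]], 1.05)
})

test_that("compactness and solidity invariants hold on random polyominoes", {
  for (s in 1:8) {
    px <- randomPolyomino(200 + s, n = 40L)
    v <- morphologicalTraits(BinaryMask(px, "side"))
    expect_gte(v[["HA"]], v[["TPA"]])
    expect_lte(v[["PC1"]], 1)
    expect_lte(v[["PC2"]], 1)
    expect_lte(v[["PC3"]], 1)   # hull of centres minimises enclosing perimeter
    expect_lte(v[["AC"]], 1)
    expect_gte(min(v[c("TPA", "H", "W", "HA")]), 0)
    expect_lte(v[["PC5"]], 1 + 1e-9)
  }
})

test_that("empty mask reports missing morphology with a warning", {
  expect_warning(v <- morphologicalTraits(BinaryMask(matrix(FALSE, 20, 20),
                                                     "side")),
                 "empty mask")
  expect_true(all(is.na(v)))
  expect_equal(length(v), 14L)
})

test_that("box-counting dimension hits plane, line and Sierpinski anchors", {
  full <- BinaryMask(matrix(TRUE, 256, 256), "top")
  expect_lt(abs(fractalDimension(full) - 2), 0.05)
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  expect_lt(abs(fractalDimension(BinaryMask(line, "top")) - 1), 0.05)
  sier <- BinaryMask(sierpinskiMask(7L), "top")
  expect_lt(abs(fractalDimension(sier) - log(3) / log(2)), 0.05)
})

test_that("FDIC crops to the bounding box while FDNIC keeps the frame", {
  m <- matrix(FALSE, 256, 256)
  m[1:32, 1:32] <- TRUE
  b <- BinaryMask(m, "top")
  expect_lt(abs(fractalDimension(b, cropped = TRUE) - 2), 0.05)
  # un-cropped: same pattern over a 256-square of mostly empty boxes
  expect_lt(fractalDimension(b, cropped = FALSE),
            fractalDimension(b, cropped = TRUE) + 1e-9)
  tiny <- matrix(FALSE, 20, 20); tiny[3, 3] <- TRUE
  expect_warning(fd <- fractalDimension(BinaryMask(tiny, "top")), "too small")
  expect_true(is.na(fd))
})

test_that("histogram texture reproduces closed-form distributions", {
  g <- matrix(NA_integer_, 32, 32)
  g[1:16, ] <- 77L                       # constant region
  v <- textureTraits(g)
  expect_equal(v[["M_TEX"]], 77 / 255)
  expect_equal(v[["SE_TEX"]], 0)
  expect_equal(v[["S_TEX"]], 0)
  expect_equal(v[["MU3_TEX"]], 0)
  expect_equal(v[["U_TEX"]], 1)
  expect_equal(v[["E_TEX"]], 0)
  g2 <- matrix(NA_integer_, 32, 32)
  g2[1:8, ] <- 0L; g2[9:16, ] <- 255L    # two levels, equal mass
  v2 <- textureTraits(g2)
  expect_equal(v2[["E_TEX"]], 1)
  expect_equal(v2[["U_TEX"]], 0.5)
  g3 <- matrix(rep(0:255, each = 4), 32, 32)  # uniform over all 256 levels
  v3 <- textureTraits(g3)
  expect_equal(v3[["E_TEX"]], 8)
  expect_equal(v3[["U_TEX"]], 1 / 256)
})

test_that("colour traits count hue-gated pixels and average green fraction", {
  px <- array(0L, c(16, 16, 3))
  px[, , 1] <- 50L; px[, , 2] <- 160L; px[, , 3] <- 55L   # hue ~ 117 deg
  f <- RGBFrame(px, "top")
  m <- matrix(FALSE, 16, 16); m[1:4, 1:4] <- TRUE
  v <- colourTraits(f, BinaryMask(m, "top"))
  expect_equal(v[["GPA"]], 16)
  expect_equal(v[["GCV"]], 160 / (50 + 160 + 55))
  # red pixels are outside the hue gate
  px[, , ] <- 0L; px[, , 1] <- 200L
  v2 <- colourTraits(RGBFrame(px, "top"), BinaryMask(m, "top"))
  expect_equal(v2[["GPA"]], 0)
})

test_that("trait catalogues have the documented sizes and suffixes", {
  expect_length(sideTraitNames(), 23L)
  expect_length(topTraitNames(), 18L)
  expect_length(imageTraitNames(), 41L)
  expect_true(all(grepl("_SV$", sideTraitNames())))
  expect_true(all(grepl("_TV$", topTraitNames())))
  expect_true("GCV_TV" %in% topTraitNames())
  expect_false("GCV_SV" %in% sideTraitNames())
})

test_that("maskTraits agrees with the naive reference on a random polyomino", {
  px <- randomPolyomino(11)
  f <- randomFrame(11)
  m <- BinaryMask(px, "side")
  a <- maskTraits(f, m)
  b <- referenceTraits(f, m)
  expect_identical(names(a), names(b))
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("single-pixel components use the documented unit contour length", {
  m <- matrix(FALSE, 70, 70)
  m[10:18, 10:18] <- TRUE        # 81-px block survives cleaning
  m[40, 40] <- TRUE              # lone pixel: contour length 1 by convention
  v <- morphologicalTraits(BinaryMask(m, "side"))
  lab <- labelComponents(BinaryMask(m, "side"))
  expect_equal(max(lab), 2L)
  expect_equal(v[["TPA"]], 82)
  expect_true(is.finite(v[["PAR"]]))
})
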