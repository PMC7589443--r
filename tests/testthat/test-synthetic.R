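test_that("scene rendering is a pure function of its spec, seed mandatory", {
  expect_error(sceneSpec(view = "side"), "seed is mandatory")
  sp <- sceneSpec(view = "side", seed = 11L)
  s1 <- renderPlantScene(sp)
  s2 <- renderPlantScene(sp)
  expect_identical(framePixels(s1$frame), framePixels(s2$frame))
  expect_identical(framePixels(s1$mask), framePixels(s2$mask))
  s3 <- renderPlantScene(sceneSpec(view = "side", seed = 12L))
  expect_false(identical(framePixels(s1$frame), framePixels(s3$frame)))
  # conveyor band occupies the bottom rows and never overlaps the plant
  expect_true(all(s1$conveyor[512 - 39:0, ]))
  expect_false(any(framePixels(s1$mask) & s1$conveyor))
})

test_that("segmentation recovers the rendered truth mask almost exactly", {
  for (spec in list(sceneSpec(view = "side", seed = 21L),
                    sceneSpec(view = "top", seed = 22L))) {
    sc <- renderPlantScene(spec)
    fr <- cropFrame(sc$frame, sc$cropConfig)
    seg <- cleanMask(segmentFrame(fr, sc$cropConfig), sc$cropConfig)
    cr <- sc$cropConfig@cropRegion
    truth <- framePixels(sc$mask)
    if (length(cr) == 4L) truth <- truth[cr[1]:cr[2], cr[3]:cr[4]]
    pred <- framePixels(seg)
    iou <- sum(pred & truth) / sum(pred | truth)
    expect_gte(iou, 0.99)
  }
})

test_that("the exponential growth generator hits its moments", {
  d <- simulateGrowthSeries(100, 0.3, cv = 0, tmax = 12L, seed = 1L)
  expect_equal(d$value, 100 * exp(0.3 * d$t))
  expect_error(simulateGrowthSeries(-1, 0.3, seed = 1L))
  # multiplicative noise keeps the series nonnegative
  d2 <- simulateGrowthSeries(10, -0.5, cv = 2, tmax = 12L, seed = 2L)
  expect_true(all(d2$value >= 0))
})

test_that("the simulated trial is balanced with the declared layout", {
  d <- simulateTrialData(nLines = 12, nEnv = 2, nRep = 5, seed = 3L)
  expect_equal(nrow(d), 12 * 2 * 5)
  tab <- table(d$line, d$env)
  expect_true(all(tab == 5))
  d2 <- simulateTrialData(nLines = 12, nEnv = 2, nRep = 5, seed = 3L)
  expect_identical(d, d2)
})

test_that("population genotypes are consistent with the segment truth", {
  pop <- simulatePopulation(nLines = 30, seed = 5L)
  geno <- pop$genotypes
  mk <- pop$markers
  expect_equal(nrow(geno), 31L)                   # lines + recurrent parent
  expect_true(all(geno["ZY821", ] == 0L))
  expect_setequal(unique(as.vector(geno)), c(0L, 1L))
  expect_equal(sum(defaultGenome()), 728e6)
  expect_true(all(mk$bp <= defaultGenome()[mk$chrom]))
  # a marker is donor iff it falls inside one of that line's segments
  for (l in sample(rownames(geno)[1:30], 5)) {
    segs <- pop$segments[pop$segments$line == l, ]
    inSeg <- vapply(seq_len(nrow(mk)), function(i) {
      any(segs$chrom == mk$chrom[i] & segs$start <= mk$bp[i] &
            segs$end >= mk$bp[i])
    }, NA)
    expect_identical(unname(geno[l, ]) == 1L, inSeg)
  }
})

test_that("planted QTL effects are recorded in the truth ledger and sized", {
  q <- data.frame(trait = "TPA_SV", time_point = 7L, chrom = "C04",
                  bp = 25e6, pve = 20)
  pop <- simulatePopulation(nLines = 60, qtls = q, seed = 7L)
  tq <- pop$truth$qtl
  expect_equal(nrow(tq), 1L)
  expect_equal(tq$chrom, "C04")
  expect_gt(tq$n_carriers, 0)
  x <- pop$genotypes[, tq$marker]
  f <- mean(x)
  vLineMean <- 1 + 0.5 / 2 + 4.1667 / 10
  expect_equal(tq$effect, sqrt(0.20 * vLineMean / (f * (1 - f))),
               tolerance = 1e-10)
  expect_error(
    simulatePopulation(nLines = 60, seed = 7L,
                       qtls = transform(q, pve = 90)),
    "unachievable")
})

test_that("the fixture directory has the documented pipeline layout", {
  dir <- tempfile("fixture")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  writeFixtureDir(dir, nScenes = 1L, seed = 9L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_setequal(man$view, c("side", "top"))
  expect_true(all(file.exists(file.path(dir, man$path))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  # recorded truth area equals the pixel count of the written mask
  id <- "side_01"
  m <- readMask(file.path(dir, "masks", paste0(id, ".png")), view = "side")
  expect_equal(truth$scenes[[id]]$tpa, sum(framePixels(m)))
})
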