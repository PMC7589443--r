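test_that("regression metrics reproduce hand-computed examples", {
  y <- c(100, 200); yhat <- c(110, 180)
  v <- regressionMetrics(y, yhat, p = 0)
  expect_equal(v[["mape_percent"]], 10)
  expect_equal(v[["sd_ape_percent"]], 0)
  # perfect prediction
  v2 <- regressionMetrics(c(3, 5, 9, 11), c(3, 5, 9, 11), p = 1)
  expect_equal(v2[["adjusted_r2"]], 1)
  expect_equal(v2[["mape_percent"]], 0)
  # adjusted R2 closed form: n = 10, p = 1, R2 = 0.5 -> 0.4375
  set.seed(1)
  y <- rnorm(10, 50, 1)
  tss <- sum((y - mean(y))^2)
  resid <- rnorm(10); resid <- resid - mean(resid)
  resid <- resid * sqrt(0.5 * tss / sum(resid^2))
  v3 <- regressionMetrics(y, y - resid, p = 1)
  expect_equal(v3[["adjusted_r2"]], 1 - 0.5 * 9 / 8, tolerance = 1e-12)
  expect_error(regressionMetrics(c(-1, 2, 3, 4), 1:4, 1), "nonpositive")
  expect_error(regressionMetrics(1:3, 1:2, 1), "lengths differ")
})

test_that("noise-free power-law data is inverted exactly", {
  d <- data.frame(TPA_SV = seq(2e3, 2e5, length.out = 40))
  d$TPA_TV <- 0.6 * d$TPA_SV^0.95
  d$FW_g <- exp(1.2) * d$TPA_SV^0.8
  d$DW_g <- 0.12 * d$FW_g
  f <- fitBiomassModel(4, d, "FW_g")
  expect_equal(unname(f@coef[1]), 1.2, tolerance = 1e-6)
  expect_equal(unname(f@coef[2]), 0.8, tolerance = 1e-6)
  expect_lt(f@metrics[["mape_percent"]], 1e-6)
  # models 4 and 9 coincide at the default m = TPA_SV
  f9 <- fitBiomassModel(9, d, "FW_g")
  expect_equal(unname(f@coef), unname(f9@coef), tolerance = 1e-12)
})

test_that("power-model predictions are positive, monotone and identity at a=0,b=1", {
  d <- data.frame(TPA_SV = c(10, 100, 1000), TPA_TV = c(6, 60, 600))
  fit <- new("BiomassFit", modelId = 4L, family = "power(TPA_SV)",
             target = "FW_g", coef = c(`(Intercept)` = 0, lnTPA_SV = 1),
             logY = TRUE, m = "TPA_SV",
             metrics = c(adjusted_r2 = 1, mape_percent = 0,
                         sd_ape_percent = 0, n = 3))
  expect_equal(predictBiomass(fit, d), d$TPA_SV)
  d2 <- simulateBiomassCalibration(seed = 5L)
  f <- fitBiomassModel(4, d2, "FW_g")
  yh <- predictBiomass(f, d2[order(d2$TPA_SV), ])
  expect_true(all(yh > 0))
  expect_true(all(diff(yh) >= 0))
})

test_that("ten-fold CV is deterministic with balanced folds and matches an oracle", {
  d <- simulateBiomassCalibration(n = 120L, seed = 21L)
  cv1 <- kfoldCV(d, 9L, k = 10, seed = 77L)
  cv2 <- kfoldCV(d, 9L, k = 10, seed = 77L)
  expect_identical(cv1, cv2)
  expect_equal(unname(cv1$fold_metrics[, "n"]), rep(12, 10))
  # hand-rolled oracle: same shuffle, lm() per fold, metrics recomputed
  set.seed(77L)
  ord <- sample.int(120)
  foldId <- integer(120); foldId[ord] <- rep(1:10, length.out = 120)
  oracle <- t(sapply(1:10, function(f) {
    tr <- d[foldId != f, ]; te <- d[foldId == f, ]
    m <- stats::lm(log(FW_g) ~ log(TPA_SV), data = tr)
    yhat <- exp(predict(m, te))
    ape <- 100 * abs(yhat - te$FW_g) / te$FW_g
    r2 <- 1 - sum((te$FW_g - yhat)^2) / sum((te$FW_g - mean(te$FW_g))^2)
    c(1 - (1 - r2) * (nrow(te) - 1) / (nrow(te) - 2), mean(ape), sd(ape))
  }))
  expect_lt(max(abs(cv1$fold_metrics[, 1:3] - oracle)), 1e-9)
  expect_error(kfoldCV(d[1:5, ], 9L, k = 10, seed = 1L), "k exceeds")
})

test_that("ranking reports all 11 models and flags degenerate designs", {
  d <- simulateBiomassCalibration(seed = 31L)
  rk <- rankBiomassModels(d, "FW_g")
  expect_equal(sort(rk$model_id), 1:11)
  expect_true(all(diff(rk$adjusted_r2) <= 1e-12))
  bad <- d; bad$TPA_TV <- 5000      # constant companion area
  expect_error(fitBiomassModel(5, bad, "FW_g"), "singular")
  neg <- d; neg$FW_g[1] <- -1
  expect_error(fitBiomassModel(4, neg, "FW_g"), "nonpositive")
})

test_that("completeTraitTable appends FW/DW rows and propagates missing areas", {
  d <- simulateBiomassCalibration(seed = 41L)
  fw <- fitBiomassModel(9, d, "FW_g")
  dw <- fitBiomassModel(9, d, "DW_g")
  tt <- expand.grid(line = c("L1", "L2"), replicate = 1:2, season = "G1",
                    time_point = 1:2, trait = c("TPA_SV", "TPA_TV"),
                    stringsAsFactors = FALSE)
  tt$value <- 1e4 + seq_len(nrow(tt))
  tt$value[tt$line == "L2" & tt$trait == "TPA_TV" & tt$time_point == 2 &
             tt$replicate == 1] <- NA
  out <- completeTraitTable(tt, fw, dw)
  expect_setequal(unique(out$trait), c("TPA_SV", "TPA_TV", "FW", "DW"))
  fwRows <- out[out$trait == "FW", ]
  expect_equal(nrow(fwRows), 8L)
  miss <- fwRows[fwRows$line == "L2" & fwRows$time_point == 2 &
                   fwRows$replicate == 1, ]
  expect_true(is.na(miss$value))
  expect_true(all(fwRows$value[!is.na(fwRows$value)] > 0))
})
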