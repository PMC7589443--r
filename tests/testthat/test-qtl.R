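test_that("marker LOD and PVE agree with a direct likelihood-ratio oracle", {
  set.seed(31)
  n <- 60
  x <- rbinom(n, 1, 0.3)
  y <- 10 + 0.8 * x + rnorm(n)
  geno <- cbind(M1 = x, M2 = rbinom(n, 1, 0.4))
  rownames(geno) <- sprintf("L%03d", 1:n)
  map <- data.frame(marker = c("M1", "M2"), chrom = c("A01", "A02"),
                    bp = c(5e6, 9e6))
  pheno <- stats::setNames(y, rownames(geno))
  scan <- qtlScan(geno, map, pheno, lodThreshold = 2.5, bgMax = 0L)
  ms <- markerStats(scan)
  rss0 <- sum(stats::resid(stats::lm(y ~ 1))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(ms$lod[ms$marker == "M1"],
               n * log(rss0 / rss1) / (2 * log(10)), tolerance = 1e-10)
  expect_equal(ms$pve[ms$marker == "M1"],
               100 * (rss0 - rss1) / tss, tolerance = 1e-10)
  expect_equal(ms$effect[ms$marker == "M1"],
               unname(stats::coef(stats::lm(y ~ x))[2]), tolerance = 1e-10)
})

test_that("a strongly planted QTL is located in the carrier segment", {
  pop <- simulatePopulation(
    qtls = data.frame(trait = "TPA_SV", time_point = 7L, chrom = "A03",
                      bp = 17.5e6, pve = 35),
    seed = 101L)
  pheno <- tapply(pop$traits$value, pop$traits$line, mean)
  scan <- qtlScan(pop$genotypes, pop$markers, pheno)
  rec <- qtlRecords(scan)
  expect_gt(nrow(rec), 0L)
  best <- rec[which.max(rec$lod), ]
  expect_equal(best$chrom, "A03")
  expect_gte(best$lod, 2.5)
  expect_lt(abs(best$bp - 17.5e6), 10e6)
})

test_that("Dunnett with one carrier equals the pooled two-sample t-test", {
  set.seed(42)
  pheno <- data.frame(line = rep(c("ZY821", "ISL001"), each = 10),
                      value = c(rnorm(10, 10), rnorm(10, 11)))
  dv <- dunnettValidate(pheno, "ISL001", "ZY821", seed = 99L)
  tt <- stats::t.test(value ~ line, data = pheno, var.equal = TRUE)
  expect_lt(abs(unname(dv$p_adj) - tt$p.value), 0.01)  # MC SE ~ 0.0015
  expect_equal(dv$df, 18)
  expect_equal(abs(unname(dv$t)), abs(unname(tt$statistic)), tolerance = 1e-10)
})

test_that("Dunnett adjustment matches the multcomp oracle for several carriers", {
  skip_if_not_installed("multcomp")
  set.seed(7)
  ph <- data.frame(line = rep(c("ZY821", paste0("ISL00", 1:3)), each = 8),
                   value = rnorm(32, rep(c(0, .4, .8, .2), each = 8)))
  dv <- dunnettValidate(ph, paste0("ISL00", 1:3), "ZY821", seed = 5L)
  ph$line <- stats::relevel(factor(ph$line), "ZY821")
  g <- multcomp::glht(stats::aov(value ~ line, ph),
                      linfct = multcomp::mcp(line = "Dunnett"))
  oracle <- as.numeric(summary(g)$test$pvalues)
  expect_lt(max(abs(unname(dv$p_adj) - oracle)), 0.01)
  expect_error(dunnettValidate(ph, "ISL009", "ZY821", seed = 1L), "carrier")
})

test_that("the QTL interval is the intersection of supporting segments", {
  segs <- data.frame(line = c("A", "B", "C"), chrom = "A01",
                     start = c(1e6, 3e6, 20e6), end = c(12e6, 9e6, 30e6))
  iv <- defineInterval("A01", 5e6, c("A", "B"), segs)
  expect_equal(iv$start, 3e6)
  expect_equal(iv$end, 9e6)
  expect_false(iv$flagged)
  expect_setequal(iv$carriers, c("A", "B"))
  # only segments containing the peak participate
  iv2 <- defineInterval("A01", 25e6, c("A", "B", "C"), segs)
  expect_equal(iv2$carriers, "C")
  expect_error(defineInterval("A01", 15e6, c("A", "B"), segs), "no carrier")
})

test_that("nonredundant merging is a transitive overlap closure, idempotent", {
  recs <- data.frame(chrom = c("A01", "A01", "A01", "C02"),
                     start = c(1e6, 4e6, 20e6, 2e6),
                     end = c(5e6, 9e6, 25e6, 3e6))
  mg <- mergeNonredundant(recs)
  expect_equal(nrow(mg$groups), 3L)
  g1 <- mg$groups[mg$groups$chrom == "A01" & mg$groups$start == 1e6, ]
  expect_equal(g1$end, 9e6)
  expect_equal(g1$n_qtl, 2L)
  # idempotent: merging the group table again changes nothing
  mg2 <- mergeNonredundant(mg$groups)
  expect_equal(nrow(mg2$groups), 3L)
  # order-invariant
  mg3 <- mergeNonredundant(recs[c(3, 1, 4, 2), ])
  expect_equal(mg3$groups[order(mg3$groups$chrom, mg3$groups$start),
                          c("chrom", "start", "end", "n_qtl")],
               mg$groups[order(mg$groups$chrom, mg$groups$start),
                         c("chrom", "start", "end", "n_qtl")],
               ignore_attr = TRUE)
  empty <- mergeNonredundant(recs[0, ])
  expect_equal(nrow(empty$groups), 0L)
})

test_that("an obvious hotspot is flagged and the permutation test is seeded", {
  genome <- defaultGenome()
  # 12 QTL piled on one window plus scattered singles
  recs <- data.frame(chrom = c(rep("A05", 12), "C03", "C07", "A09"),
                     start = c(rep(10e6, 12), 5e6, 30e6, 12e6))
  recs$end <- recs$start + 0.8e6
  hp1 <- hotspotPermutation(recs, genome, nPerm = 300, seed = 55L)
  hp2 <- hotspotPermutation(recs, genome, nPerm = 300, seed = 55L)
  expect_identical(hp1$windows, hp2$windows)
  hot <- hp1$windows[hp1$windows$hotspot, ]
  expect_true(any(hot$chrom == "A05" & hot$count >= 12))
  expect_false(any(hot$chrom %in% c("C03", "C07", "A09")))
  expect_error(hotspotPermutation(recs[0, ], genome, seed = 1L), "no QTL")
})
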