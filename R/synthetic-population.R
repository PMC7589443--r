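#' Default synthetic genome for substitution-line simulation
#'
#' Nineteen chromosomes (A01-A10, C01-C09) with physical lengths of realistic
#' Brassica napus magnitude, ~730 Mb in total.
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
defaultGenome <- function() {
  stats::setNames(
    c(32, 31, 35, 23, 28, 27, 27, 21, 37, 25,
      44, 50, 65, 53, 46, 41, 48, 42, 53) * 1e6,
    c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9)))
}

#' Simulate a growth series of projected area
#'
#' value(t) = a exp(b t) (1 + eps_t), eps_t ~ N(0, cv^2), truncated at 0.
#'
#' @param a,b exponential parameters (a > 0).
#' @param cv multiplicative noise coefficient of variation.
#' @param tmax number of time points (default 12).
#' @param seed integer seed.
#' @return data.frame: t, value.
#' @export
simulateGrowthSeries <- function(a, b, cv = 0.05, tmax = 12L, seed) {
  stopifnot(a > 0, is.finite(b))
  set.seed(seed)
  t <- seq_len(tmax)
  v <- a * exp(b * t) * (1 + stats::rnorm(tmax, 0, cv))
  data.frame(t = t, value = pmax(v, 0))
}

#' Simulate destructive biomass calibration data
#'
#' Plants span the growth range on a log-uniform projected-area scale; fresh
#' weight follows the power law FW = exp(a) TPA_SV^b with lognormal noise,
#' dry weight is a fixed fraction with its own noise, and TPA_TV is an
#' allometric companion of TPA_SV.
#'
#' @param n number of plants (measurement protocol: 120).
#' @param a,b power-law parameters on the log scale.
#' @param sigma lognormal noise SD of FW around the power law.
#' @param seed integer seed.
#' @return data.frame: plant_id, TPA_SV, TPA_TV, FW_g, DW_g.
#' @export
simulateBiomassCalibration <- function(n = 120L, a = 1.2, b = 0.8,
                                       sigma = 0.15, seed) {
  set.seed(seed)
  tpaSV <- exp(stats::runif(n, log(2e3), log(2e5)))
  tpaTV <- 0.6 * tpaSV^0.95 * exp(stats::rnorm(n, 0, 0.10))
  fw <- exp(a) * tpaSV^b * exp(stats::rnorm(n, 0, sigma))
  dw <- 0.12 * fw * exp(stats::rnorm(n, 0, 0.08))
  data.frame(plant_id = sprintf("P%03d", seq_len(n)),
             TPA_SV = tpaSV, TPA_TV = tpaTV, FW_g = fw, DW_g = dw)
}

#' Simulate a yield regression design with a planted sparse signal
#'
#' Candidate predictors mimic the line-by-(trait, time point) matrix: i.i.d.
#' standard normal columns named trait_timepoint. The response is a linear
#' combination of k planted columns plus noise scaled so the population R2
#' equals \code{r2}.
#'
#' @param n lines (population: 89 ISLs + 9 parent repeats = 98).
#' @param p candidate predictors (43 traits x 12 time points = 516).
#' @param k planted predictors.
#' @param r2 population R2 of the planted model.
#' @param seed integer seed.
#' @return list: X (n x p named matrix), y, planted (column names), beta.
#' @export
simulateYieldDesign <- function(n = 98L, p = 516L, k = 8L, r2 = 0.7, seed) {
  stopifnot(r2 > 0, r2 < 1, k <= p)
  set.seed(seed)
  tn <- paste0("trait", sprintf("%02d", seq_len(ceiling(p / 12))))
  cn <- paste(rep(tn, each = 12), rep(1:12, length(tn)), sep = "_")[seq_len(p)]
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, cn))
  planted <- sample(cn, k)
  beta <- stats::setNames(rep(sqrt(r2 / k), k), planted)
  signal <- drop(X[, planted, drop = FALSE] %*% beta)
  y <- signal + stats::rnorm(n, 0, sqrt(1 - r2))
  list(X = X, y = y, planted = planted, beta = beta)
}

#' Simulate a balanced multi-environment trial for one trait
#'
#' y_ler = mu + G_l + GE_le + e_ler with independent normal components.
#'
#' @param nLines lines.
#' @param sigma2_G,sigma2_GE,sigma2_e variance components.
#' @param nEnv environments (seasons), \code{nRep} replicates.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return data.frame: line, env, replicate, value.
#' @export
simulateTrialData <- function(nLines = 90L, sigma2_G = 1, sigma2_GE = 0.5,
                              sigma2_e = 1, nEnv = 2L, nRep = 5L, mu = 0,
                              seed) {
  set.seed(seed)
  lines_ <- sprintf("L%03d", seq_len(nLines))
  g <- stats::rnorm(nLines, 0, sqrt(sigma2_G))
  d <- expand.grid(replicate = seq_len(nRep), env = paste0("G", seq_len(nEnv)),
                   line = lines_, stringsAsFactors = FALSE)
  ge <- stats::rnorm(nLines * nEnv, 0, sqrt(sigma2_GE))
  names(ge) <- paste(rep(lines_, each = nEnv), rep(paste0("G", seq_len(nEnv)),
                                                   nLines))
  d$value <- mu + g[match(d$line, lines_)] +
    ge[paste(d$line, d$env)] +
    stats::rnorm(nrow(d), 0, sqrt(sigma2_e))
  d
}

#' Simulate a substitution-line population with planted QTL
#'
#' Generates a chromosome-segment substitution population: each line carries
#' a few donor segments on a recurrent-parent background; markers on a
#' regular grid are coded 0 (recurrent) / 1 (donor). Phenotypes for each
#' requested (trait, time_point) follow y = mu + QTL effects + polygenic G +
#' GxE + error with the requested variance components; planted QTL effects
#' are sized to hit their PVE target on the line-mean scale. Yield is a
#' linear function of the line means of designated trait/time-point cells
#' plus noise. Every planted effect is recorded in the truth ledger.
#'
#' @param nLines number of substitution lines (default 89).
#' @param parent recurrent parent id (all-0 genotype; control for Dunnett).
#' @param genome named chromosome lengths in bp.
#' @param markerSpacing marker grid spacing in bp.
#' @param meanSegments mean donor segments per line (Poisson, min 1).
#' @param meanSegLength mean segment length in bp.
#' @param traits data.frame: trait, time_point, mu, sigma2_G, sigma2_GE,
#'   sigma2_e (one phenotype cell per row).
#' @param qtls data.frame: trait, time_point, chrom, bp, pve (percent of
#'   line-mean variance). NULL for none.
#' @param nEnv environments (seasons G1, G2, ...), \code{nRep} replicates.
#' @param yieldSpec list(cells = character "trait_timepoint", r2) or NULL;
#'   yield = equal-weight combination of the named cells' line means scaled
#'   to the target R2.
#' @param seed integer seed.
#' @return list: genotypes (lines x markers 0/1), markers (marker, chrom,
#'   bp), segments (line, chrom, start, end), traits (long replicate-level
#'   table), yield (line, yield_g), truth (ledger list).
#' @export
simulatePopulation <- function(nLines = 89L, parent = "ZY821",
                               genome = defaultGenome(),
                               markerSpacing = 1e6, meanSegments = 3,
                               meanSegLength = 8e6,
                               traits = data.frame(trait = "TPA_SV",
                                                   time_point = 7L, mu = 10,
                                                   sigma2_G = 1,
                                                   sigma2_GE = 0.5,
                                                   sigma2_e = 4.1667),
                               qtls = NULL, nEnv = 2L, nRep = 5L,
                               yieldSpec = NULL, seed) {
  set.seed(seed)
  lines_ <- sprintf("ISL%03d", seq_len(nLines))
  chroms <- names(genome)
  # marker grid at mid-spacing offsets
  mk <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(markerSpacing / 2, genome[[ch]], by = markerSpacing)
    data.frame(marker = sprintf("%s_%04.0f", ch, pos / 1e6 * 10),
               chrom = ch, bp = pos)
  }))
  # donor segments
  segs <- do.call(rbind, lapply(lines_, function(l) {
    k <- max(1L, stats::rpois(1, meanSegments))
    ch <- sample(chroms, k, replace = TRUE, prob = genome / sum(genome))
    len <- pmax(1e6, stats::rgamma(k, shape = 2, scale = meanSegLength / 2))
    len <- pmin(len, genome[ch] * 0.8)
    start <- floor(stats::runif(k) * (genome[ch] - len)) + 1
    data.frame(line = l, chrom = ch, start = start, end = start + len - 1,
               donor = "donor")
  }))
  rownames(segs) <- NULL
  geno <- matrix(0L, nLines + 1L, nrow(mk),
                 dimnames = list(c(lines_, parent), mk$marker))
  for (i in seq_len(nrow(segs))) {
    hit <- mk$chrom == segs$chrom[i] & mk$bp >= segs$start[i] &
      mk$bp <= segs$end[i]
    geno[segs$line[i], hit] <- 1L
  }
  allLines <- c(lines_, parent)
  envs <- paste0("G", seq_len(nEnv))
  truth <- list(qtl = NULL, lineValues = list())
  traitRows <- list()
  lineMeanStore <- list()
  for (i in seq_len(nrow(traits))) {
    tr <- traits$trait[i]; tp <- traits$time_point[i]
    s2G <- traits$sigma2_G[i]; s2GE <- traits$sigma2_GE[i]
    s2E <- traits$sigma2_e[i]; mu <- traits$mu[i]
    vLineMean <- s2G + s2GE / nEnv + s2E / (nEnv * nRep)
    gq <- numeric(nLines + 1L)
    s2Gres <- s2G
    if (!is.null(qtls)) {
      qq <- qtls[qtls$trait == tr & qtls$time_point == tp, , drop = FALSE]
      for (j in seq_len(nrow(qq))) {
        # carrier indicator at the nearest marker
        onChr <- mk$chrom == qq$chrom[j]
        mIdx <- which(onChr)[which.min(abs(mk$bp[onChr] - qq$bp[j]))]
        x <- geno[, mIdx]
        f <- mean(x)
        if (f <= 0 || f >= 1)
          stop("planted QTL has no carriers (or all carriers)")
        vq <- qq$pve[j] / 100 * vLineMean
        if (vq >= s2G)
          stop("unachievable PVE target for planted QTL at ",
               qq$chrom[j], ":", qq$bp[j])
        a <- sqrt(vq / (f * (1 - f)))
        gq <- gq + a * x
        s2Gres <- s2Gres - vq
        truth$qtl <- rbind(truth$qtl, data.frame(
          trait = tr, time_point = tp, chrom = qq$chrom[j], bp = qq$bp[j],
          marker = mk$marker[mIdx], effect = a, pve = qq$pve[j],
          n_carriers = sum(x[seq_len(nLines)])))
      }
    }
    g <- gq + stats::rnorm(nLines + 1L, 0, sqrt(max(s2Gres, 0)))
    names(g) <- allLines
    ge <- matrix(stats::rnorm((nLines + 1L) * nEnv, 0, sqrt(s2GE)),
                 nLines + 1L, nEnv, dimnames = list(allLines, envs))
    d <- expand.grid(replicate = seq_len(nRep), env = envs, line = allLines,
                     stringsAsFactors = FALSE)
    d$value <- mu + g[d$line] + ge[cbind(d$line, d$env)] +
      stats::rnorm(nrow(d), 0, sqrt(s2E))
    traitRows[[i]] <- data.frame(line = d$line, replicate = d$replicate,
                                 season = d$env, time_point = tp, trait = tr,
                                 value = d$value)
    lm_ <- tapply(d$value, d$line, mean)
    lineMeanStore[[paste(tr, tp, sep = "_")]] <- lm_[allLines]
    truth$lineValues[[paste(tr, tp, sep = "_")]] <- mu + g
  }
  traitTable <- do.call(rbind, traitRows)
  yield <- NULL
  if (!is.null(yieldSpec)) {
    cells <- yieldSpec$cells
    miss <- setdiff(cells, names(lineMeanStore))
    if (length(miss)) stop("yield cells not simulated: ",
                           paste(miss, collapse = ", "))
    Z <- scale(do.call(cbind, lineMeanStore[cells]))
    signal <- rowMeans(Z)
    r2 <- yieldSpec$r2
    noise <- stats::rnorm(length(signal), 0,
                          stats::sd(signal) * sqrt((1 - r2) / r2))
    yg <- 50 + 10 * (signal + noise)       # grams per plant scale
    yield <- data.frame(line = allLines, yield_g = yg)
    truth$yield <- list(cells = cells, r2 = r2)
  }
  list(genotypes = geno, markers = mk, segments = segs, traits = traitTable,
       yield = yield, truth = truth)
}

#' Write a synthetic fixture directory
#'
#' Emits the standard pipeline input layout: images/ and masks/ (PNG),
#' manifest.csv, genotypes.csv, markers.csv and truth.json.
#'
#' @param dir output directory (created).
#' @param nScenes scenes per view.
#' @param population optional result of \code{\link{simulatePopulation}}.
#' @param seed integer seed.
#' @return the directory path, invisibly.
#' @export
writeFixtureDir <- function(dir, nScenes = 2L, population = NULL, seed) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  manifest <- list()
  truth <- list(scenes = list())
  for (v in c("side", "top")) for (i in seq_len(nScenes)) {
    sp <- sceneSpec(view = v, seed = seed + i + 1000L * (v == "top"))
    sc <- renderPlantScene(sp)
    id <- sprintf("%s_%02d", v, i)
    ip <- file.path(dir, "images", paste0(id, ".png"))
    mp <- file.path(dir, "masks", paste0(id, ".png"))
    writeFrame(sc$frame, ip)
    writeMask(sc$mask, mp)
    manifest[[id]] <- data.frame(
      line = sprintf("L%02d", i), replicate = 1L, season = "G1",
      time_point = 1L, view = v, frame_index = i,
      path = file.path("images", paste0(id, ".png")))
    truth$scenes[[id]] <- list(tpa = sum(framePixels(sc$mask)), seed = sp$seed)
  }
  utils::write.csv(do.call(rbind, manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(population)) {
    utils::write.csv(data.frame(line = rownames(population$genotypes),
                                population$genotypes, check.names = FALSE),
                     file.path(dir, "genotypes.csv"), row.names = FALSE)
    utils::write.csv(population$markers, file.path(dir, "markers.csv"),
                     row.names = FALSE)
    truth$qtl <- population$truth$qtl
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
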