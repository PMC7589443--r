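#' QTLScanResult: marker statistics and candidate QTL of one scan
#'
#' @slot markerStats data.frame: marker, chrom, bp, lod, pve, effect, n.
#' @slot records data.frame of candidate QTL peaks: marker, chrom, bp, lod,
#'   pve, effect, n_carriers.
#' @slot background character: cofactor markers selected for background
#'   control.
#' @slot lodThreshold numeric.
#' @exportClass QTLScanResult
setClass("QTLScanResult",
  representation(markerStats = "data.frame", records = "data.frame",
                 background = "character", lodThreshold = "numeric"))

setMethod("show", "QTLScanResult", function(object) {
  cat(sprintf("QTLScanResult: %d markers scanned, %d candidate QTL (LOD >= %g), %d background cofactor(s)\n",
              nrow(object@markerStats), nrow(object@records),
              object@lodThreshold, length(object@background)))
})

#' Accessors for QTLScanResult
#' @param x a \linkS4class{QTLScanResult}.
#' @return \code{qtlRecords}: the candidate-peak data.frame;
#'   \code{markerStats}: the full per-marker scan table.
#' @export
setGeneric("qtlRecords", function(x) standardGeneric("qtlRecords"))
#' @rdname qtlRecords
setMethod("qtlRecords", "QTLScanResult", function(x) x@records)
#' @rdname qtlRecords
#' @export
setGeneric("markerStats", function(x) standardGeneric("markerStats"))
#' @rdname qtlRecords
setMethod("markerStats", "QTLScanResult", function(x) x@markerStats)

# forward-only cofactor selection by partial F (entry p, capped)
.selectBackground <- function(X, y, pEnter = 0.01, cap = 5L) {
  n <- length(y)
  sel <- character(0)
  repeat {
    if (length(sel) >= cap) break
    cand <- setdiff(colnames(X), sel)
    if (!length(cand)) break
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    ry <- y - Q %*% crossprod(Q, y)
    Xc <- X[, cand, drop = FALSE]
    Rc <- Xc - Q %*% crossprod(Q, Xc)
    nres <- colSums(Rc^2)
    keep <- nres / pmax(colSums(Xc^2), .Machine$double.eps) > 1e-10
    if (!any(keep)) break
    cn <- cand[keep]; Rc <- Rc[, keep, drop = FALSE]; nres <- nres[keep]
    ssr <- drop(crossprod(Rc, ry))^2 / nres
    df2 <- n - length(sel) - 2
    if (df2 <= 0) break
    Fv <- ssr * df2 / pmax(sum(ry^2) - ssr, .Machine$double.eps)
    pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
    ord <- order(pv, cn)
    if (pv[ord[1]] > pEnter) break
    sel <- c(sel, cn[ord[1]])
  }
  sel
}

#' Chromosome-segment QTL scan with stepwise background control
#'
#' Two-stage regression mapping in the spirit of stepwise-cofactor
#' likelihood-ratio scans for substitution lines: stage 1 selects up to
#' \code{bgMax} background cofactor markers by forward partial-F selection
#' (entry p \code{bgPEnter}); stage 2 tests every marker with a single-marker
#' additive model, controlling for the selected cofactors except those within
#' \code{exclusionMb} of the test marker on the same chromosome. Per marker,
#' LRT = n ln(RSS0/RSS1), LOD = LRT / (2 ln 10), and
#' PVE = 100 (RSS0 - RSS1)/TSS. Candidate QTL are the LOD peaks of
#' contiguous significant marker runs.
#'
#' @param geno lines x markers matrix of codes (0 = recurrent parent,
#'   1 = donor; NA allowed), with dimnames.
#' @param map data.frame: marker, chrom, bp (1-based physical positions).
#' @param pheno named numeric vector of line means (names match geno rows).
#' @param lodThreshold LOD retention threshold (default 2.5).
#' @param bgPEnter,bgMax background-selection entry p and cofactor cap.
#' @param exclusionMb cofactors closer than this to the test marker are
#'   dropped from its null model.
#' @return a \linkS4class{QTLScanResult}.
#' @export
qtlScan <- function(geno, map, pheno, lodThreshold = 2.5,
                    bgPEnter = 0.01, bgMax = 5L, exclusionMb = 5) {
  stopifnot(!is.null(rownames(geno)), !is.null(colnames(geno)))
  lines_ <- intersect(rownames(geno), names(pheno))
  if (length(lines_) < 30) stop("need at least 30 lines")
  G <- geno[lines_, , drop = FALSE]
  y <- as.vector(pheno[lines_])   # tolerate 1-d arrays (e.g. tapply output)
  map <- map[match(colnames(G), map$marker), ]
  # screen monomorphic markers (among non-missing codes)
  poly <- apply(G, 2, function(g) {
    g <- g[!is.na(g)]; length(unique(g)) > 1
  })
  G <- G[, poly, drop = FALSE]
  map <- map[poly, , drop = FALSE]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  # background on mean-imputed genotypes (stage 1 only)
  Gi <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE); g
  })
  bg <- .selectBackground(Gi, y, bgPEnter, bgMax)
  bgMap <- map[match(bg, map$marker), ]
  stats_ <- lapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    ok <- !is.na(x)
    keepBg <- bg[!(bgMap$chrom == map$chrom[j] &
                   abs(bgMap$bp - map$bp[j]) <= exclusionMb * 1e6)]
    X0 <- cbind(1, Gi[ok, keepBg, drop = FALSE])
    q0 <- qr(X0)
    # drop collinear background columns
    if (q0$rank < ncol(X0)) {
      keep <- q0$pivot[seq_len(q0$rank)]
      X0 <- X0[, keep, drop = FALSE]
      q0 <- qr(X0)
    }
    r0 <- qr.resid(q0, y[ok])
    rss0 <- sum(r0^2)
    X1 <- cbind(X0, x = x[ok])
    q1 <- qr(X1)
    if (q1$rank < ncol(X1))       # marker collinear with background
      return(c(lod = 0, pve = 0, effect = NA_real_, n = sum(ok)))
    cf <- qr.coef(q1, y[ok])
    rss1 <- sum(qr.resid(q1, y[ok])^2)
    nOk <- sum(ok)
    lrt <- nOk * log(max(rss0, .Machine$double.xmin) /
                       max(rss1, .Machine$double.xmin))
    c(lod = lrt / (2 * log(10)),
      pve = 100 * (rss0 - rss1) / tss,
      effect = unname(cf["x"]), n = nOk)
  })
  ms <- data.frame(marker = map$marker, chrom = map$chrom, bp = map$bp,
                   do.call(rbind, stats_))
  # peaks: contiguous runs of significant markers per chromosome
  recs <- list()
  for (ch in unique(ms$chrom)) {
    sub <- ms[ms$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    sig <- sub$lod >= lodThreshold
    if (!any(sig)) next
    runId <- cumsum(c(1L, diff(sig) != 0))
    for (g in unique(runId[sig])) {
      run <- sub[runId == g & sig, ]
      peak <- run[which.max(run$lod), ]
      nc <- sum(G[, peak$marker] == 1, na.rm = TRUE)
      recs[[length(recs) + 1L]] <- cbind(peak, n_carriers = nc)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else ms[0, ]
  new("QTLScanResult", markerStats = ms, records = records,
      background = bg, lodThreshold = lodThreshold)
}

#' Dunnett many-to-one validation of a candidate QTL
#'
#' Compares each carrier line against the recurrent-parent control with
#' replicate-level phenotypes: two-sided t statistics on the pooled
#' within-group variance, adjusted for multiplicity by seeded Monte-Carlo
#' integration of the joint multivariate t distribution of the comparisons
#' (Monte-Carlo SE about 0.001-0.002 at the default 100,000 draws). The QTL
#' is validated iff at least one carrier differs from the control at
#' \code{alpha}.
#'
#' @param pheno data.frame with columns line, value (replicate level).
#' @param carriers character vector of carrier line ids.
#' @param control control line id (recurrent parent).
#' @param alpha familywise significance level.
#' @param nDraws Monte-Carlo draws.
#' @param seed integer seed (mandatory).
#' @return list: validated, p_adj (named per carrier), t (statistics), df.
#' @export
dunnettValidate <- function(pheno, carriers, control, alpha = 0.05,
                            nDraws = 1e5, seed) {
  g0 <- pheno$value[pheno$line == control]
  if (length(g0) < 2) stop("control needs at least 2 replicates")
  carriers <- intersect(carriers, unique(pheno$line))
  carriers <- setdiff(carriers, control)
  if (!length(carriers)) stop("no carrier lines with phenotypes")
  groups <- lapply(carriers, function(l) pheno$value[pheno$line == l])
  ns <- vapply(groups, length, 0L)
  if (any(ns < 1)) stop("carrier without replicates")
  allv <- c(list(g0), groups)
  df <- sum(vapply(allv, length, 0L)) - length(allv)
  s2 <- sum(vapply(allv, function(v) sum((v - mean(v))^2), 0)) / df
  if (s2 <= 0) stop("zero within-group variance")
  n0 <- length(g0)
  means <- vapply(groups, mean, 0)
  tstat <- (means - mean(g0)) / sqrt(s2 * (1 / ns + 1 / n0))
  lam <- ns / (ns + n0)
  k <- length(carriers)
  set.seed(seed)
  Z0 <- stats::rnorm(nDraws)
  S <- sqrt(stats::rchisq(nDraws, df) / df)
  Tmax <- rep(0, nDraws)
  for (j in seq_len(k)) {
    Tj <- abs(sqrt(lam[j]) * Z0 + sqrt(1 - lam[j]) * stats::rnorm(nDraws)) / S
    Tmax <- pmax(Tmax, Tj)
  }
  p_adj <- vapply(abs(tstat), function(tv) mean(Tmax >= tv), 0)
  names(p_adj) <- carriers
  list(validated = any(p_adj <= alpha), p_adj = p_adj,
       t = stats::setNames(tstat, carriers), df = df)
}

#' Physical interval of a validated QTL
#'
#' The interval is the intersection of the significant carriers' substituted
#' segments that contain the peak marker; with a single significant carrier
#' it is that carrier's segment. An empty intersection (possible only with
#' inconsistent segment data) falls back to the widest supporting segment,
#' flagged.
#'
#' @param peakChrom,peakBp peak marker position.
#' @param sigCarriers character vector of significant carrier lines.
#' @param segments data.frame: line, chrom, start, end (1-based inclusive bp).
#' @return list: chrom, start, end, carriers, flagged.
#' @export
defineInterval <- function(peakChrom, peakBp, sigCarriers, segments) {
  seg <- segments[segments$line %in% sigCarriers &
                  segments$chrom == peakChrom &
                  segments$start <= peakBp & segments$end >= peakBp, ]
  if (!nrow(seg)) stop("no carrier segment contains the peak marker")
  s <- max(seg$start); e <- min(seg$end)
  if (s > e) {           # defensive: inconsistent segments
    w <- which.max(seg$end - seg$start)
    return(list(chrom = peakChrom, start = seg$start[w], end = seg$end[w],
                carriers = unique(seg$line), flagged = TRUE))
  }
  list(chrom = peakChrom, start = s, end = e,
       carriers = unique(seg$line), flagged = FALSE)
}

#' Merge overlapping QTL intervals into nonredundant groups
#'
#' Transitive closure of pairwise interval overlap within each chromosome;
#' the group interval is the union span. Idempotent and order-invariant.
#'
#' @param records data.frame with columns chrom, start, end (1-based
#'   inclusive; additional columns preserved).
#' @return list: \code{records} (input plus a \code{group} id column) and
#'   \code{groups} (data.frame group, chrom, start, end, n_qtl).
#' @export
mergeNonredundant <- function(records) {
  if (!nrow(records)) {
    return(list(records = cbind(records, group = integer(0)),
                groups = data.frame(group = integer(0), chrom = character(0),
                                    start = numeric(0), end = numeric(0),
                                    n_qtl = integer(0))))
  }
  records$group <- NA_integer_
  gid <- 0L
  groups <- list()
  for (ch in sort(unique(records$chrom))) {
    ri <- which(records$chrom == ch)
    ord <- ri[order(records$start[ri], records$end[ri])]
    curEnd <- -Inf; curStart <- NA_real_
    for (i in ord) {
      if (records$start[i] > curEnd) {       # start a new group
        gid <- gid + 1L
        curStart <- records$start[i]; curEnd <- records$end[i]
        groups[[gid]] <- list(chrom = ch, start = curStart, end = curEnd,
                              n = 0L)
      } else {
        curEnd <- max(curEnd, records$end[i])
        groups[[gid]]$end <- curEnd
      }
      records$group[i] <- gid
      groups[[gid]]$n <- groups[[gid]]$n + 1L
    }
  }
  gdf <- data.frame(group = seq_along(groups),
                    chrom = vapply(groups, `[[`, "", "chrom"),
                    start = vapply(groups, `[[`, 0, "start"),
                    end = vapply(groups, `[[`, 0, "end"),
                    n_qtl = vapply(groups, `[[`, 0L, "n"))
  list(records = records, groups = gdf)
}

#' Permutation test for QTL hotspots in 1-Mb windows
#'
#' The observed statistic is the QTL count per 1-Mb window (a QTL is counted
#' in every window its interval overlaps). The null redistributes the same
#' intervals uniformly and independently across the genome (chromosome chosen
#' with probability proportional to the number of valid start positions).
#' The count threshold is the smallest c such that the null probability of
#' any window reaching c is at most \code{alpha}; observed windows at or
#' above it are hotspots.
#'
#' @param records data.frame with chrom, start, end.
#' @param genomeSizes named numeric vector: chromosome lengths in bp.
#' @param windowBp window size (default 1 Mb).
#' @param nPerm permutations (paper protocol: 10000).
#' @param alpha significance level (paper protocol: 0.01).
#' @param seed integer seed (mandatory).
#' @return list: windows (data.frame chrom, window, start, end, count,
#'   hotspot), threshold, alpha, n_perm, max_null (permutation maxima).
#' @export
hotspotPermutation <- function(records, genomeSizes, windowBp = 1e6,
                               nPerm = 10000, alpha = 0.01, seed) {
  if (!nrow(records)) stop("no QTL records")
  if (any(genomeSizes <= 0)) stop("genome sizes must be positive")
  if (nPerm < 100) warning("fewer than 100 permutations: threshold unstable")
  chroms <- names(genomeSizes)
  nwin <- ceiling(genomeSizes / windowBp)
  off <- stats::setNames(c(0, cumsum(nwin))[seq_along(chroms)], chroms)
  W <- sum(nwin)
  winOf <- function(chrom, s, e) {
    w1 <- (s - 1) %/% windowBp + 1
    w2 <- pmin((e - 1) %/% windowBp + 1, nwin[chrom])
    list(w1 = off[chrom] + w1, w2 = off[chrom] + w2)
  }
  countWindows <- function(w1, w2) {
    d <- numeric(W + 1L)
    inc <- tabulate(w1, nbins = W + 1L)
    dec <- tabulate(w2 + 1L, nbins = W + 1L)
    cumsum(inc - dec)[seq_len(W)]
  }
  obsW <- winOf(records$chrom, records$start, records$end)
  obs <- countWindows(obsW$w1, obsW$w2)
  len <- records$end - records$start + 1
  set.seed(seed)
  maxNull <- vapply(seq_len(nPerm), function(p) {
    ci <- vapply(len, function(l) {
      valid <- pmax(genomeSizes - l + 1, 0)
      if (all(valid == 0)) valid <- genomeSizes  # interval longer than genome
      sample.int(length(chroms), 1L, prob = valid)
    }, 0L)
    smax <- pmax(genomeSizes[ci] - len + 1, 1)
    s <- floor(stats::runif(length(len)) * smax) + 1
    pw <- winOf(chroms[ci], s, pmin(s + len - 1, genomeSizes[ci]))
    max(countWindows(pw$w1, pw$w2))
  }, 0)
  cand <- seq_len(max(maxNull) + 1L)
  exceed <- vapply(cand, function(cc) mean(maxNull >= cc), 0)
  thr <- cand[which(exceed <= alpha)[1]]
  glob <- seq_len(W)
  chromIdx <- rep(seq_along(chroms), nwin)
  winIdx <- glob - off[chromIdx]
  windows <- data.frame(
    chrom = chroms[chromIdx], window = winIdx,
    start = (winIdx - 1) * windowBp + 1,
    end = pmin(winIdx * windowBp, genomeSizes[chromIdx]),
    count = obs, hotspot = obs >= thr)
  list(windows = windows, threshold = thr, alpha = alpha, n_perm = nPerm,
       max_null = maxNull)
}
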