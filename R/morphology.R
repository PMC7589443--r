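# Geometry conventions (documented in the methods vignette):
#  - areas (TPA, HA and ratios built from them) live on the pixel-square
#    basis: the convex hull is taken over the 4 corner points of every
#    foreground pixel, so HA >= TPA and AC, PC1, PC2 <= 1 hold exactly;
#  - perimeters (P, P_hull) live on the pixel-centre basis: P is the Moore
#    boundary walk through pixel centres (diagonal steps weigh sqrt(2)),
#    P_hull the perimeter of the convex hull of the centres, so
#    PC3 = P_hull / P <= 1 holds exactly;
#  - D_max (maximum Feret diameter) uses the corner-point hull.

# Moore-neighbour outer-contour trace of one component, pixel centres.
# Returns total walk length; single pixel = 1 by convention.
.dirR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)  # N NE E SE S SW W NW
.dirC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

.traceContour <- function(lab, id) {
  nr <- nrow(lab); nc <- ncol(lab)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc
  fg <- function(r, c) inside(r, c) && lab[r, c] == id
  idx <- which(lab == id)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  if (length(idx) == 1L) return(1)            # degenerate: lone pixel
  # start: topmost row, then leftmost column (row-major scan order)
  r0 <- min(rr); c0 <- min(cc[rr == r0])
  # backtrack: pixel to the left of the start (background by construction);
  # the deterministic walk eventually cycles through its (pixel, backtrack)
  # states: the contour length is the length of that cycle
  pr <- r0; pc <- c0; bdir <- 7L               # backtrack index: W
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cum <- 0
  assign(paste(pr, pc, bdir), cum, envir = seen)
  maxSteps <- 16L * length(idx) + 16L
  for (step in seq_len(maxSteps)) {
    found <- FALSE
    for (j in 1:8) {
      d <- ((bdir - 1L + j - 1L) %% 8L) + 1L   # clockwise from backtrack
      qr <- pr + .dirR[d]; qc <- pc + .dirC[d]
      if (fg(qr, qc)) {
        cum <- cum + sqrt(sum(c(qr - pr, qc - pc)^2))
        # new backtrack direction: from q towards the cell examined before q
        prevd <- ((d - 2L) %% 8L) + 1L
        br <- pr + .dirR[prevd]; bc <- pc + .dirC[prevd]
        pr <- qr; pc <- qc
        delta <- c(br - pr, bc - pc)
        bdir <- which(.dirR == delta[1] & .dirC == delta[2])[1]
        found <- TRUE
        break
      }
    }
    if (!found) return(1)                      # isolated (cannot happen for >1 px)
    key <- paste(pr, pc, bdir)
    if (!is.null(prev <- seen[[key]])) return(cum - prev)
    assign(key, cum, envir = seen)
  }
  stop("contour trace failed to cycle")        # unreachable for valid masks
}

# shoelace area of polygon given as two-column matrix of vertices
.polyArea <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.polyPerim <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(0)
  if (n == 2L) return(2 * sqrt(sum((p[1, ] - p[2, ])^2)))
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

#' Morphological i-traits of a plant mask
#'
#' Computes the area, extent, hull and shape descriptors used throughout the
#' pipeline: TPA (total projected area, foreground pixel count), H and W
#' (bounding-box height/width), HWR = H/W, HA (convex-hull area over pixel
#' corners), PAR = P/TPA with P the outer-contour perimeter, roundness
#' R = 4*pi*TPA/P^2, AC = HA/(H*W), and the compactness family
#' PC1 = TPA/HA (solidity), PC2 = TPA/(H*W) (extent), PC3 = P_hull/P
#' (convexity), PC4 = 4*pi*TPA/P_hull^2, PC5 = equivalent-circle diameter /
#' maximum Feret diameter, PC6 = TPA / area of the Feret-diameter circle.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return named numeric vector with elements TPA, H, W, HWR, HA, PAR, R,
#'   AC, PC1..PC6 (all NA for an empty mask).
#' @examples
#' m <- matrix(FALSE, 60, 60); m[11:50, 21:40] <- TRUE
#' morphologicalTraits(BinaryMask(m, "side"))[c("TPA", "HWR", "PC1")]
#' @export
morphologicalTraits <- function(mask) {
  nm <- c("TPA", "H", "W", "HWR", "HA", "PAR", "R", "AC", paste0("PC", 1:6))
  px <- framePixels(mask)
  if (!any(px)) {
    warning("empty mask: morphological traits reported as missing",
            call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  idx <- which(px)
  nr <- nrow(px)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  tpa <- length(idx)
  H <- diff(range(r)) + 1L
  W <- diff(range(c)) + 1L
  # hull over pixel corners (x = col, y = row)
  corners <- cbind(c(c - 0.5, c - 0.5, c + 0.5, c + 0.5),
                   c(r - 0.5, r + 0.5, r - 0.5, r + 0.5))
  corners <- unique(corners)
  hidx <- grDevices::chull(corners)
  hullC <- corners[hidx, , drop = FALSE]
  HA <- .polyArea(hullC)
  # hull over pixel centres for the perimeter ratio
  centres <- unique(cbind(c, r))
  if (nrow(centres) >= 3L) {
    hullP <- .polyPerim(centres[grDevices::chull(centres), , drop = FALSE])
  } else hullP <- .polyPerim(centres)
  # outer-contour perimeter: sum of Moore walks over components
  lab <- .labelComponents(px)
  P <- sum(vapply(seq_len(max(lab)), function(i) .traceContour(lab, i), 0))
  # maximum Feret diameter from corner-hull vertices
  dmax <- max(stats::dist(hullC))
  out <- c(TPA = tpa, H = as.numeric(H), W = as.numeric(W), HWR = H / W,
           HA = HA, PAR = P / tpa, R = 4 * pi * tpa / P^2, AC = HA / (H * W),
           PC1 = tpa / HA, PC2 = tpa / (H * W), PC3 = hullP / P,
           PC4 = 4 * pi * tpa / hullP^2,
           PC5 = sqrt(4 * tpa / pi) / dmax,
           PC6 = tpa / (pi * (dmax / 2)^2))
  out[nm]
}

#' Box-counting fractal dimension of a mask
#'
#' Counts occupied boxes N(s) for dyadic box sizes s = 1, 2, 4, ... up to
#' half the (power-of-two padded) side, and reports minus the slope of the
#' least-squares fit of log N(s) on log s. With \code{cropped = TRUE} the
#' mask is first restricted to its bounding box (FDIC); otherwise the full
#' frame is used (FDNIC), so padding changes with plant position.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param cropped logical: crop to the bounding box first?
#' @return scalar dimension estimate, or NA when fewer than 3 scales are
#'   usable.
#' @examples
#' m <- matrix(TRUE, 64, 64)
#' fractalDimension(BinaryMask(m, "top"))  # ~2
#' @export
fractalDimension <- function(mask, cropped = TRUE) {
  px <- framePixels(mask)
  if (!any(px)) {
    warning("empty mask: fractal dimension is missing", call. = FALSE)
    return(NA_real_)
  }
  idx <- which(px)
  nr <- nrow(px)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  if (cropped) {
    r <- r - min(r) + 1L
    c <- c - min(c) + 1L
    ext <- max(max(r), max(c))
  } else {
    ext <- max(dim(px))
  }
  side <- 2^ceiling(log2(ext))
  ks <- 0:(log2(side) - 1)                 # box sizes 1 .. side/2
  if (length(ks) < 3L) {
    warning("mask too small for a box-counting fit", call. = FALSE)
    return(NA_real_)
  }
  n <- vapply(ks, function(k) {
    s <- 2^k
    length(unique((r - 1L) %/% s * (side / s) + (c - 1L) %/% s))
  }, 0)
  ls <- ks * log(2)
  -sum((ls - mean(ls)) * (log(n) - mean(log(n)))) / sum((ls - mean(ls))^2)
}
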