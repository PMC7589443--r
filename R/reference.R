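# Naive reference implementations of the i-trait definitions.
#
# These deliberately share no helpers with the production trait code: hulls
# are gift-wrapped, components flood-filled, contours walked with a separate
# Moore tracer written on complex coordinates, histograms accumulated in
# explicit loops. They define the ground truth attached to rendered scenes
# and serve as the equivalence oracle in the test-suite. Same definitions,
# naive algorithms.

# flood-fill 8-connected labelling (queue-based)
refLabelComponents <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!px[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            px[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# gift-wrapping (Jarvis march) convex hull; pts is a 2-col matrix (x, y)
refConvexHull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  start <- order(pts[, 1], pts[, 2])[1]   # lowest x, ties by y
  hull <- integer(0)
  p <- start
  for (guard in seq_len(n + 1L)) {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (q == p || cr < 0 ||
          (cr == 0 && sum((pts[r, ] - pts[p, ])^2) >
                      sum((pts[q, ] - pts[p, ])^2)))
        q <- r
    }
    p <- q
    if (p == start) break
  }
  pts[hull, , drop = FALSE]
}

refPolyArea <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

refPolyPerim <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(0)
  if (n == 2L) return(2 * sqrt(sum((p[1, ] - p[2, ])^2)))
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + sqrt(sum((p[i, ] - p[j, ])^2))
  }
  s
}

# Moore outer-contour walk on complex coordinates (col + row * 1i)
refContourLength <- function(lab, id) {
  cells <- which(lab == id, arr.ind = TRUE)
  if (nrow(cells) == 1L) return(1)
  zset <- complex(real = cells[, 2], imaginary = cells[, 1])
  inSet <- function(z) any(abs(zset - z) < 1e-9)
  dirs <- complex(real = c(0, 1, 1, 1, 0, -1, -1, -1),
                  imaginary = c(-1, -1, 0, 1, 1, 1, 0, -1))  # N NE E SE S SW W NW
  r0 <- min(cells[, 1])
  c0 <- min(cells[cells[, 1] == r0, 2])
  s <- complex(real = c0, imaginary = r0)
  p <- s; bdir <- 7L                              # backtrack: west
  # the deterministic walk cycles in (pixel, backtrack) state space; the
  # contour length is the cycle length
  states <- paste(Re(p), Im(p), bdir)
  lens <- 0
  perim <- 0
  nmax <- 16L * nrow(cells) + 16L
  for (step in seq_len(nmax)) {
    moved <- FALSE
    for (j in 1:8) {
      d <- ((bdir - 1L + j - 1L) %% 8L) + 1L
      q <- p + dirs[d]
      if (inSet(q)) {
        perim <- perim + Mod(q - p)
        prevd <- ((d - 2L) %% 8L) + 1L
        bpt <- p + dirs[prevd]
        p <- q
        bdir <- which(abs(dirs - (bpt - p)) < 1e-9)[1]
        moved <- TRUE
        break
      }
    }
    if (!moved) return(1)
    key <- paste(Re(p), Im(p), bdir)
    hit <- match(key, states)
    if (!is.na(hit)) return(perim - lens[hit])
    states <- c(states, key)
    lens <- c(lens, perim)
  }
  stop("reference contour trace failed to cycle")
}

#' Naive reference i-traits of a frame/mask pair
#'
#' Computes the same trait definitions as \code{\link{maskTraits}} by
#' deliberately independent naive algorithms (gift-wrapped hulls, flood-fill
#' components, loop-accumulated histograms). Used as ground truth for
#' rendered scenes and as the equivalence oracle.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @param mask a \linkS4class{BinaryMask}.
#' @param config a \linkS4class{SegmentationConfig} (hue range for GPA).
#' @return named numeric vector matching \code{\link{maskTraits}} names.
#' @export
referenceTraits <- function(frame, mask, config = SegmentationConfig()) {
  px <- framePixels(mask)
  img <- framePixels(frame)
  side <- frameView(frame) == "side"
  cells <- which(px, arr.ind = TRUE)
  tpa <- nrow(cells)
  stopifnot(tpa > 0)
  r <- cells[, 1]; c <- cells[, 2]
  H <- max(r) - min(r) + 1; W <- max(c) - min(c) + 1
  # hull area over pixel corners; restrict to boundary pixels (same hull)
  onBorder <- vapply(seq_len(tpa), function(i) {
    rr <- r[i]; cc <- c[i]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- rr + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nrow(px) || c2 < 1 || c2 > ncol(px) || !px[r2, c2])
        return(TRUE)
    }
    FALSE
  }, TRUE)
  rb <- r[onBorder]; cb <- c[onBorder]
  corners <- unique(cbind(c(cb - .5, cb - .5, cb + .5, cb + .5),
                          c(rb - .5, rb + .5, rb - .5, rb + .5)))
  hullC <- refConvexHull(corners)
  HA <- refPolyArea(hullC)
  centres <- unique(cbind(c, r))
  hullP <- refPolyPerim(refConvexHull(centres))
  lab <- refLabelComponents(px)
  P <- 0
  for (i in seq_len(max(lab))) P <- P + refContourLength(lab, i)
  dmax <- 0
  for (i in seq_len(nrow(hullC))) for (j in seq_len(nrow(hullC)))
    dmax <- max(dmax, sqrt(sum((hullC[i, ] - hullC[j, ])^2)))
  morph <- c(TPA = tpa, H = H, W = W, HWR = H / W, HA = HA, PAR = P / tpa,
             R = 4 * pi * tpa / P^2, AC = HA / (H * W), PC1 = tpa / HA,
             PC2 = tpa / (H * W), PC3 = hullP / P,
             PC4 = 4 * pi * tpa / hullP^2, PC5 = sqrt(4 * tpa / pi) / dmax,
             PC6 = tpa / (pi * (dmax / 2)^2))
  # histogram texture on the masked intensity channel
  grey <- integer(tpa)
  for (i in seq_len(tpa))
    grey[i] <- round((as.numeric(img[r[i], c[i], 1]) + img[r[i], c[i], 2] +
                        img[r[i], c[i], 3]) / 3)
  p_ <- numeric(256)
  for (v in grey) p_[v + 1] <- p_[v + 1] + 1
  p_ <- p_ / tpa
  z <- (0:255) / 255
  m <- 0; for (i in 1:256) m <- m + z[i] * p_[i]
  v2 <- 0; v3 <- 0; u <- 0; e <- 0
  for (i in 1:256) {
    v2 <- v2 + (z[i] - m)^2 * p_[i]
    v3 <- v3 + (z[i] - m)^3 * p_[i]
    u <- u + p_[i]^2
    if (p_[i] > 0) e <- e - p_[i] * log2(p_[i])
  }
  tex <- c(M_TEX = m, SE_TEX = sqrt(v2), S_TEX = 1 - 1 / (1 + v2),
           MU3_TEX = v3, U_TEX = u, E_TEX = e)
  # colour traits
  gpa <- 0; gsum <- 0
  for (i in seq_len(tpa)) {
    R_ <- as.numeric(img[r[i], c[i], 1]); G_ <- img[r[i], c[i], 2]
    B_ <- img[r[i], c[i], 3]
    sm <- R_ + G_ + B_
    if (sm == 0 || min(R_, G_, B_) * 3 == sm) {
      hdeg <- 0
    } else {
      ct <- ((R_ - G_) + (R_ - B_)) / 2 /
        sqrt((R_ - G_)^2 + (R_ - B_) * (G_ - B_))
      ct <- min(1, max(-1, ct))
      hdeg <- acos(ct) * 180 / pi
      if (B_ > G_) hdeg <- 360 - hdeg
      if (hdeg >= 360) hdeg <- 0
    }
    if (hdeg >= config@hueRange[1] && hdeg <= config@hueRange[2])
      gpa <- gpa + 1
    gsum <- gsum + if (sm == 0) 1 / 3 else G_ / sm
  }
  col <- c(GPA = gpa, GCV = gsum / tpa)
  fd <- c(FDIC = refBoxCount(px, cropped = TRUE),
          FDNIC = refBoxCount(px, cropped = FALSE))
  v <- c(morph, tex, col, fd)
  nm <- sub("_(SV|TV)$", "", if (side) sideTraitNames() else topTraitNames())
  v[nm]
}

# naive box-counting dimension
refBoxCount <- function(px, cropped) {
  cells <- which(px, arr.ind = TRUE)
  r <- cells[, 1]; c <- cells[, 2]
  if (cropped) {
    r <- r - min(r) + 1; c <- c - min(c) + 1
    ext <- max(r, c)
  } else ext <- max(dim(px))
  side <- 2^ceiling(log2(ext))
  if (side < 8) return(NA_real_)
  ks <- 0:(log2(side) - 1)
  logN <- numeric(length(ks)); logS <- numeric(length(ks))
  for (i in seq_along(ks)) {
    s <- 2^ks[i]
    boxes <- character(0)
    for (j in seq_along(r))
      boxes <- c(boxes, paste((r[j] - 1) %/% s, (c[j] - 1) %/% s))
    logN[i] <- log(length(unique(boxes)))
    logS[i] <- log(s)
  }
  f <- stats::lm(logN ~ logS)
  -unname(stats::coef(f)[2])
}
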