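#' Specification of a synthetic imaging-chamber scene
#'
#' Describes a deterministic plant scene: a stem and a set of elliptical
#' leaves in vegetation green on a blue chamber background, with an optional
#' grey conveyor band at the bottom (side view). The renderer is a pure
#' function of the spec (including its mandatory seed).
#'
#' @param view "side" or "top".
#' @param canvas c(rows, cols), default 512 x 512.
#' @param centreCol horizontal plant centre (px).
#' @param stemHeight stem height in px (side view).
#' @param stemWidth stem width in px.
#' @param leafCount number of leaves.
#' @param leafAxes c(major, minor) leaf ellipse semi-axes in px.
#' @param leafHueJitter per-leaf jitter of the green tone (0..1 scale of the
#'   default channel offsets).
#' @param bgColour background RGB (blue imaging chamber).
#' @param conveyorRows number of bottom rows covered by the conveyor band
#'   (side view only; 0 for none).
#' @param conveyorColour conveyor RGB.
#' @param noiseSD Gaussian pixel noise SD added to every channel (8-bit).
#' @param seed mandatory RNG seed.
#' @return a list with class "sceneSpec".
#' @export
sceneSpec <- function(view = c("side", "top"), canvas = c(512L, 512L),
                      centreCol = round(canvas[2] / 2), stemHeight = 180L,
                      stemWidth = 8L, leafCount = 6L, leafAxes = c(70, 28),
                      leafHueJitter = 0.3, bgColour = c(90L, 110L, 170L),
                      conveyorRows = if (match.arg(view) == "side") 40L else 0L,
                      conveyorColour = c(120L, 120L, 125L), noiseSD = 2,
                      seed) {
  view <- match.arg(view)
  if (missing(seed)) stop("seed is mandatory for scene rendering")
  structure(list(view = view, canvas = as.integer(canvas),
                 centreCol = centreCol, stemHeight = as.integer(stemHeight),
                 stemWidth = as.integer(stemWidth),
                 leafCount = as.integer(leafCount), leafAxes = leafAxes,
                 leafHueJitter = leafHueJitter, bgColour = bgColour,
                 conveyorRows = as.integer(conveyorRows),
                 conveyorColour = conveyorColour, noiseSD = noiseSD,
                 seed = as.integer(seed)),
            class = "sceneSpec")
}

# fill a rotated ellipse into logical matrix m; returns updated m
.fillEllipse <- function(m, r0, c0, a, b, theta) {
  nr <- nrow(m); nc <- ncol(m)
  ext <- ceiling(max(a, b))
  rs <- max(1, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  dr <- outer(rs - r0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - c0)
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  m[rs, cs] <- m[rs, cs] | hit
  m
}

#' Render a synthetic plant scene with ground truth
#'
#' Deterministically paints the scene described by a \code{\link{sceneSpec}}
#' and returns the frame together with the exact truth mask (the set of
#' painted plant pixels) and, optionally, the truth trait vector computed by
#' the naive reference implementations (\code{\link{referenceTraits}}).
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @param computeTraits also compute the reference truth traits (slower)?
#' @param config segmentation config used only for the truth GPA hue gate.
#' @return list: frame (\linkS4class{RGBFrame}), mask (truth
#'   \linkS4class{BinaryMask}), conveyor (logical matrix of conveyor pixels),
#'   cropConfig (a \linkS4class{SegmentationConfig} whose crop removes the
#'   conveyor band), truth (named trait vector or NULL).
#' @export
renderPlantScene <- function(spec, computeTraits = FALSE,
                             config = SegmentationConfig()) {
  stopifnot(inherits(spec, "sceneSpec"))
  set.seed(spec$seed)
  nr <- spec$canvas[1]; nc <- spec$canvas[2]
  px <- array(0, c(nr, nc, 3))
  for (ch in 1:3) px[, , ch] <- spec$bgColour[ch]
  conveyor <- matrix(FALSE, nr, nc)
  if (spec$conveyorRows > 0) {
    rows <- (nr - spec$conveyorRows + 1):nr
    conveyor[rows, ] <- TRUE
    for (ch in 1:3) px[rows, , ch] <- spec$conveyorColour[ch]
  }
  plantTop <- nr - spec$conveyorRows
  mask <- matrix(FALSE, nr, nc)
  leafColour <- function() {
    # vegetation green with per-leaf jitter; stays inside the HSI/EG gates
    j <- spec$leafHueJitter
    base <- c(50, 160, 55)
    off <- round(c(stats::runif(1, -25, 25), stats::runif(1, -30, 35),
                   stats::runif(1, -20, 20)) * j)
    pmin(pmax(base + off, 10), 235)
  }
  paint <- function(px, m, colr) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- colr[ch]
      px[, , ch] <- plane
    }
    px
  }
  if (spec$view == "side") {
    stemRows <- max(1, plantTop - spec$stemHeight + 1):plantTop
    half <- max(1L, spec$stemWidth %/% 2L)
    stemCols <- max(1, spec$centreCol - half):min(nc, spec$centreCol + half)
    stem <- matrix(FALSE, nr, nc)
    stem[stemRows, stemCols] <- TRUE
    px <- paint(px, stem & !mask, c(60, 150, 60))
    mask <- mask | stem
    if (spec$leafCount > 0) for (i in seq_len(spec$leafCount)) {
      frac <- stats::runif(1, 0.25, 0.95)
      r0 <- plantTop - frac * spec$stemHeight
      side <- if (i %% 2 == 0) 1 else -1
      theta <- side * stats::runif(1, 0.25, 0.8)
      c0 <- spec$centreCol + side * spec$leafAxes[1] * 0.7 * cos(theta)
      r0l <- r0 - spec$leafAxes[1] * 0.4 * abs(sin(theta))
      leaf <- .fillEllipse(matrix(FALSE, nr, nc), r0l, c0,
                           spec$leafAxes[1], spec$leafAxes[2], theta)
      px <- paint(px, leaf, leafColour())
      mask <- mask | leaf
    }
  } else {
    r0 <- nr / 2; c0 <- spec$centreCol
    core <- .fillEllipse(matrix(FALSE, nr, nc), r0, c0,
                         spec$leafAxes[2], spec$leafAxes[2], 0)
    px <- paint(px, core, c(60, 150, 60))
    mask <- mask | core
    if (spec$leafCount > 0) for (i in seq_len(spec$leafCount)) {
      ang <- 2 * pi * (i - 1) / spec$leafCount + stats::runif(1, -0.1, 0.1)
      d <- spec$leafAxes[1] * 0.8
      leaf <- .fillEllipse(matrix(FALSE, nr, nc),
                           r0 + d * sin(ang), c0 + d * cos(ang),
                           spec$leafAxes[1], spec$leafAxes[2], ang)
      px <- paint(px, leaf, leafColour())
      mask <- mask | leaf
    }
  }
  if (any(mask & conveyor))
    stop("scene geometry overlaps the conveyor band")
  if (spec$noiseSD > 0)
    px <- px + array(stats::rnorm(length(px), 0, spec$noiseSD), dim(px))
  px <- round(pmin(pmax(px, 0), 255))
  frame <- RGBFrame(px, view = spec$view,
                    frameId = sprintf("scene-%s-%d", spec$view, spec$seed))
  cropConfig <- SegmentationConfig(
    cropRegion = if (spec$conveyorRows > 0) c(1L, plantTop, 1L, nc) else NULL,
    hueRange = config@hueRange, satMin = config@satMin,
    intRange = config@intRange, egThreshold = config@egThreshold,
    minComponentArea = config@minComponentArea)
  truth <- NULL
  if (computeTraits)
    truth <- referenceTraits(frame, BinaryMask(mask, spec$view), config)
  list(frame = frame, mask = BinaryMask(mask, spec$view),
       conveyor = conveyor, cropConfig = cropConfig, truth = truth)
}
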