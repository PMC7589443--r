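#' Read and write frames and masks as PNG
#'
#' Frames are 8-bit RGB PNGs; masks are single-channel PNGs holding 0
#' (background) or 255 (foreground). Round trips are lossless.
#'
#' @param path file path.
#' @param view "side" or "top".
#' @param frameId identifier; defaults to the file name.
#' @return \code{readFrame}: an \linkS4class{RGBFrame}; \code{readMask}: a
#'   \linkS4class{BinaryMask}.
#' @export
readFrame <- function(path, view, frameId = basename(path)) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  RGBFrame(round(img[, , 1:3] * 255), view = view, frameId = frameId)
}

#' @rdname readFrame
#' @param frame an \linkS4class{RGBFrame} to write.
#' @export
writeFrame <- function(frame, path) {
  png::writePNG(framePixels(frame) / 255, target = path)
  invisible(path)
}

#' @rdname readFrame
#' @export
readMask <- function(path, view) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  BinaryMask(img > 0.5, view = view)
}

#' @rdname readFrame
#' @param mask a \linkS4class{BinaryMask} to write.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(ifelse(framePixels(mask), 1, 0), target = path)
  invisible(path)
}

#' Read / write a SegmentationConfig as YAML
#'
#' Fields: \code{crop_region} (row1, row2, col1, col2; omit for none),
#' \code{hsi_hue_range}, \code{hsi_sat_min}, \code{hsi_int_range},
#' \code{eg_threshold}, \code{min_component_area}.
#'
#' @param path YAML file path.
#' @return a \linkS4class{SegmentationConfig}.
#' @export
readSegmentationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  SegmentationConfig(
    cropRegion = y$crop_region,
    hueRange = if (!is.null(y$hsi_hue_range)) y$hsi_hue_range else c(60, 180),
    satMin = if (!is.null(y$hsi_sat_min)) y$hsi_sat_min else 0.15,
    intRange = if (!is.null(y$hsi_int_range)) y$hsi_int_range else c(0.02, 0.98),
    egThreshold = if (!is.null(y$eg_threshold)) y$eg_threshold else 20,
    minComponentArea = if (!is.null(y$min_component_area)) y$min_component_area else 64)
}

#' @rdname readSegmentationConfig
#' @param config a \linkS4class{SegmentationConfig}.
#' @export
writeSegmentationConfig <- function(config, path) {
  y <- list(hsi_hue_range = config@hueRange, hsi_sat_min = config@satMin,
            hsi_int_range = config@intRange, eg_threshold = config@egThreshold,
            min_component_area = config@minComponentArea)
  if (length(config@cropRegion)) y$crop_region <- config@cropRegion
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Crop a frame to the configured imaging region
#'
#' Removes the conveyor band and other fixed chamber furniture by copying the
#' configured sub-rectangle (1-based, inclusive bounds). With an empty
#' \code{cropRegion} the frame is returned unchanged.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return the cropped \linkS4class{RGBFrame}.
#' @examples
#' px <- array(128L, c(100, 100, 3))
#' f <- RGBFrame(px, "side")
#' cropFrame(f, SegmentationConfig(cropRegion = c(11, 90, 1, 100)))
#' @export
cropFrame <- function(frame, config) {
  cr <- config@cropRegion
  if (!length(cr)) return(frame)
  d <- dim(framePixels(frame))
  if (cr[2] > d[1])
    stop(sprintf("crop row bound %d exceeds frame height %d", cr[2], d[1]),
         call. = FALSE)
  if (cr[4] > d[2])
    stop(sprintf("crop col bound %d exceeds frame width %d", cr[4], d[2]),
         call. = FALSE)
  RGBFrame(framePixels(frame)[cr[1]:cr[2], cr[3]:cr[4], , drop = FALSE],
           view = frameView(frame), frameId = frameId(frame))
}

#' Convert an RGB frame to HSI rasters
#'
#' Hue-saturation-intensity decomposition using the standard geometric
#' formulas: intensity \eqn{I = (R+G+B)/(3 \cdot 255)}, saturation
#' \eqn{S = 1 - 3\min(R,G,B)/(R+G+B)} (0 for black pixels), and hue from the
#' arccosine form, in degrees [0, 360). Achromatic pixels (S = 0) report hue
#' 0 by convention.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @return list with matrices \code{h} (degrees), \code{s}, \code{i} (both
#'   fractions in [0, 1]).
#' @examples
#' px <- array(0L, c(16, 16, 3)); px[, , 2] <- 255L
#' rgbToHSI(RGBFrame(px, "side"))$h[1, 1]  # 120
#' @export
rgbToHSI <- function(frame) {
  px <- framePixels(frame)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  sm <- r + g + b
  i <- sm / (3 * 255)
  s <- ifelse(sm == 0, 0, 1 - 3 * pmin(r, g, b) / sm)
  num <- ((r - g) + (r - b)) / 2
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ct <- ifelse(den == 0, 1, pmin(1, pmax(-1, num / den)))
  theta <- acos(ct) * 180 / pi
  h <- ifelse(b <= g, theta, 360 - theta)
  h[s == 0] <- 0          # achromatic convention
  h[h >= 360] <- 0
  list(h = h, s = s, i = i)
}

#' Excess-green index
#'
#' Per-pixel vegetation index \eqn{EG = 2G - R - B}, range [-510, 510].
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @return integer matrix.
#' @export
excessGreen <- function(frame) {
  px <- framePixels(frame)
  2L * px[, , 2] - px[, , 1] - px[, , 3]
}

#' Segment a side-view frame by HSI thresholding
#'
#' A pixel is foreground iff its hue lies in \code{hueRange}, its saturation
#' is at least \code{satMin}, and its intensity lies in \code{intRange}
#' (half-open at the low end). An empty mask is legal and produces a warning,
#' not an error.
#'
#' @param frame a side-view \linkS4class{RGBFrame}, already cropped.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return a \linkS4class{BinaryMask}.
#' @export
segmentSideView <- function(frame, config = SegmentationConfig()) {
  stopifnot(frameView(frame) == "side")
  hsi <- rgbToHSI(frame)
  fg <- hsi$h >= config@hueRange[1] & hsi$h <= config@hueRange[2] &
        hsi$s >= config@satMin &
        hsi$i > config@intRange[1] & hsi$i <= config@intRange[2]
  if (!any(fg))
    warning("side-view segmentation produced an empty mask (frame ",
            frameId(frame), ")", call. = FALSE)
  BinaryMask(fg, view = "side")
}

#' Segment a top-view frame by the excess-green index
#'
#' A pixel is foreground iff \eqn{EG > } \code{egThreshold}.
#'
#' @param frame a top-view \linkS4class{RGBFrame}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return a \linkS4class{BinaryMask}.
#' @export
segmentTopView <- function(frame, config = SegmentationConfig()) {
  stopifnot(frameView(frame) == "top")
  fg <- excessGreen(frame) > config@egThreshold
  if (!any(fg))
    warning("top-view segmentation produced an empty mask (frame ",
            frameId(frame), ")", call. = FALSE)
  BinaryMask(fg, view = "top")
}

# Two-pass union-find labelling of 8-connected foreground components.
# Returns an integer matrix: 0 = background, 1..k component labels.
.labelComponents <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  idx <- which(px)                       # column-major scan order
  lab <- integer(nr * nc)
  if (!length(idx)) return(matrix(lab, nr, nc))
  parent <- integer(length(idx))
  nlab <- 0L
  for (k in idx) {
    r <- ((k - 1L) %% nr) + 1L
    nb <- integer(0)
    if (r > 1L && lab[k - 1L]) nb <- lab[k - 1L]
    if (k > nr) {                        # previous column exists
      base <- k - nr
      if (lab[base]) nb <- c(nb, lab[base])
      if (r > 1L && lab[base - 1L]) nb <- c(nb, lab[base - 1L])
      if (r < nr && lab[base + 1L]) nb <- c(nb, lab[base + 1L])
    }
    if (!length(nb)) {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab[k] <- nlab
    } else {
      roots <- nb
      for (j in seq_along(roots)) {
        i <- roots[j]
        while (parent[i] != i) i <- parent[i]
        roots[j] <- i
      }
      m <- min(roots)
      lab[k] <- m
      for (i in roots) parent[i] <- m
    }
  }
  for (i in seq_len(nlab)) {             # resolve chains (point downward)
    j <- i
    while (parent[j] != j) j <- parent[j]
    parent[i] <- j
  }
  roots <- parent[seq_len(nlab)]
  remap <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  matrix(lab, nr, nc)
}

#' Label 8-connected foreground components
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return integer matrix: 0 background, 1..k labels.
#' @export
labelComponents <- function(mask) .labelComponents(framePixels(mask))

#' Remove small impurities from a mask
#'
#' Deletes 8-connected components with fewer than \code{minComponentArea}
#' pixels; every surviving pixel was foreground in the input.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return the cleaned \linkS4class{BinaryMask}.
#' @export
cleanMask <- function(mask, config = SegmentationConfig()) {
  lab <- .labelComponents(framePixels(mask))
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= config@minComponentArea)
  BinaryMask(matrix(lab %in% keep, nrow(lab), ncol(lab)),
             view = frameView(mask))
}

#' Masked grey raster
#'
#' Restricts a grey channel of the frame to the foreground: values outside
#' the mask are NA and never enter downstream histograms. The intensity
#' channel is \eqn{(R+G+B)/3} rounded to 8-bit; the green channel is G.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @param mask a \linkS4class{BinaryMask} of the same shape.
#' @param channel "intensity" or "green".
#' @return integer matrix with NA outside the mask.
#' @export
maskedGrey <- function(frame, mask, channel = c("intensity", "green")) {
  channel <- match.arg(channel)
  px <- framePixels(frame); m <- framePixels(mask)
  if (!all(dim(px)[1:2] == dim(m)))
    stop("frame and mask shapes differ", call. = FALSE)
  if (!any(m))
    stop(structure(class = c("emptyForegroundError", "error", "condition"),
                   list(message = "mask has no foreground pixels",
                        call = sys.call(-1))))
  g <- if (channel == "green") px[, , 2]
       else as.integer(round((px[, , 1] + px[, , 2] + px[, , 3]) / 3))
  g <- matrix(as.integer(g), nrow(m), ncol(m))
  g[!m] <- NA_integer_
  g
}
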