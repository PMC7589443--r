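#' @import methods
NULL

#' RGBFrame: an 8-bit RGB raster with a view tag
#'
#' Container for a single plant image as acquired in the imaging chamber.
#' Pixel values are integers in [0, 255], stored as a rows x cols x 3 array
#' (R, G, B planes). The view tag records whether the camera looked at the
#' plant from the side or from above; segmentation dispatches on it.
#'
#' @slot pixels integer array, dim = c(rows, cols, 3), values in [0, 255].
#' @slot view character, "side" or "top".
#' @slot frameId opaque identifier string.
#'
#' @exportClass RGBFrame
setClass("RGBFrame",
  representation(pixels = "array", view = "character", frameId = "character"))

setValidity("RGBFrame", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a rows x cols x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    return("frame must be at least 16 x 16 pixels")
  if (anyNA(object@pixels) || min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must lie in [0, 255]")
  if (!(object@view %in% c("side", "top")))
    return("view must be 'side' or 'top'")
  TRUE
})

#' BinaryMask: foreground plant pixels
#'
#' Logical raster aligned with a source \linkS4class{RGBFrame}: TRUE marks a
#' plant (foreground) pixel. An all-FALSE mask is legal (plant not detected).
#'
#' @slot pixels logical matrix (rows x cols).
#' @slot view character, "side" or "top".
#'
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", view = "character"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  if (anyNA(object@pixels)) return("mask pixels must not contain NA")
  if (!(object@view %in% c("side", "top")))
    return("view must be 'side' or 'top'")
  TRUE
})

#' SegmentationConfig: thresholds and geometry for plant segmentation
#'
#' Holds the tunable segmentation parameters. All rectangles are 1-based,
#' inclusive row/column bounds (R matrix convention). Defaults target green
#' vegetation photographed against a non-green chamber background; they are
#' data, not code constants, and every field can be overridden (or read from
#' a YAML file, see \code{\link{readSegmentationConfig}}).
#'
#' @slot cropRegion integer(4): (row1, row2, col1, col2), inclusive; or
#'   integer(0) for no cropping.
#' @slot hueRange numeric(2): HSI hue gate in degrees, within [0, 360).
#' @slot satMin numeric(1): minimum HSI saturation, in [0, 1].
#' @slot intRange numeric(2): HSI intensity gate (lo, hi], each in [0, 1].
#' @slot egThreshold numeric(1): excess-green cut-off (foreground iff EG >
#'   threshold); EG ranges over [-510, 510].
#' @slot minComponentArea integer(1): connected components (8-connectivity)
#'   smaller than this many pixels are removed by \code{\link{cleanMask}}.
#'
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(cropRegion = "integer", hueRange = "numeric",
                 satMin = "numeric", intRange = "numeric",
                 egThreshold = "numeric", minComponentArea = "integer"),
  prototype(cropRegion = integer(0), hueRange = c(60, 180), satMin = 0.15,
            intRange = c(0.02, 0.98), egThreshold = 20,
            minComponentArea = 64L))

setValidity("SegmentationConfig", function(object) {
  cr <- object@cropRegion
  if (!(length(cr) %in% c(0L, 4L)))
    return("cropRegion must be empty or (row1, row2, col1, col2)")
  if (length(cr) == 4L && (cr[1] > cr[2] || cr[3] > cr[4] || any(cr < 1L)))
    return("cropRegion bounds must satisfy 1 <= row1 <= row2, 1 <= col1 <= col2")
  if (length(object@hueRange) != 2L || any(object@hueRange < 0) ||
      any(object@hueRange >= 360) || object@hueRange[1] > object@hueRange[2])
    return("hueRange must be an ordered pair within [0, 360)")
  if (object@satMin < 0 || object@satMin > 1)
    return("satMin must lie in [0, 1]")
  if (length(object@intRange) != 2L || object@intRange[1] > object@intRange[2])
    return("intRange must be an ordered pair")
  if (object@minComponentArea < 1L)
    return("minComponentArea must be >= 1")
  TRUE
})

#' Construct an RGBFrame
#'
#' @param pixels numeric or integer array rows x cols x 3 with values in
#'   [0, 255] (coerced to integer storage).
#' @param view "side" or "top".
#' @param frameId identifier string.
#' @return an \linkS4class{RGBFrame}.
#' @examples
#' px <- array(0L, c(16, 16, 3)); px[, , 2] <- 255L
#' RGBFrame(px, "top")
#' @export
RGBFrame <- function(pixels, view, frameId = "frame") {
  storage.mode(pixels) <- "integer"
  new("RGBFrame", pixels = pixels, view = view, frameId = frameId)
}

#' Construct a BinaryMask
#'
#' @param pixels logical matrix, TRUE = foreground.
#' @param view "side" or "top".
#' @return a \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(pixels, view) {
  new("BinaryMask", pixels = pixels, view = view)
}

#' Construct a SegmentationConfig
#'
#' @param cropRegion integer(4) inclusive bounds (row1, row2, col1, col2), or
#'   NULL for no crop.
#' @param hueRange,satMin,intRange HSI gates for side-view segmentation.
#' @param egThreshold excess-green cut-off for top-view segmentation.
#' @param minComponentArea minimum connected-component area kept (pixels).
#' @return a \linkS4class{SegmentationConfig}.
#' @examples
#' SegmentationConfig(cropRegion = c(1, 400, 1, 512))
#' @export
SegmentationConfig <- function(cropRegion = NULL, hueRange = c(60, 180),
                               satMin = 0.15, intRange = c(0.02, 0.98),
                               egThreshold = 20, minComponentArea = 64) {
  new("SegmentationConfig",
      cropRegion = if (is.null(cropRegion)) integer(0) else as.integer(cropRegion),
      hueRange = as.numeric(hueRange), satMin = as.numeric(satMin),
      intRange = as.numeric(intRange), egThreshold = as.numeric(egThreshold),
      minComponentArea = as.integer(minComponentArea))
}

setMethod("show", "RGBFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBFrame '%s' (%s view): %d x %d, 8-bit RGB\n",
              object@frameId, object@view, d[1], d[2]))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask (%s view): %d x %d, %d foreground px\n",
              object@view, nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels)))
})

setMethod("show", "SegmentationConfig", function(object) {
  cr <- if (length(object@cropRegion)) paste(object@cropRegion, collapse = ",")
        else "none"
  cat(sprintf(paste0("SegmentationConfig: crop [%s]; hue [%g, %g] deg; ",
                     "sat >= %g; int (%g, %g]; EG > %g; min area %d px\n"),
              cr, object@hueRange[1], object@hueRange[2], object@satMin,
              object@intRange[1], object@intRange[2], object@egThreshold,
              object@minComponentArea))
})
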