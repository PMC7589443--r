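#' Accessors for image classes
#'
#' @param x an \linkS4class{RGBFrame} or \linkS4class{BinaryMask}.
#' @return \code{framePixels}: the pixel array / logical matrix;
#'   \code{frameView}: "side" or "top"; \code{frameId}: the identifier.
#' @name frame-accessors
NULL

#' @rdname frame-accessors
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))

#' @rdname frame-accessors
#' @export
setGeneric("frameView", function(x) standardGeneric("frameView"))

#' @rdname frame-accessors
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname frame-accessors
setMethod("framePixels", "RGBFrame", function(x) x@pixels)
#' @rdname frame-accessors
setMethod("framePixels", "BinaryMask", function(x) x@pixels)
#' @rdname frame-accessors
setMethod("frameView", "RGBFrame", function(x) x@view)
#' @rdname frame-accessors
setMethod("frameView", "BinaryMask", function(x) x@view)
#' @rdname frame-accessors
setMethod("frameId", "RGBFrame", function(x) x@frameId)

#' Segment a frame into a plant mask
#'
#' Dispatches on the frame's view: side views are thresholded in HSI colour
#' space, top views by the excess-green index. See
#' \code{\link{segmentSideView}} and \code{\link{segmentTopView}}.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return a \linkS4class{BinaryMask}.
#' @export
setGeneric("segmentFrame", function(frame, config) standardGeneric("segmentFrame"))

setMethod("segmentFrame", "RGBFrame", function(frame, config) {
  if (frame@view == "side") segmentSideView(frame, config)
  else segmentTopView(frame, config)
})
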