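#' The fixed i-trait catalogue
#'
#' 23 side-view (SV) and 18 top-view (TV) image-derived traits; FW and DW
#' (model-estimated fresh and dry weight, see
#' \code{\link{predictBiomass}}) complete the 43-trait set.
#'
#' @return character vector of trait names.
#' @export
sideTraitNames <- function() {
  paste0(c("AC", "E_TEX", "FDIC", "FDNIC", "GPA", "H", "HA", "HWR", "M_TEX",
           "MU3_TEX", "PAR", paste0("PC", 1:6), "R", "S_TEX", "SE_TEX",
           "TPA", "U_TEX", "W"), "_SV")
}

#' @rdname sideTraitNames
#' @export
topTraitNames <- function() {
  paste0(c("AC", "E_TEX", "FDIC", "FDNIC", "GCV", "GPA", "H", "HA", "HWR",
           "M_TEX", "MU3_TEX", "PAR", "R", "S_TEX", "SE_TEX", "TPA",
           "U_TEX", "W"), "_TV")
}

#' @rdname sideTraitNames
#' @export
imageTraitNames <- function() c(sideTraitNames(), topTraitNames())

#' Extract all i-traits of one frame
#'
#' Runs the full single-frame pipeline: crop to the configured region,
#' segment (HSI for side views, excess green for top views), clean small
#' components, then measure morphology, fractal dimensions, histogram
#' texture (intensity channel) and colour traits. Suffixes (_SV/_TV) are not
#' appended; see \code{\link{extractInspection}} for the suffixed, aggregated
#' inspection vector.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return named numeric vector of per-view traits (23 for side, 18 for
#'   top, unsuffixed); all NA if segmentation finds no plant.
#' @export
frameTraits <- function(frame, config = SegmentationConfig()) {
  frame <- cropFrame(frame, config)
  mask <- suppressWarnings(segmentFrame(frame, config))
  mask <- cleanMask(mask, config)
  maskTraits(frame, mask, config)
}

#' @rdname frameTraits
#' @param mask a precomputed \linkS4class{BinaryMask} (already cleaned).
#' @export
maskTraits <- function(frame, mask, config = SegmentationConfig()) {
  side <- frameView(frame) == "side"
  nm <- sub("_(SV|TV)$", "",
            if (side) sideTraitNames() else topTraitNames())
  if (!any(framePixels(mask)))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  morph <- morphologicalTraits(mask)
  tex <- textureTraits(maskedGrey(frame, mask, "intensity"))
  col <- colourTraits(frame, mask, config)
  v <- c(morph, tex, col,
         FDIC = fractalDimension(mask, cropped = TRUE),
         FDNIC = fractalDimension(mask, cropped = FALSE))
  v[nm]
}

#' Aggregate one inspection into the 41-entry i-trait vector
#'
#' An inspection comprises several side-view rotations (15 in the imaging
#' chamber) and a single top-view image. Each side frame is segmented and
#' measured independently and the side-view trait values are reduced across
#' frames (mean by default, median by option); top-view traits come from the
#' single top frame.
#'
#' @param sideFrames list of side-view \linkS4class{RGBFrame}s (>= 1).
#' @param topFrame the top-view \linkS4class{RGBFrame}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @param reduce "mean" or "median" across side frames.
#' @return named numeric vector of the 41 image traits (suffixed _SV/_TV);
#'   if any frame fails, all values are NA and attr "failed" is TRUE.
#' @export
extractInspection <- function(sideFrames, topFrame,
                              config = SegmentationConfig(),
                              reduce = c("mean", "median")) {
  reduce <- match.arg(reduce)
  stopifnot(length(sideFrames) >= 1L)
  nm <- imageTraitNames()
  out <- tryCatch({
    sv <- vapply(sideFrames, frameTraits, numeric(23), config = config)
    red <- if (reduce == "mean") rowMeans(sv)
           else apply(sv, 1, stats::median)
    tv <- frameTraits(topFrame, config)
    v <- c(stats::setNames(red, paste0(names(red), "_SV")),
           stats::setNames(tv, paste0(names(tv), "_TV")))
    v[nm]
  }, error = function(e) {
    warning("inspection flagged failed: ", conditionMessage(e), call. = FALSE)
    structure(stats::setNames(rep(NA_real_, length(nm)), nm), failed = TRUE)
  })
  out
}

#' Long-format trait table I/O
#'
#' The trait table is the pipeline's central long-format record: one row per
#' (line, replicate, season, time_point, trait). Missing values are written
#' as empty fields, never zeros.
#'
#' @param x data.frame with columns line, replicate, season, time_point,
#'   trait, value.
#' @param path CSV path.
#' @return \code{readTraitTable}: the data.frame.
#' @export
writeTraitTable <- function(x, path) {
  stopifnot(all(c("line", "replicate", "season", "time_point",
                  "trait", "value") %in% names(x)))
  utils::write.csv(x[c("line", "replicate", "season", "time_point",
                       "trait", "value")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTraitTable
#' @export
readTraitTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(line = "character"))
  x$value <- as.numeric(x$value)
  x
}
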