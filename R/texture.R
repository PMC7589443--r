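#' Grey-level histogram texture traits
#'
#' Statistical texture descriptors of the foreground grey-level histogram.
#' With p(z_i) the normalised 256-bin histogram and grey levels rescaled to
#' z_i = i/255 in [0, 1]:
#' mean M_TEX = sum z_i p_i; standard deviation SE_TEX; smoothness
#' S_TEX = 1 - 1/(1 + SE_TEX^2); third moment MU3_TEX; uniformity
#' U_TEX = sum p_i^2; entropy E_TEX = -sum p_i log2 p_i (bits, 0 log 0 = 0).
#'
#' @param grey integer matrix of grey levels 0..255 with NA outside the
#'   foreground (see \code{\link{maskedGrey}}), or a vector of foreground
#'   grey levels.
#' @return named numeric vector M_TEX, SE_TEX, S_TEX, MU3_TEX, U_TEX, E_TEX
#'   (all NA when no foreground pixel is present).
#' @examples
#' textureTraits(c(0L, 255L))  # two equal-mass levels: E_TEX = 1 bit
#' @export
textureTraits <- function(grey) {
  nm <- c("M_TEX", "SE_TEX", "S_TEX", "MU3_TEX", "U_TEX", "E_TEX")
  v <- as.integer(grey[!is.na(grey)])
  if (!length(v)) {
    warning("no foreground grey levels: texture traits are missing",
            call. = FALSE)
    return(stats::setNames(rep(NA_real_, 6L), nm))
  }
  p <- tabulate(v + 1L, nbins = 256L) / length(v)
  z <- (0:255) / 255
  m <- sum(z * p)
  se <- sqrt(sum((z - m)^2 * p))
  pe <- p[p > 0]
  stats::setNames(
    c(m, se, 1 - 1 / (1 + se^2), sum((z - m)^3 * p), sum(p^2),
      -sum(pe * log2(pe))),
    nm)
}

#' Colour i-traits
#'
#' GPA (green projected area) counts foreground pixels whose HSI hue falls in
#' the configured green hue range (the same gate used for side-view
#' segmentation). GCV (green colour value, top view) is the mean over the
#' foreground of g = G/(R+G+B); black pixels contribute 1/3.
#'
#' @param frame an \linkS4class{RGBFrame}.
#' @param mask a \linkS4class{BinaryMask} of the same shape.
#' @param config a \linkS4class{SegmentationConfig} supplying the hue range.
#' @return named numeric vector GPA, GCV (NA when the mask is empty).
#' @export
colourTraits <- function(frame, mask, config = SegmentationConfig()) {
  px <- framePixels(frame); m <- framePixels(mask)
  if (!all(dim(px)[1:2] == dim(m)))
    stop("frame and mask shapes differ", call. = FALSE)
  if (!any(m)) {
    warning("empty mask: colour traits are missing", call. = FALSE)
    return(c(GPA = NA_real_, GCV = NA_real_))
  }
  h <- rgbToHSI(frame)$h
  gpa <- sum(h[m] >= config@hueRange[1] & h[m] <= config@hueRange[2])
  r <- px[, , 1][m]; g <- px[, , 2][m]; b <- px[, , 3][m]
  sm <- r + g + b
  gfrac <- ifelse(sm == 0, 1 / 3, g / sm)
  c(GPA = gpa, GCV = mean(gfrac))
}
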