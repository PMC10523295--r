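#' Convert an RGB image to HSV
#'
#' Standard hexcone conversion; all three output channels are on the [0, 1]
#' scale (hue is a fraction of a turn, not degrees).
#'
#' @param image H x W x 3 RGB array with values in [0, 1].
#' @return H x W x 3 array: hue, saturation, value.
#' @export
rgbToHsv <- function(image) {
  if (any(image < 0 | image > 1))
    stop("RGB values must be in [0, 1]", call. = FALSE)
  d <- dim(image)
  px <- t(matrix(image, ncol = 3L))          # 3 x n, rows r,g,b
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  array(t(hsv), dim = d)
}

#' Threshold masks on the hue and saturation channels
#'
#' Builds the three binary masks that a colour-threshold segmenter
#' multiplies together: the lower mask keeps pixels with hue >= `lowerHue`,
#' the upper mask keeps hue <= `upperHue`, and the saturation mask keeps
#' saturation >= `saturationMin` (removing the pale, desaturated
#' background). Hue bounds are a plain interval — no wraparound.
#'
#' @param hsv H x W x 3 HSV array from [rgbToHsv()].
#' @param thresholds An [hsvThresholds()] object.
#' @return List of binary matrices `lower`, `upper`, `saturation`.
#' @export
thresholdMasks <- function(hsv, thresholds) {
  stopifnot(is(thresholds, "HsvThresholds"))
  list(lower = (hsv[, , 1] >= thresholds@lowerHue) * 1,
       upper = (hsv[, , 1] <= thresholds@upperHue) * 1,
       saturation = (hsv[, , 2] >= thresholds@saturationMin) * 1)
}

#' Combine threshold masks by elementwise multiplication
#'
#' For binary masks the product is the logical AND of the three conditions.
#'
#' @param lower,upper,saturation Binary matrices of identical shape.
#' @return Binary matrix.
#' @export
combineMasks <- function(lower, upper, saturation) {
  if (!all(dim(lower) == dim(upper)) || !all(dim(lower) == dim(saturation)))
    stop("mask shapes differ", call. = FALSE)
  lower * upper * saturation
}

#' Apply a binary mask to every channel of an RGB image
#'
#' @param image H x W x 3 array.
#' @param mask H x W binary matrix.
#' @return H x W x 3 array, zero wherever the mask is zero.
#' @export
applyMask <- function(image, mask) {
  d <- dim(image)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image ", paste(d[1:2], collapse = "x"),
         call. = FALSE)
  image * array(rep(mask, 3L), dim = d)
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening (removes speckle noise smaller than the structuring
#' element) followed by closing (fills holes) with a disc of the given
#' radius. Radius 0 is the identity.
#'
#' @param mask Binary matrix.
#' @param radius Disc radius in pixels, >= 0.
#' @return Cleaned binary matrix.
#' @export
morphologicalCleanup <- function(mask, radius = 2L) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L)
    stop("radius must be >= 0", call. = FALSE)
  if (radius == 0L) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  m <- EBImage::Image(t(mask))
  m <- EBImage::closing(EBImage::opening(m, brush), brush)
  out <- t(EBImage::imageData(m))
  (out > 0.5) * 1
}

#' Segment a stained cell by HSV colour thresholds
#'
#' The full segmentation composition: RGB to HSV conversion, the three
#' threshold masks, their product, morphological cleanup, and application of
#' the final mask to every RGB channel. Parameters used are recorded in the
#' result.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param thresholds An [hsvThresholds()] object; see [defaultThresholds()].
#' @param radius Morphology disc radius (default 2); 0 disables cleanup.
#' @return A [SegmentationResult-class] object.
#' @examples
#' s <- renderCell(defaultAppearance("neutrophil"), 64, seed = 3)
#' r <- segmentImage(s@image, defaultThresholds("neutrophil"))
#' maskIoU(r@mask, s@mask)
#' @export
segmentImage <- function(image, thresholds, radius = 2L) {
  hsv <- rgbToHsv(image)
  m <- thresholdMasks(hsv, thresholds)
  mask <- combineMasks(m$lower, m$upper, m$saturation)
  mask <- morphologicalCleanup(mask, radius)
  new("SegmentationResult", mask = mask, segmented = applyMask(image, mask),
      thresholds = thresholds, radius = as.integer(radius))
}

#' Default segmentation thresholds per leukocyte class
#'
#' The neutrophil setting is the published one: hue bounds 0.0 and 1.0 (hue
#' unconstrained) with saturation threshold 0.45. The other three classes
#' are not published; their hue intervals here bracket the default synthetic
#' stain hues of each class and are tuned on the synthetic generator —
#' configuration values, not literature constants.
#'
#' @param class One of `cellClasses()`.
#' @return An [hsvThresholds()] object.
#' @export
defaultThresholds <- function(class) {
  checkCellClass(class)
  switch(class,
    eosinophil = hsvThresholds(0.70, 1.00, 0.45),
    lymphocyte = hsvThresholds(0.50, 0.85, 0.45),
    monocyte   = hsvThresholds(0.45, 0.80, 0.45),
    neutrophil = hsvThresholds(0.00, 1.00, 0.45))
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Binary matrices of identical shape.
#' @return IoU in [0, 1]; 1 when both masks are empty.
#' @export
maskIoU <- function(a, b) {
  inter <- sum(a * b)
  union <- sum((a + b) > 0)
  if (union == 0) return(1)
  inter / union
}
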