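#' @import methods
NULL

#' The four leukocyte classes
#'
#' The classifier distinguishes the four common white-blood-cell types;
#' basophils (under 1\% of circulating leukocytes) are excluded. The order is
#' alphabetical and fixed: it defines the integer coding used by every model,
#' confusion matrix and manifest in the package.
#'
#' @return Character vector of the four class names in canonical order.
#' @examples
#' cellClasses()
#' @export
cellClasses <- function() {
  c("eosinophil", "lymphocyte", "monocyte", "neutrophil")
}

#' Map a class name to its canonical zero-based index
#'
#' @param name Class name, one of `cellClasses()`.
#' @return Integer index in 0..3.
#' @examples
#' classIndex("eosinophil")  # 0
#' @export
classIndex <- function(name) {
  checkCellClass(name)
  match(name, cellClasses()) - 1L
}

checkCellClass <- function(name) {
  ok <- is.character(name) & name %in% cellClasses()
  if (!all(ok)) {
    stop("unknown cell class '", paste(name[!ok], collapse = "', '"),
         "'; valid classes are: ", paste(cellClasses(), collapse = ", "),
         call. = FALSE)
  }
  invisible(name)
}

#' @slot cellClass leukocyte type this appearance renders
#' @slot nucleusLobes number of nuclear lobes (>= 1)
#' @slot nucleusFraction nucleus-to-cell radius fraction in (0, 1]
#' @slot nucleusHue,cytoplasmHue hues in [0, 1]
#' @slot nucleusSaturation,cytoplasmSaturation saturations in [0, 1]
#' @slot cellRadiusPx nominal cell radius in pixels
#' @slot jitter named numeric vector of jitter amplitudes (position, radius)
#' @rdname defaultAppearance
#' @export
setClass("CellAppearance", representation(
  cellClass = "character",
  nucleusLobes = "integer",
  nucleusFraction = "numeric",
  nucleusHue = "numeric",
  cytoplasmHue = "numeric",
  nucleusSaturation = "numeric",
  cytoplasmSaturation = "numeric",
  cellRadiusPx = "integer",
  jitter = "numeric"
), validity = function(object) {
  msg <- character()
  if (!object@cellClass %in% cellClasses())
    msg <- c(msg, "cellClass must be one of cellClasses()")
  if (object@nucleusLobes < 1L) msg <- c(msg, "nucleusLobes must be >= 1")
  if (object@nucleusFraction <= 0 || object@nucleusFraction > 1)
    msg <- c(msg, "nucleusFraction must be in (0, 1]")
  hs <- c(object@nucleusHue, object@cytoplasmHue,
          object@nucleusSaturation, object@cytoplasmSaturation)
  if (any(hs < 0 | hs > 1)) msg <- c(msg, "hues/saturations must be in [0, 1]")
  if (object@cellRadiusPx < 1L) msg <- c(msg, "cellRadiusPx must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @slot image H x W x 3 RGB array with values in [0, 1]
#' @slot mask H x W binary matrix (1 = cell pixel)
#' @slot label leukocyte class of the rendered cell
#' @slot seed integer seed the sample was rendered with
#' @rdname renderCell
#' @export
setClass("SyntheticSample", representation(
  image = "array", mask = "matrix", label = "character", seed = "integer"
), validity = function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "image must be H x W x 3")
  if (!all(dim(object@mask) == d[1:2]))
    msg <- c(msg, "mask must match image spatial dims")
  if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary")
  if (sum(object@mask) < 1) msg <- c(msg, "mask must have >= 1 foreground pixel")
  if (!object@label %in% cellClasses()) msg <- c(msg, "unknown label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticSample: %s, %dx%d, %d cell px, seed %d\n",
              object@label, d[1], d[2], sum(object@mask), object@seed))
})

#' HSV threshold set driving the segmentation mask
#'
#' Three bounds on the HSV representation of a smear image: pixels are kept
#' where hue >= `lowerHue`, hue <= `upperHue` and saturation >=
#' `saturationMin`. All values live on the [0, 1] scale. The published
#' neutrophil setting is hue bounds 0.0 and 1.0 (hue unconstrained) with
#' saturation threshold 0.45.
#'
#' @param lowerHue,upperHue Hue bounds in [0, 1], `lowerHue <= upperHue`.
#' @param saturationMin Minimum saturation in [0, 1].
#' @return An `HsvThresholds` object.
#' @examples
#' hsvThresholds(0, 1, 0.45)  # the neutrophil setting
#' @aliases HsvThresholds-class
#' @export
hsvThresholds <- function(lowerHue = 0, upperHue = 1, saturationMin = 0.45) {
  new("HsvThresholds", lowerHue = as.numeric(lowerHue),
      upperHue = as.numeric(upperHue),
      saturationMin = as.numeric(saturationMin))
}

#' @export
setClass("HsvThresholds", representation(
  lowerHue = "numeric", upperHue = "numeric", saturationMin = "numeric"
), validity = function(object) {
  msg <- character()
  v <- c(object@lowerHue, object@upperHue, object@saturationMin)
  if (any(v < 0 | v > 1)) msg <- c(msg, "thresholds must be in [0, 1]")
  if (object@lowerHue > object@upperHue)
    msg <- c(msg, "lowerHue must be <= upperHue")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HsvThresholds", function(object) {
  cat(sprintf("HsvThresholds: hue in [%.3f, %.3f], saturation >= %.3f\n",
              object@lowerHue, object@upperHue, object@saturationMin))
})

#' @slot mask binary matrix of kept pixels
#' @slot segmented RGB array with background zeroed
#' @slot thresholds the HsvThresholds used
#' @slot radius morphology structuring-element radius used
#' @rdname segmentImage
#' @export
setClass("SegmentationResult", representation(
  mask = "matrix", segmented = "array", thresholds = "HsvThresholds",
  radius = "integer"
))

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d/%d pixels kept (radius %d)\n",
              sum(object@mask), length(object@mask), object@radius))
})

#' Preprocessing configuration
#'
#' Controls the resize/normalize stage applied before classification. Images
#' are resized to `targetSide` x `targetSide` (default 244, the published
#' input size) and standardized per channel as (x - mean) / sd. The
#' `normalize` mode reflects the published protocol in which only training
#' images are normalized (`"train_only"`, the default); `"both"` applies the
#' training-set statistics to both splits and `"none"` disables the step.
#'
#' @param targetSide Integer side length (>= 32) images are resized to.
#' @param normalize One of `"train_only"`, `"both"`, `"none"`.
#' @param channelMeans,channelStds Optional fixed per-channel statistics
#'   (length-3). When `NA` (default) they are computed from the training set.
#' @return A `PreprocessConfig` object.
#' @examples
#' preprocessConfig(targetSide = 64, normalize = "both")
#' @aliases PreprocessConfig-class
#' @export
preprocessConfig <- function(targetSide = 244L,
                             normalize = c("train_only", "both", "none"),
                             channelMeans = rep(NA_real_, 3),
                             channelStds = rep(NA_real_, 3)) {
  normalize <- match.arg(normalize)
  new("PreprocessConfig", targetSide = as.integer(targetSide),
      normalize = normalize, channelMeans = as.numeric(channelMeans),
      channelStds = as.numeric(channelStds))
}

#' @export
setClass("PreprocessConfig", representation(
  targetSide = "integer", normalize = "character",
  channelMeans = "numeric", channelStds = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@targetSide < 32L) msg <- c(msg, "targetSide must be >= 32")
  if (!object@normalize %in% c("train_only", "both", "none"))
    msg <- c(msg, "normalize must be train_only, both or none")
  if (any(!is.na(object@channelStds) & object@channelStds <= 0))
    msg <- c(msg, "channelStds must be > 0")
  if (length(msg)) msg else TRUE
})

#' Dense-connectivity network configuration
#'
#' Describes the topology of the classifier: a stem convolution, a sequence
#' of dense blocks in which every layer receives the concatenation of the
#' block input and all previous layer outputs (so an L-layer block carries
#' L(L+1)/2 direct connections), channel-compressing transition layers
#' between blocks, and a linear head over globally pooled features.
#'
#' @param initialChannels Channels produced by the stem convolution (k0).
#' @param growthRate Channels each dense layer appends (k).
#' @param blockLayout Integer vector: number of dense layers per block.
#' @param compression Transition compression factor in (0, 1].
#' @param nClasses Number of output classes (default 4).
#' @param inputSide Expected square input side in pixels.
#' @param seed Integer seed for parameter initialization.
#' @return A `DenseNetConfig` object.
#' @examples
#' denseNetConfig(blockLayout = c(2, 2), growthRate = 8, inputSide = 64)
#' @aliases DenseNetConfig-class
#' @export
denseNetConfig <- function(initialChannels = 16L, growthRate = 8L,
                           blockLayout = c(2L, 2L), compression = 0.5,
                           nClasses = 4L, inputSide = 64L, seed = 1L) {
  new("DenseNetConfig", initialChannels = as.integer(initialChannels),
      growthRate = as.integer(growthRate),
      blockLayout = as.integer(blockLayout),
      compression = as.numeric(compression), nClasses = as.integer(nClasses),
      inputSide = as.integer(inputSide), seed = as.integer(seed))
}

#' @export
setClass("DenseNetConfig", representation(
  initialChannels = "integer", growthRate = "integer",
  blockLayout = "integer", compression = "numeric", nClasses = "integer",
  inputSide = "integer", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@initialChannels < 1L || object@growthRate < 1L ||
      any(object@blockLayout < 1L) || object@nClasses < 1L ||
      object@inputSide < 1L)
    msg <- c(msg, "all size fields must be integers >= 1")
  if (object@compression <= 0 || object@compression > 1)
    msg <- c(msg, "compression must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DenseNetConfig", function(object) {
  cat(sprintf(
    "DenseNetConfig: k0=%d, growth=%d, blocks [%s], compression %.2f, %d classes, input %dx%d\n",
    object@initialChannels, object@growthRate,
    paste(object@blockLayout, collapse = ", "), object@compression,
    object@nClasses, object@inputSide, object@inputSide))
})

#' @slot config the DenseNetConfig the model was built from
#' @slot params flat named list of parameter arrays
#' @slot running flat named list of batch-norm running statistics
#' @slot classNames class-name order of the head outputs
#' @slot freezeBody if TRUE, only head parameters receive gradient updates
#' @rdname buildModel
#' @export
setClass("DenseModel", representation(
  config = "DenseNetConfig", params = "list", running = "list",
  classNames = "character", freezeBody = "logical"
))

setMethod("show", "DenseModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("DenseModel: %s classes, %d parameters\n",
              paste(object@classNames, collapse = "/"), np))
  show(object@config)
})

#' One-cycle learning-rate schedule
#'
#' A single cyclical learning-rate cycle: the rate grows linearly from
#' `minLR` to `maxLR` over `stepSize` iterations, falls back linearly to
#' `minLR` over the next `stepSize`, then an annihilation tail lowers it
#' linearly to `finalLR` (far below `minLR`) for the remaining iterations.
#'
#' @seealso [buildSchedule()], [lrAt()]
#' @slot minLR,maxLR cycle bounds (minLR < maxLR)
#' @slot stepSize iterations per half-cycle
#' @slot totalIterations schedule length
#' @slot finalLR terminal rate, < minLR
#' @aliases OneCycleSchedule-class
#' @export
setClass("OneCycleSchedule", representation(
  minLR = "numeric", maxLR = "numeric", stepSize = "integer",
  totalIterations = "integer", finalLR = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@minLR <= 0 || object@maxLR <= 0 || object@finalLR <= 0)
    msg <- c(msg, "learning rates must be positive")
  if (object@minLR >= object@maxLR) msg <- c(msg, "minLR must be < maxLR")
  if (object@finalLR >= object@minLR) msg <- c(msg, "finalLR must be < minLR")
  if (2L * object@stepSize > object@totalIterations)
    msg <- c(msg, "2 * stepSize must be <= totalIterations")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OneCycleSchedule", function(object) {
  cat(sprintf(
    "OneCycleSchedule: lr %.2g -> %.2g -> %.2g, step %d, %d iterations (tail %d)\n",
    object@minLR, object@maxLR, object@finalLR, object@stepSize,
    object@totalIterations, object@totalIterations - 2L * object@stepSize))
})

#' @slot lrs strictly increasing probe rates
#' @slot losses exponentially smoothed losses, one per probe
#' @slot rawLosses unsmoothed losses
#' @slot divergedAt index at which the run stopped, NA if it ran out
#' @slot suggestedMax probe rate at the smoothed-loss minimum
#' @rdname lrRangeTest
#' @export
setClass("RangeTestResult", representation(
  lrs = "numeric", losses = "numeric", rawLosses = "numeric",
  divergedAt = "integer", suggestedMax = "numeric"
), validity = function(object) {
  if (length(object@lrs) != length(object@losses))
    return("lrs and losses must have equal length")
  if (any(diff(object@lrs) <= 0)) return("lrs must be strictly increasing")
  TRUE
})

setMethod("show", "RangeTestResult", function(object) {
  cat(sprintf("RangeTestResult: %d probes, suggested max lr %.4g%s\n",
              length(object@lrs), object@suggestedMax,
              if (is.na(object@divergedAt)) ""
              else sprintf(", diverged at %d", object@divergedAt)))
})

#' @slot iterations data.frame with columns iteration, lr, loss
#' @slot epochs data.frame with columns epoch, train_acc, val_acc,
#'   train_loss, val_loss
#' @rdname trainModel
#' @export
setClass("TrainHistory", representation(
  iterations = "data.frame", epochs = "data.frame"
))

setMethod("show", "TrainHistory", function(object) {
  n <- nrow(object@epochs)
  cat(sprintf("TrainHistory: %d iterations, %d epochs",
              nrow(object@iterations), n))
  if (n > 0)
    cat(sprintf("; final val acc %.3f", object@epochs$val_acc[n]))
  cat("\n")
})

#' @slot confusion C x C confusion matrix, rows = truth, columns = predicted
#' @slot accuracy overall accuracy p0
#' @slot perClass data.frame: class, precision, recall, f1, undefined flags
#' @slot macroPrecision,macroRecall,macroF1 unweighted class means
#' @slot microF1 micro-averaged F1
#' @slot kappa,p0,pe Cohen's kappa with observed and chance agreement
#' @slot roc per-class list of data.frames (fpr, tpr)
#' @slot auc named per-class AUC (NA when undefined)
#' @rdname evaluateModel
#' @export
setClass("EvalReport", representation(
  confusion = "matrix", accuracy = "numeric", perClass = "data.frame",
  macroPrecision = "numeric", macroRecall = "numeric", macroF1 = "numeric",
  microF1 = "numeric", kappa = "numeric", p0 = "numeric", pe = "numeric",
  roc = "list", auc = "numeric"
))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: n=%d  accuracy %.3f  macro-F1 %.3f  micro-F1 %.3f  kappa %.3f\n",
    sum(object@confusion), object@accuracy, object@macroF1, object@microF1,
    object@kappa))
  print(object@perClass, row.names = FALSE, digits = 3)
})
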