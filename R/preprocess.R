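#' Load labelled images from a class-folder tree or a CSV manifest
#'
#' Reads a directory of JPEG/PNG single-cell images. Labels come from a
#' manifest CSV (header `filename,label`) when one is supplied, otherwise
#' from the parent folder name of each image. Images that cannot be decoded
#' are skipped with a warning and counted; any label outside the four
#' accepted leukocyte classes (basophils are excluded from the task) raises
#' an error naming the valid set.
#'
#' @param root Directory containing class subfolders of images (and/or the
#'   files named by `manifest`).
#' @param manifest Optional path to a CSV with columns `filename,label`;
#'   filenames are interpreted relative to `root`.
#' @return data.frame with columns `path` (absolute) and `label`, one row
#'   per decodable image; attribute `skipped` counts unreadable files.
#' @export
loadLabeledImages <- function(root, manifest = NULL) {
  if (!dir.exists(root)) stop("directory not found: ", root, call. = FALSE)
  if (!is.null(manifest)) {
    m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("filename", "label") %in% names(m)))
      stop("manifest must have columns 'filename,label'", call. = FALSE)
    files <- file.path(root, m$filename)
    labels <- m$label
  } else {
    files <- list.files(root, pattern = "\\.(png|jpe?g)$", recursive = TRUE,
                        full.names = TRUE, ignore.case = TRUE)
    files <- files[!grepl("(^|/)masks/", files)]
    labels <- basename(dirname(files))
  }
  if (length(files) == 0L) {
    out <- data.frame(path = character(), label = character(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- 0L
    return(out)
  }
  checkCellClass(unique(labels))
  ok <- logical(length(files))
  for (i in seq_along(files)) {
    ok[i] <- tryCatch({
      img <- EBImage::readImage(files[i])
      length(dim(img)) >= 2L
    }, error = function(e) FALSE)
  }
  nskip <- sum(!ok)
  if (nskip > 0L)
    warning(nskip, " unreadable image(s) skipped", call. = FALSE)
  out <- data.frame(path = normalizePath(files[ok]), label = labels[ok],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- nskip
  out
}

#' Stratified train/validation split
#'
#' Splits labelled items into training and validation subsets class by
#' class, mirroring the conventional 80/20 protocol. Within each class the
#' validation count is `round((1 - fraction) * n)` (round-half-to-even), so
#' it always lies in `{floor, ceil}` of the exact product; shuffling is
#' seed-deterministic.
#'
#' @param items data.frame with columns `path`/`filename` and `label`.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer shuffle seed.
#' @param classes Classes that must each contribute at least one item;
#'   defaults to the classes present in `items`. Pass `cellClasses()` to
#'   require the full four-class task.
#' @return List with elements `train` and `validation` (data.frames of the
#'   same shape as `items`), plus `seed` and `fraction`.
#' @export
stratifiedSplit <- function(items, fraction = 0.8, seed = 1L,
                            classes = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  labs <- items$label
  checkCellClass(unique(labs))
  if (is.null(classes)) classes <- unique(labs)
  for (cl in classes) if (sum(labs == cl) < 1L)
    stop("class '", cl, "' has 0 items", call. = FALSE)
  present <- unique(labs)
  trainIdx <- integer(0)
  valIdx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cl in sort(present)) {
      ix <- which(labs == cl)
      ix <- ix[sample.int(length(ix))]
      nVal <- round((1 - fraction) * length(ix))
      nVal <- max(0L, min(length(ix), nVal))
      valIdx <- c(valIdx, ix[seq_len(nVal)])
      trainIdx <- c(trainIdx, ix[setdiff(seq_along(ix), seq_len(nVal))])
    }
  })
  list(train = items[sort(trainIdx), , drop = FALSE],
       validation = items[sort(valIdx), , drop = FALSE],
       seed = as.integer(seed), fraction = fraction)
}

#' Write a split manifest to CSV
#'
#' @param split Result of [stratifiedSplit()].
#' @param path Output CSV path; columns `filename,label,subset`.
#' @return Invisibly, the written data.frame.
#' @export
writeSplitManifest <- function(split, path) {
  nm <- if ("path" %in% names(split$train)) "path" else "filename"
  df <- rbind(
    data.frame(filename = split$train[[nm]], label = split$train$label,
               subset = "train", stringsAsFactors = FALSE),
    data.frame(filename = split$validation[[nm]],
               label = split$validation$label, subset = "validation",
               stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Dataset bookkeeping totals from per-class counts
#'
#' Sums per-class training and validation counts into per-class totals, the
#' training total, the validation total and the grand total — the arithmetic
#' behind a dataset composition table.
#'
#' @param perClassTrain,perClassVal Numeric vectors of 4 non-negative
#'   per-class counts, alphabetical class order.
#' @return List with `perClassTotal` (named), `trainTotal`, `valTotal`,
#'   `grandTotal`.
#' @examples
#' manifestSummary(c(2497, 2483, 2487, 2499), c(623, 620, 620, 624))
#' @export
manifestSummary <- function(perClassTrain, perClassVal) {
  if (length(perClassTrain) != 4L || length(perClassVal) != 4L)
    stop("expected 4 per-class counts for each subset", call. = FALSE)
  if (any(perClassTrain < 0) || any(perClassVal < 0))
    stop("counts must be >= 0", call. = FALSE)
  perClassTotal <- perClassTrain + perClassVal
  names(perClassTotal) <- cellClasses()
  list(perClassTotal = perClassTotal,
       trainTotal = sum(perClassTrain),
       valTotal = sum(perClassVal),
       grandTotal = sum(perClassTrain) + sum(perClassVal))
}

#' Resize an RGB image to a square side
#'
#' Bilinear resize to `side` x `side`; output values are clamped to [0, 1].
#'
#' @param image H x W x 3 array with values in [0, 1].
#' @param side Target side, >= 1.
#' @return side x side x 3 array.
#' @export
resizeImage <- function(image, side) {
  side <- as.integer(side)
  if (is.na(side) || side < 1L) stop("side must be >= 1", call. = FALSE)
  d <- dim(image)
  if (d[1] == side && d[2] == side) return(image)
  img <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = side, h = side)
  out <- aperm(EBImage::imageData(out), c(2, 1, 3))
  pmin(pmax(out, 0), 1)
}

#' Standardize an image channel-wise
#'
#' Applies `(x - mean_c) / std_c` per channel. The result is unbounded; the
#' transform is exactly invertible given the statistics.
#'
#' @param image H x W x 3 array.
#' @param means,stds Length-3 per-channel statistics; all `stds` > 0.
#' @return H x W x 3 numeric array.
#' @export
normalizeImage <- function(image, means, stds) {
  if (length(means) != 3L || length(stds) != 3L)
    stop("means and stds must have length 3", call. = FALSE)
  if (any(stds <= 0)) stop("stds must be > 0", call. = FALSE)
  out <- image
  for (c in 1:3) out[, , c] <- (image[, , c] - means[c]) / stds[c]
  out
}

#' Per-channel mean and standard deviation of a set of images
#'
#' @param images List of H x W x 3 arrays.
#' @return List with `means` and `stds`, each length 3.
#' @export
channelStats <- function(images) {
  px <- do.call(rbind, lapply(images, function(im) {
    matrix(im, ncol = 3L)
  }))
  list(means = colMeans(px), stds = apply(px, 2, stats::sd))
}

#' Optional augmentation for synthetic images
#'
#' The four standard photometric-free transforms (horizontal/vertical flip,
#' small rotation, zoom) used to enlarge a training set. Off the default
#' training path because the reference dataset ships pre-augmented.
#'
#' @param image H x W x 3 array.
#' @param seed Integer seed choosing the transform parameters.
#' @return Transformed H x W x 3 array of the same size.
#' @export
augmentImage <- function(image, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- image
    if (stats::runif(1) < 0.5) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    if (stats::runif(1) < 0.5) out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    ang <- stats::runif(1, -15, 15)
    zoom <- stats::runif(1, 0.9, 1.1)
    img <- EBImage::Image(aperm(out, c(2, 1, 3)), colormode = "Color")
    img <- EBImage::rotate(img, ang, output.dim = dim(img)[1:2],
                           bg.col = "white")
    side0 <- dim(out)[1]
    img <- EBImage::resize(img, w = round(side0 * zoom))
    arr <- aperm(EBImage::imageData(img), c(2, 1, 3))
    arr <- resizeImage(pmin(pmax(arr, 0), 1), side0)
    arr
  })
}
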