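#' Default rendering appearance for a leukocyte class
#'
#' Returns the fixed appearance used by the synthetic smear generator for one
#' of the four classes. The appearances encode the standard morphological
#' cues of Romanowsky-stained cells: neutrophils a small multilobed (3-lobe)
#' nucleus, eosinophils a bilobed nucleus with pink cytoplasm, lymphocytes a
#' single large dark purple nucleus with a thin cytoplasm rim, monocytes the
#' largest cell with abundant pale blue-grey cytoplasm. Classes differ in
#' nucleus lobe count, nucleus fraction and cell radius, and in mean
#' hue/saturation, so simple colour/size features separate them.
#'
#' Radii are calibrated for a 64-pixel frame and scaled linearly with the
#' rendered side.
#'
#' @param class One of `cellClasses()`.
#' @return A [CellAppearance-class] object.
#' @examples
#' defaultAppearance("neutrophil")
#' @export
defaultAppearance <- function(class) {
  checkCellClass(class)
  spec <- switch(class,
    eosinophil = list(lobes = 2L, frac = 0.55, nHue = 0.78, cHue = 0.93,
                      nSat = 0.75, cSat = 0.60, r = 16L),
    lymphocyte = list(lobes = 1L, frac = 0.85, nHue = 0.75, cHue = 0.60,
                      nSat = 0.85, cSat = 0.55, r = 13L),
    monocyte   = list(lobes = 1L, frac = 0.50, nHue = 0.70, cHue = 0.55,
                      nSat = 0.70, cSat = 0.55, r = 22L),
    neutrophil = list(lobes = 3L, frac = 0.55, nHue = 0.63, cHue = 0.88,
                      nSat = 0.80, cSat = 0.55, r = 16L))
  new("CellAppearance", cellClass = class, nucleusLobes = spec$lobes,
      nucleusFraction = spec$frac, nucleusHue = spec$nHue,
      cytoplasmHue = spec$cHue, nucleusSaturation = spec$nSat,
      cytoplasmSaturation = spec$cSat, cellRadiusPx = spec$r,
      jitter = c(position = 0.05, radius = 0.08))
}

# Background staining of the synthetic slide: pale, low-saturation field.
# Saturation sits far below every class threshold (0.45) so the saturation
# mask separates cell from background even with additive noise.
.bgHSV <- c(h = 0.12, s = 0.08, v = 0.96)
.noiseAmp <- 0.01

# Vectorized hexcone HSV -> RGB used by the renderer (h, s, v in [0, 1]).
hsvToRgbVec <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Render one synthetic leukocyte image with its ground-truth mask
#'
#' Draws a single stained cell — a filled cytoplasm ellipse containing one or
#' more overlapping nucleus-lobe ellipses — centred with positional jitter on
#' a pale low-saturation background, then adds small uniform RGB noise. The
#' binary mask marks exactly the cytoplasm-ellipse pixels, so
#' colour-threshold segmentation can be scored against an exact reference.
#' Rendering is fully deterministic in `(appearance, imageSide, seed)`.
#'
#' @param appearance A [CellAppearance-class], e.g. from
#'   [defaultAppearance()].
#' @param imageSide Square image side in pixels, >= 32.
#' @param seed Integer seed for jitter and noise.
#' @return A [SyntheticSample-class] object.
#' @examples
#' s <- renderCell(defaultAppearance("lymphocyte"), 64, seed = 1)
#' dim(s@image)
#' @export
renderCell <- function(appearance, imageSide, seed = 1L) {
  stopifnot(is(appearance, "CellAppearance"))
  imageSide <- as.integer(imageSide)
  if (imageSide < 32L)
    stop("imageSide must be >= 32, got ", imageSide, call. = FALSE)
  seed <- as.integer(seed)

  withr::with_seed(seed, {
    side <- imageSide
    scale <- side / 64
    jit <- appearance@jitter
    cx <- side / 2 + stats::runif(1, -1, 1) * jit[["position"]] * side
    cy <- side / 2 + stats::runif(1, -1, 1) * jit[["position"]] * side
    r0 <- appearance@cellRadiusPx * scale
    rx <- r0 * (1 + stats::runif(1, -1, 1) * jit[["radius"]])
    ry <- r0 * (1 + stats::runif(1, -1, 1) * jit[["radius"]])

    row <- matrix(seq_len(side), side, side)          # y coordinate
    col <- matrix(seq_len(side), side, side, byrow = TRUE)
    cell <- ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1

    # nucleus: nucleusLobes ellipses on a small ring inside the cell
    L <- appearance@nucleusLobes
    nf <- appearance@nucleusFraction
    lobeR <- if (L == 1L) 0.95 * nf * min(rx, ry) else
      0.62 * nf * min(rx, ry)
    ringR <- if (L == 1L) 0 else 0.38 * min(rx, ry)
    ang0 <- stats::runif(1, 0, 2 * pi)
    nuc <- matrix(FALSE, side, side)
    for (l in seq_len(L)) {
      a <- ang0 + 2 * pi * (l - 1) / max(L, 1)
      lx <- cx + ringR * cos(a)
      ly <- cy + ringR * sin(a)
      nuc <- nuc | (((row - ly)^2 + (col - lx)^2) <= lobeR^2)
    }
    nuc <- nuc & cell

    h <- matrix(.bgHSV[["h"]], side, side)
    s <- matrix(.bgHSV[["s"]], side, side)
    v <- matrix(.bgHSV[["v"]], side, side)
    h[cell] <- appearance@cytoplasmHue
    s[cell] <- appearance@cytoplasmSaturation
    v[cell] <- 0.80
    h[nuc] <- appearance@nucleusHue
    s[nuc] <- appearance@nucleusSaturation
    v[nuc] <- 0.45

    rgb <- hsvToRgbVec(as.vector(h), as.vector(s), as.vector(v))
    img <- array(rgb, dim = c(side, side, 3))
    img <- img + array(stats::runif(length(img), -.noiseAmp, .noiseAmp),
                       dim = dim(img))
    img <- pmin(pmax(img, 0), 1)

    new("SyntheticSample", image = img,
        mask = matrix(as.numeric(cell), side, side),
        label = appearance@cellClass, seed = seed)
  })
}

#' Generate a balanced labelled synthetic smear dataset
#'
#' Renders `nPerClass` samples for each of the four leukocyte classes with
#' their default appearances. Per-sample seeds are derived deterministically
#' from the master seed as `seed + overall sample index` (0-based, class-major
#' in alphabetical class order), so the same master seed always reproduces
#' the identical sample sequence.
#'
#' @param nPerClass Samples per class, >= 1.
#' @param imageSide Square image side in pixels (default 64).
#' @param seed Master seed.
#' @return List of `4 * nPerClass` [SyntheticSample-class] objects, grouped
#'   by class in alphabetical order.
#' @examples
#' ds <- generateDataset(2, imageSide = 64, seed = 7)
#' table(vapply(ds, function(s) s@label, ""))
#' @export
generateDataset <- function(nPerClass, imageSide = 64L, seed = 1L) {
  nPerClass <- as.integer(nPerClass)
  if (is.na(nPerClass) || nPerClass < 1L)
    stop("nPerClass must be >= 1", call. = FALSE)
  idx <- 0L
  out <- vector("list", 4L * nPerClass)
  for (cl in cellClasses()) {
    app <- defaultAppearance(cl)
    for (i in seq_len(nPerClass)) {
      idx <- idx + 1L
      out[[idx]] <- renderCell(app, imageSide, seed = as.integer(seed) + idx - 1L)
    }
  }
  out
}

#' Write synthetic samples to an image-folder tree with a label manifest
#'
#' Lays the samples out in the conventional classification dialect: one
#' subdirectory per class holding PNG images, ground-truth masks under
#' `masks/<class>/`, and a `manifest.csv` with header `filename,label`.
#'
#' @param samples List of [SyntheticSample-class] objects.
#' @param root Output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
writeDataset <- function(samples, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(samples))
  counter <- stats::setNames(integer(4), cellClasses())
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    cl <- s@label
    counter[[cl]] <- counter[[cl]] + 1L
    dir.create(file.path(root, cl), showWarnings = FALSE)
    dir.create(file.path(root, "masks", cl), recursive = TRUE,
               showWarnings = FALSE)
    fname <- file.path(cl, sprintf("%04d.png", counter[[cl]]))
    EBImage::writeImage(
      EBImage::Image(aperm(s@image, c(2, 1, 3)), colormode = "Color"),
      file.path(root, fname))
    EBImage::writeImage(EBImage::Image(t(s@mask)),
                        file.path(root, "masks", fname))
    rows[[i]] <- data.frame(filename = fname, label = cl,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
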