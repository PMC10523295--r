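# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

fixtureDataset <- function(nPerClass, side = 64L, seed = 7L) {
  key <- paste("ds", nPerClass, side, seed, sep = "-")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateDataset(nPerClass, side, seed = seed)
  .fixtures[[key]]
}

# Balanced train/val tensors from synthetic samples, channel-standardized
# with training-set statistics applied to both splits.
fixtureTrainVal <- function(nTrain = 50L, nVal = 20L, side = 64L,
                            seed = 7L) {
  key <- paste("tv", nTrain, nVal, side, seed, sep = "-")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  samples <- fixtureDataset(nTrain + nVal, side, seed)
  labels <- vapply(samples, function(s) s@label, "")
  trainIdx <- unlist(lapply(cellClasses(),
                            function(cl) which(labels == cl)[seq_len(nTrain)]))
  valIdx <- setdiff(seq_along(samples), trainIdx)
  st <- stackImages(samples)
  tr <- matrix(aperm(st$x[, , , trainIdx, drop = FALSE], c(1, 2, 4, 3)),
               ncol = 3)
  mn <- colMeans(tr)
  sdv <- apply(tr, 2, sd)
  norm <- function(x) {
    for (c in 1:3) x[, , c, ] <- (x[, , c, ] - mn[c]) / sdv[c]
    x
  }
  out <- list(
    train = list(x = norm(st$x[, , , trainIdx, drop = FALSE]),
                 y = match(labels[trainIdx], cellClasses()),
                 labels = labels[trainIdx]),
    val = list(x = norm(st$x[, , , valIdx, drop = FALSE]),
               y = match(labels[valIdx], cellClasses()),
               labels = labels[valIdx]))
  .fixtures[[key]] <- out
  out
}

tinyModel <- function(seed = 1L, side = 64L) {
  buildModel(denseNetConfig(initialChannels = 16L, growthRate = 8L,
                            blockLayout = c(2L, 2L), inputSide = side,
                            seed = seed))
}

randomConfusion <- function(C, n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rmultinom(1, n, rep(1, C * C)), C)
    dimnames(m) <- list(letters[1:C], letters[1:C])
    m
  })
}
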