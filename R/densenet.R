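#' Number of direct connections in an L-layer dense block
#'
#' With dense connectivity, layer l receives the block input and all l - 1
#' previous layer outputs, so an L-layer block carries L(L+1)/2 direct
#' connections instead of L.
#'
#' @param L Number of layers, >= 1.
#' @return Integer L(L+1)/2.
#' @examples
#' countDenseConnections(3)  # 6
#' @export
countDenseConnections <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be >= 1", call. = FALSE)
  (L * (L + 1L)) %/% 2L
}

# Channel and spatial bookkeeping for a config. Returns, per block, the
# input channel count of every dense layer (closed form k0_block + (l-1)*k)
# and the spatial side entering the block; errors if a transition collapses
# the spatial grid.
channelPlan <- function(config) {
  k <- config@growthRate
  side <- config@inputSide
  side <- (side + 2L - 3L) %/% 2L + 1L   # stem conv 3x3 stride 2 pad 1
  side <- side %/% 2L                    # stem 2x2 average pool
  channels <- config@initialChannels
  blocks <- list()
  for (bi in seq_along(config@blockLayout)) {
    if (side < 1L)
      stop("spatial size collapses to 0 before block ", bi,
           "; reduce transitions or enlarge inputSide", call. = FALSE)
    L <- config@blockLayout[bi]
    layerIn <- channels + (seq_len(L) - 1L) * k
    channels <- channels + L * k
    blocks[[bi]] <- list(layerInputChannels = layerIn,
                         outputChannels = channels, side = side)
    if (bi < length(config@blockLayout)) {
      channels <- as.integer(floor(channels * config@compression))
      side <- side %/% 2L
    }
  }
  list(blocks = blocks, finalChannels = channels, finalSide = side)
}

# Edge list of the concatenative connectivity graph of one dense block:
# nodes 0 (block input) .. L (layers); layer l consumes node outputs 0..l-1.
blockConnectionGraph <- function(L) {
  edges <- NULL
  for (l in seq_len(L))
    edges <- rbind(edges, cbind(from = 0:(l - 1L), to = l))
  edges
}

initConv <- function(kh, kw, cin, cout) {
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

#' Build a dense-connectivity convolutional classifier
#'
#' Constructs the model described by a [denseNetConfig()]: a 3x3 stride-2
#' stem convolution with batch norm, rectifier and 2x2 average pooling,
#' then dense blocks whose layers follow the bottleneck recipe
#' BN - ReLU - 1x1 conv (4k channels) - BN - ReLU - 3x3 conv (k channels),
#' each output concatenated onto the running feature stack; transitions
#' between blocks apply BN - ReLU - 1x1 compressing convolution - 2x2
#' average pooling; a final BN - ReLU, global average pooling and a linear
#' head produce the class scores. Parameter initialization is
#' seed-deterministic from the config seed.
#'
#' @param config A [denseNetConfig()] object.
#' @return A [DenseModel-class] object.
#' @examples
#' m <- buildModel(denseNetConfig(blockLayout = c(2, 2), inputSide = 64))
#' @export
buildModel <- function(config) {
  stopifnot(is(config, "DenseNetConfig"))
  plan <- channelPlan(config)
  k <- config@growthRate
  P <- list()
  R <- list()
  withr::with_seed(config@seed, {
    st <- initConv(3L, 3L, 3L, config@initialChannels)
    P[["stem.conv.w"]] <- st$w; P[["stem.conv.b"]] <- st$b
    P[["stem.bn.gamma"]] <- rep(1, config@initialChannels)
    P[["stem.bn.beta"]] <- numeric(config@initialChannels)
    R[["stem.bn.mean"]] <- numeric(config@initialChannels)
    R[["stem.bn.var"]] <- rep(1, config@initialChannels)
    for (bi in seq_along(config@blockLayout)) {
      blk <- plan$blocks[[bi]]
      for (li in seq_len(config@blockLayout[bi])) {
        cin <- blk$layerInputChannels[li]
        pre <- sprintf("b%d.l%d", bi, li)
        P[[paste0(pre, ".bn1.gamma")]] <- rep(1, cin)
        P[[paste0(pre, ".bn1.beta")]] <- numeric(cin)
        R[[paste0(pre, ".bn1.mean")]] <- numeric(cin)
        R[[paste0(pre, ".bn1.var")]] <- rep(1, cin)
        c1 <- initConv(1L, 1L, cin, 4L * k)
        P[[paste0(pre, ".conv1.w")]] <- c1$w
        P[[paste0(pre, ".conv1.b")]] <- c1$b
        P[[paste0(pre, ".bn2.gamma")]] <- rep(1, 4L * k)
        P[[paste0(pre, ".bn2.beta")]] <- numeric(4L * k)
        R[[paste0(pre, ".bn2.mean")]] <- numeric(4L * k)
        R[[paste0(pre, ".bn2.var")]] <- rep(1, 4L * k)
        c2 <- initConv(3L, 3L, 4L * k, k)
        P[[paste0(pre, ".conv2.w")]] <- c2$w
        P[[paste0(pre, ".conv2.b")]] <- c2$b
      }
      if (bi < length(config@blockLayout)) {
        cin <- blk$outputChannels
        cout <- as.integer(floor(cin * config@compression))
        pre <- sprintf("t%d", bi)
        P[[paste0(pre, ".bn.gamma")]] <- rep(1, cin)
        P[[paste0(pre, ".bn.beta")]] <- numeric(cin)
        R[[paste0(pre, ".bn.mean")]] <- numeric(cin)
        R[[paste0(pre, ".bn.var")]] <- rep(1, cin)
        tc <- initConv(1L, 1L, cin, cout)
        P[[paste0(pre, ".conv.w")]] <- tc$w
        P[[paste0(pre, ".conv.b")]] <- tc$b
      }
    }
    fc <- plan$finalChannels
    P[["final.bn.gamma"]] <- rep(1, fc)
    P[["final.bn.beta"]] <- numeric(fc)
    R[["final.bn.mean"]] <- numeric(fc)
    R[["final.bn.var"]] <- rep(1, fc)
    P[["head.w"]] <- matrix(stats::rnorm(config@nClasses * fc, sd = 0.01),
                            config@nClasses, fc)
    P[["head.b"]] <- numeric(config@nClasses)
  })
  classNames <- if (config@nClasses == 4L) cellClasses() else
    paste0("class", seq_len(config@nClasses) - 1L)
  new("DenseModel", config = config, params = P, running = R,
      classNames = classNames, freezeBody = FALSE)
}

# Full forward pass. Returns logits [nClasses, N]; with keepCache = TRUE
# also the per-op caches needed for backprop, and (in training mode) the
# updated batch-norm running statistics.
denseForward <- function(model, x, training = FALSE, keepCache = FALSE) {
  P <- model@params
  R <- model@running
  cfg <- model@config
  cache <- if (keepCache) list() else NULL
  keep <- function(name, val) if (keepCache) cache[[name]] <<- val

  keep("stem.x", x)
  z <- convFw(x, P[["stem.conv.w"]], P[["stem.conv.b"]], stride = 2L, pad = 1L)
  bn <- bnFw(z, P[["stem.bn.gamma"]], P[["stem.bn.beta"]],
             R[["stem.bn.mean"]], R[["stem.bn.var"]], training)
  R[["stem.bn.mean"]] <- bn$rmean; R[["stem.bn.var"]] <- bn$rvar
  keep("stem.bnin", z); keep("stem.bn", bn$cache)
  z <- reluFw(bn$y)
  keep("stem.relu", z)
  keep("stem.prepool", dim(z))
  z <- poolFw(z)

  for (bi in seq_along(cfg@blockLayout)) {
    for (li in seq_len(cfg@blockLayout[bi])) {
      pre <- sprintf("b%d.l%d", bi, li)
      keep(paste0(pre, ".in"), z)
      bn1 <- bnFw(z, P[[paste0(pre, ".bn1.gamma")]],
                  P[[paste0(pre, ".bn1.beta")]],
                  R[[paste0(pre, ".bn1.mean")]], R[[paste0(pre, ".bn1.var")]],
                  training)
      R[[paste0(pre, ".bn1.mean")]] <- bn1$rmean
      R[[paste0(pre, ".bn1.var")]] <- bn1$rvar
      keep(paste0(pre, ".bn1"), bn1$cache)
      a1 <- reluFw(bn1$y)
      keep(paste0(pre, ".a1pre"), bn1$y); keep(paste0(pre, ".a1"), a1)
      h <- convFw(a1, P[[paste0(pre, ".conv1.w")]],
                  P[[paste0(pre, ".conv1.b")]])
      keep(paste0(pre, ".h"), h)
      bn2 <- bnFw(h, P[[paste0(pre, ".bn2.gamma")]],
                  P[[paste0(pre, ".bn2.beta")]],
                  R[[paste0(pre, ".bn2.mean")]], R[[paste0(pre, ".bn2.var")]],
                  training)
      R[[paste0(pre, ".bn2.mean")]] <- bn2$rmean
      R[[paste0(pre, ".bn2.var")]] <- bn2$rvar
      keep(paste0(pre, ".bn2"), bn2$cache)
      a2 <- reluFw(bn2$y)
      keep(paste0(pre, ".a2pre"), bn2$y); keep(paste0(pre, ".a2"), a2)
      out <- convFw(a2, P[[paste0(pre, ".conv2.w")]],
                    P[[paste0(pre, ".conv2.b")]], pad = 1L)
      z <- catChannels(z, out)
    }
    if (bi < length(cfg@blockLayout)) {
      pre <- sprintf("t%d", bi)
      keep(paste0(pre, ".in"), z)
      bn <- bnFw(z, P[[paste0(pre, ".bn.gamma")]], P[[paste0(pre, ".bn.beta")]],
                 R[[paste0(pre, ".bn.mean")]], R[[paste0(pre, ".bn.var")]],
                 training)
      R[[paste0(pre, ".bn.mean")]] <- bn$rmean
      R[[paste0(pre, ".bn.var")]] <- bn$rvar
      keep(paste0(pre, ".bn"), bn$cache)
      a <- reluFw(bn$y)
      keep(paste0(pre, ".apre"), bn$y); keep(paste0(pre, ".a"), a)
      z <- convFw(a, P[[paste0(pre, ".conv.w")]], P[[paste0(pre, ".conv.b")]])
      keep(paste0(pre, ".prepool"), dim(z))
      z <- poolFw(z)
    }
  }

  keep("final.in", z)
  bn <- bnFw(z, P[["final.bn.gamma"]], P[["final.bn.beta"]],
             R[["final.bn.mean"]], R[["final.bn.var"]], training)
  R[["final.bn.mean"]] <- bn$rmean; R[["final.bn.var"]] <- bn$rvar
  keep("final.bn", bn$cache)
  a <- reluFw(bn$y)
  keep("final.apre", bn$y)
  keep("final.dim", dim(a))
  f <- globalPoolFw(a)
  keep("features", f)
  logits <- P[["head.w"]] %*% f + P[["head.b"]]
  list(logits = logits, cache = cache, running = R)
}

# Backward pass mirroring denseForward; returns gradients named like params.
denseBackward <- function(model, cache, dlogits) {
  P <- model@params
  cfg <- model@config
  G <- list()
  f <- cache[["features"]]
  G[["head.w"]] <- dlogits %*% t(f)
  G[["head.b"]] <- rowSums(dlogits)
  df <- t(P[["head.w"]]) %*% dlogits
  da <- globalPoolBw(df, cache[["final.dim"]])
  da <- reluBw(da, cache[["final.apre"]])
  bb <- bnBw(da, P[["final.bn.gamma"]], cache[["final.bn"]])
  G[["final.bn.gamma"]] <- bb$dgamma
  G[["final.bn.beta"]] <- bb$dbeta
  dz <- bb$dx

  for (bi in rev(seq_along(cfg@blockLayout))) {
    if (bi < length(cfg@blockLayout)) {
      pre <- sprintf("t%d", bi)
      dz <- poolBw(dz, cache[[paste0(pre, ".prepool")]])
      cb <- convBw(cache[[paste0(pre, ".a")]], P[[paste0(pre, ".conv.w")]], dz)
      G[[paste0(pre, ".conv.w")]] <- cb$gw
      G[[paste0(pre, ".conv.b")]] <- cb$gb
      da <- reluBw(cb$gx, cache[[paste0(pre, ".apre")]])
      bb <- bnBw(da, P[[paste0(pre, ".bn.gamma")]], cache[[paste0(pre, ".bn")]])
      G[[paste0(pre, ".bn.gamma")]] <- bb$dgamma
      G[[paste0(pre, ".bn.beta")]] <- bb$dbeta
      dz <- bb$dx
    }
    for (li in rev(seq_len(cfg@blockLayout[bi]))) {
      pre <- sprintf("b%d.l%d", bi, li)
      zin <- cache[[paste0(pre, ".in")]]
      cin <- dim(zin)[3]
      k <- cfg@growthRate
      dout <- dz[, , cin + seq_len(k), , drop = FALSE]
      dzin <- dz[, , seq_len(cin), , drop = FALSE]
      cb2 <- convBw(cache[[paste0(pre, ".a2")]], P[[paste0(pre, ".conv2.w")]],
                    dout, pad = 1L)
      G[[paste0(pre, ".conv2.w")]] <- cb2$gw
      G[[paste0(pre, ".conv2.b")]] <- cb2$gb
      da2 <- reluBw(cb2$gx, cache[[paste0(pre, ".a2pre")]])
      bb2 <- bnBw(da2, P[[paste0(pre, ".bn2.gamma")]],
                  cache[[paste0(pre, ".bn2")]])
      G[[paste0(pre, ".bn2.gamma")]] <- bb2$dgamma
      G[[paste0(pre, ".bn2.beta")]] <- bb2$dbeta
      cb1 <- convBw(cache[[paste0(pre, ".a1")]], P[[paste0(pre, ".conv1.w")]],
                    bb2$dx)
      G[[paste0(pre, ".conv1.w")]] <- cb1$gw
      G[[paste0(pre, ".conv1.b")]] <- cb1$gb
      da1 <- reluBw(cb1$gx, cache[[paste0(pre, ".a1pre")]])
      bb1 <- bnBw(da1, P[[paste0(pre, ".bn1.gamma")]],
                  cache[[paste0(pre, ".bn1")]])
      G[[paste0(pre, ".bn1.gamma")]] <- bb1$dgamma
      G[[paste0(pre, ".bn1.beta")]] <- bb1$dbeta
      dz <- dzin + bb1$dx
    }
  }

  dz <- poolBw(dz, cache[["stem.prepool"]])
  dz <- reluBw(dz, cache[["stem.relu"]])  # relu output > 0 iff input > 0
  bb <- bnBw(dz, P[["stem.bn.gamma"]], cache[["stem.bn"]])
  G[["stem.bn.gamma"]] <- bb$dgamma
  G[["stem.bn.beta"]] <- bb$dbeta
  cb <- convBw(cache[["stem.x"]], P[["stem.conv.w"]], bb$dx,
               stride = 2L, pad = 1L)
  G[["stem.conv.w"]] <- cb$gw
  G[["stem.conv.b"]] <- cb$gb
  G
}

#' Replace the classifier head of a built model
#'
#' Swaps the final fully connected layer for a freshly initialized one with
#' `nClasses` outputs — the transfer-learning step that adapts a backbone
#' trained on one label set to a new task (e.g. 1,000 classes down to 4).
#' Every non-head parameter is kept bitwise unchanged; setting
#' `freeze = TRUE` additionally marks the body so training updates only the
#' head.
#'
#' @param model A [DenseModel-class].
#' @param nClasses New number of output classes, >= 2.
#' @param freeze If TRUE, only head parameters receive gradient updates.
#' @param seed Seed for the head re-initialization.
#' @return The modified [DenseModel-class].
#' @export
replaceHead <- function(model, nClasses, freeze = FALSE, seed = NULL) {
  stopifnot(is(model, "DenseModel"))
  nClasses <- as.integer(nClasses)
  if (is.na(nClasses) || nClasses < 2L)
    stop("nClasses must be >= 2", call. = FALSE)
  fc <- ncol(model@params[["head.w"]])
  if (is.null(seed)) seed <- model@config@seed + 1L
  withr::with_seed(as.integer(seed), {
    model@params[["head.w"]] <- matrix(stats::rnorm(nClasses * fc, sd = 0.01),
                                       nClasses, fc)
    model@params[["head.b"]] <- numeric(nClasses)
  })
  model@config@nClasses <- nClasses
  model@classNames <- if (nClasses == 4L) cellClasses() else
    paste0("class", seq_len(nClasses) - 1L)
  model@freezeBody <- isTRUE(freeze)
  model
}

#' Stack images (or synthetic samples) into a 4-D input tensor
#'
#' @param items List of H x W x 3 arrays or [SyntheticSample-class] objects.
#' @param side Optional side to resize each image to.
#' @return List with `x` (side x side x 3 x N array) and `labels`
#'   (character, NA where unknown).
#' @export
stackImages <- function(items, side = NULL) {
  n <- length(items)
  imgs <- vector("list", n)
  labels <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    it <- items[[i]]
    if (is(it, "SyntheticSample")) {
      imgs[[i]] <- it@image
      labels[i] <- it@label
    } else {
      imgs[[i]] <- it
    }
    if (!is.null(side)) imgs[[i]] <- resizeImage(imgs[[i]], side)
  }
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 3, n))
  for (i in seq_len(n)) x[, , , i] <- imgs[[i]]
  list(x = x, labels = labels)
}

#' Class-probability predictions for a batch of images
#'
#' Runs the model in evaluation mode (batch-norm running statistics) and
#' returns softmax probabilities and the argmax class per image.
#'
#' @param object A [DenseModel-class].
#' @param images side x side x 3 x N array, or a list accepted by
#'   [stackImages()], with side equal to the model's `inputSide`.
#' @param batchSize Forward-pass minibatch size.
#' @return List with `probabilities` (N x nClasses matrix, columns named by
#'   class) and `predicted` (character vector of argmax classes).
#' @export
predictModel <- function(object, images, batchSize = 32L) {
  if (is.list(images)) images <- stackImages(images)$x
  d <- dim(images)
  side <- object@config@inputSide
  if (length(d) == 3L) {
    images <- array(images, c(d, 1L))
    d <- dim(images)
  }
  if (d[1] != side || d[2] != side)
    stop("expected ", side, "x", side, " inputs, got ",
         d[1], "x", d[2], call. = FALSE)
  n <- d[4]
  probs <- matrix(0, n, object@config@nClasses,
                  dimnames = list(NULL, object@classNames))
  for (start in seq(1L, n, by = batchSize)) {
    ix <- start:min(start + batchSize - 1L, n)
    fw <- denseForward(object, images[, , , ix, drop = FALSE],
                       training = FALSE)
    probs[ix, ] <- t(softmaxProbs(fw$logits))
  }
  list(probabilities = probs,
       predicted = object@classNames[max.col(probs, ties.method = "first")])
}

#' @describeIn predictModel Method for the standard `predict` generic.
#' @param ... Passed through to `predictModel`.
#' @export
setMethod("predict", "DenseModel", function(object, ...) {
  predictModel(object, ...)
})

#' Save / load a model checkpoint
#'
#' The parameter store is written in R's native serialization with a JSON
#' sidecar (`<path>.json`) recording the config and class-name order.
#'
#' @param model A [DenseModel-class].
#' @param path Checkpoint file path.
#' @return `saveModel`: invisibly, `path`; `loadModel`: the restored model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(params = model@params, running = model@running,
               freezeBody = model@freezeBody), path)
  cfg <- model@config
  sidecar <- list(
    config = list(initialChannels = cfg@initialChannels,
                  growthRate = cfg@growthRate,
                  blockLayout = cfg@blockLayout,
                  compression = cfg@compression, nClasses = cfg@nClasses,
                  inputSide = cfg@inputSide, seed = cfg@seed),
    classNames = model@classNames)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  blob <- readRDS(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- denseNetConfig(
    initialChannels = sc$config$initialChannels,
    growthRate = sc$config$growthRate,
    blockLayout = sc$config$blockLayout,
    compression = sc$config$compression, nClasses = sc$config$nClasses,
    inputSide = sc$config$inputSide, seed = sc$config$seed)
  new("DenseModel", config = cfg, params = blob$params,
      running = blob$running, classNames = sc$classNames,
      freezeBody = isTRUE(blob$freezeBody))
}
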