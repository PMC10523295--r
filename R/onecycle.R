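#' Build a one-cycle learning-rate schedule
#'
#' Partitions `totalIterations` into one cyclical learning-rate cycle of two
#' equal linear steps (ascent min to max, descent max to min) plus an
#' annihilation tail. The step size is
#' `floor(totalIterations * (1 - finalFraction) / 2)`; the tail absorbs the
#' remainder and lowers the rate linearly to `finalLR` (default
#' `minLR / 100`), far below the cycle minimum.
#'
#' @param minLR,maxLR Cycle bounds, `0 < minLR < maxLR`.
#' @param totalIterations Schedule length, >= 4.
#' @param finalFraction Fraction of iterations reserved for the tail, in
#'   \[0, 1); default 0.1.
#' @param finalLR Terminal rate; default `minLR / 100`.
#' @return An [OneCycleSchedule-class] object.
#' @examples
#' s <- buildSchedule(0.01, 0.1, 100, 0.1)
#' s@stepSize  # 45
#' @export
buildSchedule <- function(minLR, maxLR, totalIterations, finalFraction = 0.1,
                          finalLR = minLR / 100) {
  if (minLR >= maxLR) stop("minLR must be < maxLR", call. = FALSE)
  totalIterations <- as.integer(totalIterations)
  if (is.na(totalIterations) || totalIterations < 4L)
    stop("totalIterations must be >= 4", call. = FALSE)
  if (finalFraction < 0 || finalFraction >= 1)
    stop("finalFraction must be in [0, 1)", call. = FALSE)
  stepSize <- as.integer(floor(totalIterations * (1 - finalFraction) / 2))
  new("OneCycleSchedule", minLR = minLR, maxLR = maxLR, stepSize = stepSize,
      totalIterations = totalIterations, finalLR = finalLR)
}

#' Learning rate at a given iteration of a schedule
#'
#' Piecewise linear and continuous: ascent `minLR -> maxLR` over
#' `[0, stepSize]`, descent `maxLR -> minLR` over `[stepSize, 2*stepSize]`,
#' then the annihilation tail `minLR -> finalLR` over the remaining
#' iterations, ending below `minLR`.
#'
#' @param schedule An [OneCycleSchedule-class].
#' @param iteration 0-based iteration index (vectorized), in
#'   `[0, totalIterations)`.
#' @return Learning rate(s).
#' @export
lrAt <- function(schedule, iteration) {
  stopifnot(is(schedule, "OneCycleSchedule"))
  it <- iteration
  if (any(it < 0 | it >= schedule@totalIterations))
    stop("iteration out of range [0, ", schedule@totalIterations, ")",
         call. = FALSE)
  s <- schedule@stepSize
  tot <- schedule@totalIterations
  lo <- schedule@minLR
  hi <- schedule@maxLR
  fin <- schedule@finalLR
  tailEnd <- tot - 1L
  out <- numeric(length(it))
  asc <- it <= s
  out[asc] <- lo + (hi - lo) * it[asc] / s
  desc <- it > s & it <= 2L * s
  out[desc] <- hi - (hi - lo) * (it[desc] - s) / s
  tl <- it > 2L * s
  if (any(tl)) {
    denom <- max(tailEnd - 2L * s, 1L)
    out[tl] <- lo + (fin - lo) * (it[tl] - 2L * s) / denom
  }
  out
}

#' Learning-rate range test
#'
#' A pretraining probe: the learning rate rises from `lrStart` to `lrEnd`
#' (linearly, or log-spaced) over `nIterations` calls of `stepFn`, a
#' function taking the rate and returning the loss of one optimization step
#' at that rate. Losses are exponentially smoothed; the run stops early —
#' recording `divergedAt` — when the smoothed loss exceeds
#' `divergenceFactor` times the best smoothed loss so far, or the loss is
#' non-finite. The suggested maximum bound is the probe rate at the minimum
#' of the smoothed loss, the largest rate at which training still improves.
#'
#' @param stepFn Function `(lr) -> loss`.
#' @param lrStart,lrEnd Probe range, `0 < lrStart < lrEnd`.
#' @param nIterations Number of probes, >= 10.
#' @param smoothing Exponential smoothing coefficient in \[0, 1);
#'   default 0.98.
#' @param divergenceFactor Stopping multiple (> 1) of the best smoothed
#'   loss; default 4.
#' @param logSpacing If TRUE, probes are log-spaced.
#' @return A [RangeTestResult-class] object.
#' @export
lrRangeTest <- function(stepFn, lrStart, lrEnd, nIterations = 100L,
                        smoothing = 0.98, divergenceFactor = 4,
                        logSpacing = FALSE) {
  if (lrStart <= 0 || lrStart >= lrEnd)
    stop("need 0 < lrStart < lrEnd", call. = FALSE)
  nIterations <- as.integer(nIterations)
  if (nIterations < 10L) stop("nIterations must be >= 10", call. = FALSE)
  if (smoothing < 0 || smoothing >= 1)
    stop("smoothing must be in [0, 1)", call. = FALSE)
  if (divergenceFactor <= 1) stop("divergenceFactor must be > 1", call. = FALSE)
  lrs <- if (logSpacing)
    exp(seq(log(lrStart), log(lrEnd), length.out = nIterations))
  else seq(lrStart, lrEnd, length.out = nIterations)
  raw <- numeric(0)
  sm <- numeric(0)
  divergedAt <- NA_integer_
  ema <- 0
  for (i in seq_len(nIterations)) {
    loss <- stepFn(lrs[i])
    if (!is.finite(loss)) {
      divergedAt <- i
      raw[i] <- loss
      sm[i] <- if (i == 1L) Inf else sm[i - 1L]
      break
    }
    ema <- smoothing * ema + (1 - smoothing) * loss
    raw[i] <- loss
    sm[i] <- ema / (1 - smoothing^i)   # bias-corrected, so sm[1] = loss
    if (sm[i] > divergenceFactor * min(sm[seq_len(i)])) {
      divergedAt <- i
      break
    }
  }
  nDone <- length(raw)
  finiteSm <- sm
  finiteSm[!is.finite(finiteSm)] <- Inf
  best <- which.min(finiteSm)
  new("RangeTestResult", lrs = lrs[seq_len(nDone)], losses = sm,
      rawLosses = raw, divergedAt = divergedAt,
      suggestedMax = if (length(best)) lrs[best] else NA_real_)
}

# Replays the stopping rule on a recorded loss sequence; used to check that
# divergence detection is a pure function of the losses.
replayRangeTest <- function(losses, lrs, smoothing = 0.98,
                            divergenceFactor = 4) {
  i <- 0L
  f <- function(lr) {
    i <<- i + 1L
    losses[i]
  }
  lrRangeTest(f, lrs[1], lrs[length(lrs)], length(lrs),
              smoothing = smoothing, divergenceFactor = divergenceFactor)
}

#' Cycle bounds from a range-test result
#'
#' The maximum bound is the range test's suggested rate; the minimum bound
#' is that maximum divided by 3.5 under the `factor3_4` policy (a factor of
#' 3 to 4 below the maximum) or by 15 under `factor10_20_one_cycle` (a
#' factor of 10 to 20 below, recommended when a single cycle is used) — the
#' midpoints of the two published ranges.
#'
#' @param result A [RangeTestResult-class] with a finite `suggestedMax`.
#' @param policy `"factor3_4"` or `"factor10_20_one_cycle"`.
#' @return Named numeric vector `c(minLR, maxLR)`.
#' @export
suggestBounds <- function(result,
                          policy = c("factor3_4", "factor10_20_one_cycle")) {
  policy <- match.arg(policy)
  maxLR <- result@suggestedMax
  if (!is.finite(maxLR)) stop("result has no suggestedMax", call. = FALSE)
  minLR <- maxLR / switch(policy, factor3_4 = 3.5,
                          factor10_20_one_cycle = 15)
  c(minLR = minLR, maxLR = maxLR)
}

schedTrace <- function(schedule, total) {
  if (is.numeric(schedule)) {
    if (length(schedule) == 1L) rep(schedule, total) else schedule
  } else {
    lrAt(schedule, seq_len(total) - 1L)
  }
}

#' Train a dense model with a one-cycle (or fixed) learning-rate schedule
#'
#' Minibatch gradient descent with momentum on the softmax cross-entropy,
#' following the supplied learning-rate schedule exactly: iteration i uses
#' `lrAt(schedule, i)`. Batch order is reshuffled seed-deterministically
#' every epoch, so training is reproducible for a fixed seed. The schedule
#' may also be a plain numeric vector of per-iteration rates (or a single
#' rate), which is how a constant-rate baseline is expressed.
#'
#' @param model A [DenseModel-class].
#' @param trainData,valData Lists with `x` (side x side x 3 x N array) and
#'   `y` (integer class indices, 1-based) — see [stackImages()].
#' @param schedule An [OneCycleSchedule-class] whose `totalIterations`
#'   equals `epochs * ceil(N / batchSize)`, or a numeric rate vector of that
#'   length (or length 1).
#' @param epochs Number of epochs; 0 returns the model unchanged with an
#'   empty history.
#' @param batchSize Minibatch size, >= 1.
#' @param seed Shuffle seed.
#' @param momentum,weightDecay Optimizer hyperparameters (defaults 0.9,
#'   1e-4; decay is not applied to batch-norm parameters or biases).
#' @return List with `model` (trained) and `history`
#'   ([TrainHistory-class]).
#' @export
trainModel <- function(model, trainData, valData = NULL, schedule,
                       epochs, batchSize = 32L, seed = 1L, momentum = 0.9,
                       weightDecay = 1e-4) {
  stopifnot(is(model, "DenseModel"))
  epochs <- as.integer(epochs)
  if (epochs == 0L) {
    return(list(model = model, history = new("TrainHistory",
      iterations = data.frame(iteration = integer(), lr = numeric(),
                              loss = numeric()),
      epochs = data.frame(epoch = integer(), train_acc = numeric(),
                          val_acc = numeric(), train_loss = numeric(),
                          val_loss = numeric()))))
  }
  batchSize <- as.integer(batchSize)
  if (batchSize < 1L) stop("batchSize must be >= 1", call. = FALSE)
  n <- dim(trainData$x)[4]
  iterPerEpoch <- as.integer(ceiling(n / batchSize))
  total <- epochs * iterPerEpoch
  if (is(schedule, "OneCycleSchedule") &&
      schedule@totalIterations != total)
    stop("schedule has ", schedule@totalIterations,
         " iterations but training needs ", total,
         " (epochs x ceil(n/batchSize))", call. = FALSE)
  lrs <- schedTrace(schedule, total)
  if (length(lrs) != total)
    stop("schedule trace has ", length(lrs), " rates but training needs ",
         total, call. = FALSE)

  P <- model@params
  vel <- lapply(P, function(p) p * 0)
  decayable <- grepl("conv\\.w$|conv1\\.w$|conv2\\.w$|head\\.w$", names(P))
  headOnly <- model@freezeBody
  isHead <- grepl("^head\\.", names(P))

  itRows <- vector("list", total)
  epRows <- vector("list", epochs)
  it <- 0L
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      for (b in seq_len(iterPerEpoch)) {
        it <- it + 1L
        ix <- ord[((b - 1L) * batchSize + 1L):min(b * batchSize, n)]
        xb <- trainData$x[, , , ix, drop = FALSE]
        yb <- trainData$y[ix]
        fw <- denseForward(model, xb, training = TRUE, keepCache = TRUE)
        model@running <- fw$running
        ce <- softmaxCrossEntropy(fw$logits, yb)
        G <- denseBackward(model, fw$cache, ce$dlogits)
        lr <- lrs[it]
        for (nm in names(P)) {
          if (headOnly && !isHead[match(nm, names(P))]) next
          g <- G[[nm]]
          if (is.null(g)) next
          if (decayable[match(nm, names(P))]) g <- g + weightDecay * P[[nm]]
          vel[[nm]] <- momentum * vel[[nm]] + g
          P[[nm]] <- P[[nm]] - lr * vel[[nm]]
        }
        model@params <- P
        epochLoss <- epochLoss + ce$loss
        itRows[[it]] <- data.frame(iteration = it - 1L, lr = lr,
                                   loss = ce$loss)
      }
      trEval <- evalOnData(model, trainData)
      vaEval <- if (is.null(valData)) list(acc = NA_real_, loss = NA_real_)
                else evalOnData(model, valData)
      epRows[[ep]] <- data.frame(epoch = ep, train_acc = trEval$acc,
                                 val_acc = vaEval$acc,
                                 train_loss = trEval$loss,
                                 val_loss = vaEval$loss)
    }
  })
  history <- new("TrainHistory", iterations = do.call(rbind, itRows),
                 epochs = do.call(rbind, epRows))
  list(model = model, history = history)
}

# Eval-mode accuracy and mean cross-entropy on a data list.
evalOnData <- function(model, data, batchSize = 64L) {
  n <- dim(data$x)[4]
  correct <- 0L
  loss <- 0
  for (start in seq(1L, n, by = batchSize)) {
    ix <- start:min(start + batchSize - 1L, n)
    fw <- denseForward(model, data$x[, , , ix, drop = FALSE],
                       training = FALSE)
    ce <- softmaxCrossEntropy(fw$logits, data$y[ix])
    loss <- loss + ce$loss * length(ix)
    correct <- correct + sum(max.col(t(fw$logits)) == data$y[ix])
  }
  list(acc = correct / n, loss = loss / n)
}

#' Range-test step function for a model on a dataset
#'
#' Builds the `stepFn` consumed by [lrRangeTest()]: each call draws the next
#' minibatch (cycling, seed-deterministic order), applies one momentum-SGD
#' step at the probed rate to a private copy of the model, and returns the
#' batch loss.
#'
#' @param model A [DenseModel-class] (left unmodified; the probe works on a
#'   copy).
#' @param data List with `x` and `y` as in [trainModel()].
#' @param batchSize Minibatch size.
#' @param seed Batch-order seed.
#' @param momentum Momentum coefficient.
#' @return Function `(lr) -> loss`.
#' @export
rangeTestStepFn <- function(model, data, batchSize = 16L, seed = 1L,
                            momentum = 0.9) {
  n <- dim(data$x)[4]
  ord <- withr::with_seed(as.integer(seed), sample.int(n))
  pos <- 0L
  P <- model@params
  vel <- lapply(P, function(p) p * 0)
  mdl <- model
  function(lr) {
    ix <- integer(0)
    for (j in seq_len(batchSize)) {
      pos <<- if (pos >= n) 1L else pos + 1L
      ix <- c(ix, ord[pos])
    }
    fw <- denseForward(mdl, data$x[, , , ix, drop = FALSE], training = TRUE,
                       keepCache = TRUE)
    mdl@running <<- fw$running
    ce <- softmaxCrossEntropy(fw$logits, data$y[ix])
    G <- denseBackward(mdl, fw$cache, ce$dlogits)
    for (nm in names(P)) {
      g <- G[[nm]]
      if (is.null(g)) next
      vel[[nm]] <<- momentum * vel[[nm]] + g
      P[[nm]] <<- P[[nm]] - lr * vel[[nm]]
    }
    mdl@params <<- P
    ce$loss
  }
}

#' Export a training history to CSV
#'
#' Writes `<stem>_iterations.csv` (iteration, lr, loss) and
#' `<stem>_epochs.csv` (epoch, train_acc, val_acc, train_loss, val_loss).
#'
#' @param history A [TrainHistory-class].
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
writeHistory <- function(history, stem) {
  p1 <- paste0(stem, "_iterations.csv")
  p2 <- paste0(stem, "_epochs.csv")
  utils::write.csv(history@iterations, p1, row.names = FALSE)
  utils::write.csv(history@epochs, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
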