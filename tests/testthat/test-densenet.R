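test_that("dense connection count follows L(L+1)/2", {
  expect_identical(countDenseConnections(1), 1L)
  expect_identical(countDenseConnections(3), 6L)
  # oracle: enumerate (earlier node -> later layer) edges of the block graph
  for (L in c(1L, 2L, 5L, 8L)) {
    edges <- leukoscope:::blockConnectionGraph(L)
    expect_identical(nrow(edges), countDenseConnections(L))
  }
  expect_error(countDenseConnections(0), ">= 1")
})

test_that("channel bookkeeping matches the closed form k0 + (l-1)k", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      k0 <- sample(4:32, 1)
      k <- sample(2:16, 1)
      layout <- sample(1:4, sample(1:3, 1), replace = TRUE)
      cfg <- denseNetConfig(initialChannels = k0, growthRate = k,
                            blockLayout = layout, inputSide = 64)
      plan <- leukoscope:::channelPlan(cfg)
      cin <- k0
      for (bi in seq_along(layout)) {
        blk <- plan$blocks[[bi]]
        expect_identical(blk$layerInputChannels,
                         cin + (seq_len(layout[bi]) - 1L) * k)
        expect_identical(blk$outputChannels, cin + layout[bi] * k)
        cin <- if (bi < length(layout))
          as.integer(floor((cin + layout[bi] * k) * 0.5)) else cin
      }
    }
  })
})

test_that("built models carry the planned channel widths end to end", {
  cfg <- denseNetConfig(initialChannels = 16, growthRate = 8,
                        blockLayout = c(4L, 2L), inputSide = 64, seed = 2)
  m <- buildModel(cfg)
  # layer 4 of block 1 sees 16 + 3*8 = 40 input channels
  expect_identical(dim(m@params[["b1.l4.conv1.w"]])[3], 40L)
  # bottleneck emits 4k, the 3x3 conv emits k
  expect_identical(dim(m@params[["b1.l4.conv1.w"]])[4], 32L)
  expect_identical(dim(m@params[["b1.l4.conv2.w"]])[4], 8L)
  # an L=1 block's single layer sees only the block input
  m1 <- buildModel(denseNetConfig(initialChannels = 12, growthRate = 4,
                                  blockLayout = 1L, inputSide = 64))
  expect_identical(dim(m1@params[["b1.l1.conv1.w"]])[3], 12L)
})

test_that("the published DenseNet-161 layout builds at input side 244", {
  cfg <- denseNetConfig(initialChannels = 96, growthRate = 48,
                        blockLayout = c(6L, 12L, 36L, 24L),
                        compression = 0.5, nClasses = 4L, inputSide = 244)
  plan <- leukoscope:::channelPlan(cfg)
  expect_identical(plan$finalChannels, 2208L)  # canonical DenseNet-161 width
  m <- buildModel(cfg)
  expect_identical(ncol(m@params[["head.w"]]), 2208L)
})

test_that("too many transitions for the input side is a config error", {
  cfg <- denseNetConfig(blockLayout = rep(2L, 6), inputSide = 32)
  expect_error(buildModel(cfg), "block")
})

test_that("replaceHead swaps only the head and can freeze the body", {
  m <- tinyModel(seed = 3)
  m1000 <- m
  m1000@params[["head.w"]] <- matrix(rnorm(1000 * 32, sd = 0.01), 1000, 32)
  m1000@params[["head.b"]] <- numeric(1000)
  m1000@config@nClasses <- 1000L

  m4 <- replaceHead(m1000, 4)
  expect_identical(nrow(m4@params[["head.w"]]), 4L)
  body <- setdiff(names(m@params), c("head.w", "head.b"))
  for (nm in body)
    expect_identical(m4@params[[nm]], m1000@params[[nm]])

  # same class count: shape kept, values re-initialized
  m4b <- replaceHead(m4, 4, seed = 99)
  expect_identical(dim(m4b@params[["head.w"]]), dim(m4@params[["head.w"]]))
  expect_false(identical(m4b@params[["head.w"]], m4@params[["head.w"]]))

  expect_error(replaceHead(m, 1), ">= 2")

  # freeze flag: after one training step only head parameters differ
  frozen <- replaceHead(m, 4, freeze = TRUE)
  tv <- fixtureTrainVal(4, 2, 64, seed = 7)
  fit <- trainModel(frozen, tv$train, NULL, schedule = 0.05, epochs = 1,
                    batchSize = 16, seed = 1)
  for (nm in body)
    expect_identical(fit$model@params[[nm]], frozen@params[[nm]])
  expect_false(identical(fit$model@params[["head.w"]],
                         frozen@params[["head.w"]]))
})

test_that("predictions are normalized, deterministic and shape-checked", {
  m <- tinyModel(seed = 4)
  tv <- fixtureTrainVal(4, 2, 64, seed = 7)
  x <- tv$val$x
  p <- predictModel(m, x)
  expect_equal(rowSums(p$probabilities), rep(1, dim(x)[4]), tolerance = 1e-6)
  expect_true(all(p$probabilities >= 0))

  # duplicated image -> identical predictions in eval mode
  dup <- x[, , , c(1, 1, 2), drop = FALSE]
  pd <- predictModel(m, dup)
  expect_equal(pd$probabilities[1, ], pd$probabilities[2, ])

  # permutation consistency
  perm <- c(3, 1, 2, 4:dim(x)[4])
  pp <- predictModel(m, x[, , , perm, drop = FALSE])
  expect_equal(pp$probabilities, p$probabilities[perm, ], tolerance = 1e-12)

  expect_error(predictModel(m, array(0, c(32, 32, 3, 1))), "64x64")
})

test_that("untrained models predict at chance on a balanced set", {
  tv <- fixtureTrainVal(4, 5, 64, seed = 7)
  accs <- vapply(1:10, function(s) {
    m <- buildModel(denseNetConfig(initialChannels = 8, growthRate = 4,
                                   blockLayout = c(2L, 2L), inputSide = 64,
                                   seed = s))
    p <- predictModel(m, tv$val$x)
    mean(p$predicted == tv$val$labels)
  }, 1)
  expect_gte(mean(accs), 0.15)
  expect_lte(mean(accs), 0.35)
})

test_that("checkpoints round-trip through save/load with a JSON sidecar", {
  m <- tinyModel(seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- loadModel(path)
  expect_identical(m2@params, m@params)
  expect_identical(m2@classNames, m@classNames)
  tv <- fixtureTrainVal(4, 2, 64, seed = 7)
  expect_equal(predictModel(m2, tv$val$x)$probabilities,
               predictModel(m, tv$val$x)$probabilities)
})
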