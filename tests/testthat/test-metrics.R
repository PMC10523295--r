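test_that("confusionMatrix counts pairs exactly", {
  cm <- confusionMatrix(rep("a", 8), rep("a", 8), classes = c("a", "b"))
  expect_identical(sum(diag(cm)), 8L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  cm2 <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"),
                         classes = c("A", "B"))
  expect_identical(unname(cm2), matrix(c(1L, 0L, 1L, 1L), 2))

  # brute-force pairwise tally oracle on a random 200-item case
  withr::with_seed(17, {
    classes <- c("w", "x", "y", "z")
    tr <- sample(classes, 200, replace = TRUE)
    pr <- sample(classes, 200, replace = TRUE)
    cm3 <- confusionMatrix(tr, pr, classes)
    for (i in classes) for (j in classes)
      expect_identical(cm3[i, j], sum(tr == i & pr == j))
  })

  expect_error(confusionMatrix(c("a", "b"), c("a")), "length")
  expect_error(confusionMatrix(c("a"), c("q"), classes = c("a", "b")),
               "outside the class set")
})

test_that("accuracy is trace over total", {
  expect_equal(overallAccuracy(diag(c(5, 5, 5, 5))), 1)
  expect_equal(overallAccuracy(matrix(25, 2, 2)), 0.5)
  cm <- randomConfusion(4, 300, seed = 2)
  manual <- 0
  for (i in 1:4) manual <- manual + cm[i, i]
  expect_equal(overallAccuracy(cm), manual / sum(cm))
  expect_error(overallAccuracy(matrix(0, 2, 2)), "empty")
})

test_that("per-class precision/recall/F1 reproduce printed worked rows", {
  # published worked values: P 0.80, R 1.00 -> F1 0.89; P 1.00, R 0.98 -> 0.99
  expect_equal(roundHalfUp(f1Score(0.80, 1.00)), 0.89)
  expect_equal(f1Score(0.80, 1.00), 2 * 0.8 / 1.8, tolerance = 1e-12)
  expect_equal(roundHalfUp(f1Score(1.00, 0.98)), 0.99)
  # harmonic mean of equals is the value itself
  for (p in c(0.1, 0.5, 0.97)) expect_equal(f1Score(p, p), p)

  cm <- rbind(c(8, 2), c(0, 10))
  dimnames(cm) <- list(c("a", "b"), c("a", "b"))
  prf <- perClassPRF(cm)
  expect_equal(prf$precision, c(1, 10 / 12))
  expect_equal(prf$recall, c(0.8, 1))
  expect_false(any(prf$undefined))

  # degenerate class: flagged, not an error
  cm0 <- rbind(c(5, 0), c(3, 0))
  dimnames(cm0) <- list(c("a", "b"), c("a", "b"))
  prf0 <- perClassPRF(cm0)
  expect_true(prf0$undefined[2])
  expect_identical(prf0$precision[2], 0)
})

test_that("macro scores are unweighted class means", {
  pc <- data.frame(precision = c(1, 1, 0.8, 1), recall = c(1, 1, 1, 0.98),
                   f1 = f1Score(c(1, 1, 0.8, 1), c(1, 1, 1, 0.98)))
  mac <- macroScores(pc)
  expect_equal(unname(mac["macroPrecision"]), 0.95)  # printed macro row
  # arithmetic oracle by explicit loop
  s <- 0
  for (i in 1:4) s <- s + pc$f1[i]
  expect_equal(unname(mac["macroF1"]), s / 4)
  # identical classes collapse to the shared value
  same <- data.frame(precision = rep(0.7, 3), recall = rep(0.7, 3),
                     f1 = rep(0.7, 3))
  expect_equal(unname(macroScores(same)), rep(0.7, 3))
})

test_that("micro-F1 equals accuracy for single-label multiclass matrices", {
  expect_equal(microF1(diag(c(3, 4, 5))), 1)
  for (seed in 1:100) {
    cm <- randomConfusion(sample(2:5, 1), sample(20:200, 1), seed)
    expect_equal(microF1(cm), overallAccuracy(cm), tolerance = 1e-12)
  }
  # counting oracle on one random case
  cm <- randomConfusion(4, 120, seed = 7)
  tp <- sum(diag(cm)); fp <- sum(cm) - tp; fn <- sum(cm) - tp
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  expect_equal(microF1(cm), 2 * p * r / (p + r))
})

test_that("kappa implements chance-corrected agreement", {
  expect_equal(cohenKappa(diag(c(10, 10, 10, 10)))$kappa, 1)
  k0 <- cohenKappa(matrix(25, 2, 2))
  expect_equal(k0$p0, 0.5)
  expect_equal(k0$pe, 0.5)
  expect_equal(k0$kappa, 0)

  cm <- rbind(c(30, 10, 0), c(5, 40, 5), c(0, 10, 50))
  k <- cohenKappa(cm)
  # direct arithmetic oracle
  tot <- sum(cm)
  p0 <- (30 + 40 + 50) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  expect_equal(k$kappa, (p0 - pe) / (1 - pe))
  expect_lte(k$kappa, k$p0)

  # degenerate concentration: all mass in one diagonal cell gives pe = 1,
  # which is flagged and resolved as perfect agreement
  kd <- cohenKappa(matrix(c(7, 0, 0, 0), 2))
  expect_equal(kd$kappa, 1)
})

test_that("kappa and accuracy are invariant under class relabeling", {
  cm <- randomConfusion(4, 160, seed = 11)
  perm <- c(3, 1, 4, 2)
  cmP <- cm[perm, perm]
  expect_equal(cohenKappa(cmP)$kappa, cohenKappa(cm)$kappa)
  expect_equal(overallAccuracy(cmP), overallAccuracy(cm))
})

test_that("one-vs-rest AUC equals Mann-Whitney concordance", {
  # perfectly separated scores
  sc <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  r <- rocAuc(sc, c("a", "a", "b", "b"))
  expect_equal(r$a$auc, 1)
  expect_equal(r$b$auc, 1)

  # identical constant scores: ties give 0.5
  scT <- cbind(a = rep(0.5, 6), b = rep(0.5, 6))
  rT <- rocAuc(scT, rep(c("a", "b"), 3))
  expect_equal(rT$a$auc, 0.5)

  # exhaustive pair-counting oracle with half-credit ties
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 20
      labs <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(labs)) < 2) next
      s <- round(runif(n), 1)   # coarse grid forces ties
      got <- rocAuc(cbind(a = s, b = 1 - s), labs)$a$auc
      pos <- s[labs == "a"]; neg <- s[labs != "a"]
      conc <- 0
      for (p in pos) for (q in neg)
        conc <- conc + (p > q) + 0.5 * (p == q)
      expect_equal(got, conc / (length(pos) * length(neg)),
                   tolerance = 1e-12)
    }
  })

  # single-class ground truth flagged undefined
  r1 <- rocAuc(cbind(a = c(0.1, 0.9), b = c(0.9, 0.1)), c("a", "a"))
  expect_true(is.na(r1$a$auc))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    labs <- sample(c("a", "b"), 50, replace = TRUE)
    s <- runif(50)
    ours <- rocAuc(cbind(a = s, b = 1 - s), labs)$a$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labs == "a", predictor = s, quiet = TRUE,
      direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(13, {
    labs <- sample(c("a", "b"), 30, replace = TRUE)
    s <- runif(30)
    a1 <- rocAuc(cbind(a = s, b = 1 - s), labs)$a$auc
    a2 <- rocAuc(cbind(a = exp(3 * s), b = 1 - s), labs)$a$auc
    expect_equal(a1, a2, tolerance = 1e-12)
  })
})

test_that("evaluation reports are internally consistent", {
  # oracle predictor: report collapses to perfection
  labs <- rep(cellClasses(), each = 5)
  sc <- diag(4)[match(labs, cellClasses()), ]
  colnames(sc) <- cellClasses()
  rep1 <- buildEvalReport(labs, labs, sc)
  expect_equal(rep1@accuracy, 1)
  expect_equal(rep1@kappa, 1)
  expect_true(all(rep1@auc == 1))

  # antagonist two-class predictor: zero accuracy, non-positive kappa
  rep0 <- buildEvalReport(c("a", "a", "b", "b"), c("b", "b", "a", "a"),
                          classes = c("a", "b"))
  expect_equal(rep0@accuracy, 0)
  expect_lte(rep0@kappa, 0)

  # every metric in a report recomputes from its own confusion matrix
  withr::with_seed(3, {
    tr <- sample(cellClasses(), 100, replace = TRUE)
    pr <- sample(cellClasses(), 100, replace = TRUE)
  })
  r <- buildEvalReport(tr, pr)
  expect_equal(r@accuracy, overallAccuracy(r@confusion))
  expect_equal(r@microF1, microF1(r@confusion))
  expect_equal(r@macroF1, unname(macroScores(perClassPRF(r@confusion))["macroF1"]))
  expect_equal(r@kappa, cohenKappa(r@confusion)$kappa)
  expect_identical(sum(r@confusion), 100L)
})

test_that("report files mirror the classification-report layout", {
  labs <- rep(cellClasses(), each = 5)
  pred <- labs; pred[3] <- "monocyte"
  dir <- withr::local_tempdir()
  writeEvalReport(buildEvalReport(labs, pred), dir)
  tab <- utils::read.csv(file.path(dir, "per_class.csv"))
  expect_identical(tab$class, c(cellClasses(), "accuracy", "macro avg",
                                "weighted avg"))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$accuracy, 19 / 20)
  expect_true(file.exists(file.path(dir, "confusion.csv")))
})

test_that("display rounding is half-up at two decimals", {
  expect_equal(roundHalfUp(0.885), 0.89)
  expect_equal(roundHalfUp(0.884999), 0.88)
  expect_equal(roundHalfUp(-0.885), -0.89)
})
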