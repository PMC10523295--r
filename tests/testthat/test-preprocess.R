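test_that("loadLabeledImages reads folder trees and manifests", {
  root <- withr::local_tempdir()
  ds <- c(generateDataset(3, 64, seed = 1)[1:3],   # 3 eosinophils
          generateDataset(2, 64, seed = 9)[5:6])   # 2 monocytes
  writeDataset(ds, root)

  items <- loadLabeledImages(root)
  expect_identical(nrow(items), 5L)
  expect_identical(sort(unique(items$label)), c("eosinophil", "monocyte"))
  expect_identical(sum(items$label == "eosinophil"), 3L)

  # via manifest
  items2 <- loadLabeledImages(root, file.path(root, "manifest.csv"))
  expect_identical(nrow(items2), 5L)

  # basophils are excluded from the task
  bad <- data.frame(filename = basename(items$path)[1], label = "basophil")
  badCsv <- file.path(root, "bad.csv")
  utils::write.csv(bad, badCsv, row.names = FALSE)
  expect_error(loadLabeledImages(root, badCsv), "basophil")
  expect_error(loadLabeledImages(root, badCsv), "valid classes")

  # empty directory: empty result, no error
  empty <- withr::local_tempdir()
  out <- loadLabeledImages(empty)
  expect_identical(nrow(out), 0L)

  # unreadable file skipped with a warning
  writeLines("not a png", file.path(root, "eosinophil", "broken.png"))
  expect_warning(items3 <- loadLabeledImages(root), "skipped")
  expect_identical(nrow(items3), 5L)
})

test_that("stratifiedSplit partitions exactly, deterministically, per class", {
  items <- data.frame(
    path = sprintf("img%03d.png", 1:40),
    label = rep(cellClasses(), each = 10),
    stringsAsFactors = FALSE)
  sp <- stratifiedSplit(items, fraction = 0.8, seed = 4)
  expect_identical(nrow(sp$train), 32L)
  expect_identical(nrow(sp$validation), 8L)
  expect_true(all(table(sp$train$label) == 8L))
  expect_true(all(table(sp$validation$label) == 2L))
  # partition: disjoint, exhaustive
  expect_length(intersect(sp$train$path, sp$validation$path), 0L)
  expect_setequal(c(sp$train$path, sp$validation$path), items$path)

  sp2 <- stratifiedSplit(items, fraction = 0.8, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- stratifiedSplit(items, fraction = 0.8, seed = 5)
  expect_false(identical(sp$validation$path, sp3$validation$path))
  expect_identical(dim(sp3$train), dim(sp$train))

  # floor/ceil bound: 3,120 items at fraction 0.8 -> 623 or 624 validation
  big <- data.frame(path = sprintf("e%04d", 1:3120),
                    label = rep("eosinophil", 3120))
  spb <- stratifiedSplit(big, fraction = 0.8, seed = 1)
  expect_true(nrow(spb$validation) %in% c(623L, 624L))

  expect_error(stratifiedSplit(items, fraction = 1.2), "fraction")
  expect_error(
    stratifiedSplit(items[items$label != "monocyte", ], 0.8, 1,
                    classes = cellClasses()),
    "monocyte")
})

test_that("manifestSummary reproduces printed dataset totals", {
  s <- manifestSummary(c(2497, 2483, 2487, 2499), c(623, 620, 620, 624))
  expect_identical(s$trainTotal, 9966)
  expect_identical(s$valTotal, 2487)
  expect_identical(s$grandTotal, 12453)
  expect_identical(unname(s$perClassTotal["eosinophil"]), 3120)

  z <- manifestSummary(rep(0, 4), rep(0, 4))
  expect_identical(z$grandTotal, 0)
  expect_error(manifestSummary(c(-1, 0, 0, 0), rep(0, 4)), ">= 0")
})

test_that("resizeImage hits the target side and preserves range", {
  img <- array(runif(240 * 320 * 3), c(240, 320, 3))
  out <- resizeImage(img, 244)
  expect_identical(dim(out), c(244L, 244L, 3L))
  expect_true(all(out >= 0 & out <= 1))

  flat <- array(0.37, c(50, 60, 3))
  expect_equal(resizeImage(flat, 32), array(0.37, c(32, 32, 3)),
               tolerance = 1e-6)

  sq <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(resizeImage(sq, 64), sq)
  expect_error(resizeImage(sq, 0), ">= 1")
})

test_that("normalizeImage matches the per-channel formula and inverts", {
  img <- array(runif(10 * 10 * 3), c(10, 10, 3))
  means <- c(0.2, 0.5, 0.7)
  stds <- c(0.3, 0.1, 0.9)
  out <- normalizeImage(img, means, stds)
  # elementwise oracle
  for (c in 1:3)
    expect_equal(out[, , c], (img[, , c] - means[c]) / stds[c])
  # invertibility
  back <- out
  for (c in 1:3) back[, , c] <- out[, , c] * stds[c] + means[c]
  expect_equal(back, img, tolerance = 1e-12)

  expect_equal(normalizeImage(array(rep(means, each = 100), c(10, 10, 3)),
                              means, stds),
               array(0, c(10, 10, 3)))
  expect_identical(normalizeImage(img, c(0, 0, 0), c(1, 1, 1)), img)
  expect_error(normalizeImage(img, means, c(0, 1, 1)), "> 0")
})

test_that("preprocess configuration validates its fields", {
  cfg <- preprocessConfig()
  expect_identical(cfg@targetSide, 244L)           # published input side
  expect_identical(cfg@normalize, "train_only")    # published protocol
  cfg2 <- preprocessConfig(targetSide = 64, normalize = "both")
  expect_identical(cfg2@normalize, "both")
  expect_error(preprocessConfig(targetSide = 16), "targetSide")
  expect_error(preprocessConfig(normalize = "sometimes"), "should be one of")
  expect_error(preprocessConfig(channelStds = c(1, 0, 1)), "channelStds")
})

test_that("class indices are the fixed alphabetical coding", {
  expect_identical(cellClasses(),
                   c("eosinophil", "lymphocyte", "monocyte", "neutrophil"))
  expect_identical(vapply(cellClasses(), classIndex, 1L,
                          USE.NAMES = FALSE), 0:3)
  expect_error(classIndex("basophil"), "valid classes")
})

test_that("augmentation preserves geometry and value range", {
  img <- renderCell(defaultAppearance("monocyte"), 64, seed = 2)@image
  a1 <- augmentImage(img, seed = 5)
  expect_identical(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_identical(augmentImage(img, seed = 5), a1)  # seed-deterministic
  expect_false(identical(a1, augmentImage(img, seed = 6)))
})

test_that("split manifests round-trip through CSV", {
  items <- data.frame(path = sprintf("x%02d.png", 1:20),
                      label = rep(c("monocyte", "neutrophil"), each = 10))
  sp <- stratifiedSplit(items, 0.8, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSplitManifest(sp, f)
  df <- utils::read.csv(f)
  expect_identical(nrow(df), 20L)
  expect_identical(sum(df$subset == "validation"), 4L)
})

test_that("channelStats recovers simple constructed statistics", {
  a <- array(0, c(4, 4, 3)); a[, , 2] <- 1
  b <- array(1, c(4, 4, 3)); b[, , 2] <- 0
  st <- channelStats(list(a, b))
  expect_equal(unname(st$means), c(0.5, 0.5, 0.5))
})
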