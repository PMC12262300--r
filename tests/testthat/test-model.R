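# Two-tower scorer: loss closed forms, gradients, training, thresholding.

test_that("the weighted BCE loss matches its closed forms", {
  expect_equal(pairLoss(0, 1), 9 * log(2), tolerance = 1e-12)
  expect_equal(pairLoss(0, 0), log(2), tolerance = 1e-12)
  expect_equal(pairLoss(0, 1, lossConfig(m = 1, p = 1)), log(2),
               tolerance = 1e-12)
  # stabilized at large magnitudes: compare to high-precision evaluation
  expect_equal(pairLoss(-20, 1), 9 * log1p(exp(20)), tolerance = 1e-10)
  expect_true(is.finite(pairLoss(-500, 1)))
  expect_true(is.finite(pairLoss(500, 0)))
  expect_equal(pairLoss(-20, 1), 180, tolerance = 1e-3)
  # equals plain BCE whenever m*p = 1
  x <- seq(-4, 4, by = 0.5)
  plain <- -(1 * log(stats::plogis(x)))
  expect_equal(pairLoss(x, rep(1, length(x)), lossConfig(m = 0.5, p = 2)),
               plain, tolerance = 1e-12)
  expect_true(all(pairLoss(rnorm(50), rbinom(50, 1, 0.5)) >= 0))
  expect_error(pairLoss(0, 2), "labels")
})

test_that("loss gradients match central finite differences", {
  set.seed(42)
  xs <- rnorm(100, sd = 3)
  ys <- rbinom(100, 1, 0.5)
  h <- 1e-6
  fd <- (pairLoss(xs + h, ys) - pairLoss(xs - h, ys)) / (2 * h)
  expect_equal(pairLossGradient(xs, ys), fd, tolerance = 1e-5)
})

test_that("scorePair follows the dot-product + sigmoid closed forms", {
  cfg <- encoderConfig("rc_aggregated", M = 2, hidden = 6, d = 6, seed = 7)
  model <- rcnetModel(cfg, proteinDim = 10)
  r <- pyruvateLactate()
  zr <- embedReaction(r, cfg, modelWeights(model))
  # protein embedding engineered so the projected vector is orthogonal to zr
  Wp <- modelWeights(model)$Wp
  e <- rnorm(10)
  zp <- as.numeric(Wp %*% e)
  eOrth <- e - sum(zp * zr) / sum((t(Wp) %*% zr)^2) * as.numeric(t(Wp) %*% zr)
  expect_equal(scorePair(model, r, eOrth), 0.5, tolerance = 1e-10)
  # a protein embedding whose projection aligns with zr at dot ln 3
  # scores exactly sigmoid(ln 3) = 0.75
  target <- zr * log(3) / sum(zr^2)
  eAligned <- as.numeric(t(Wp) %*% solve(Wp %*% t(Wp), target))
  expect_equal(scorePair(model, r, eAligned), 0.75, tolerance = 1e-10)
  expect_error(scorePair(model, r, rnorm(4)), "dim")
})

test_that("two pairs can be memorized and training is reproducible", {
  setup <- tinyTrainingSetup(seed = 15)
  rx <- setup$reactions[1:2]
  pids <- proteinIds(setup$proteins)[1:2]
  pairs <- data.frame(
    protein_id = pids, reaction_id = names(rx),
    label = c(1L, 0L), fold = "cv1", provenance = c("observed", "sampled"),
    stringsAsFactors = FALSE)
  pd <- new("PairDataset", pairs = pairs, ratios = c(cv1 = 1), seed = 1L)
  cfg <- encoderConfig("rc_aggregated", M = 2, hidden = 8, d = 8, seed = 2)
  tc <- trainConfig(epochs = 200, lr = 5e-3, seed = 2)
  m <- trainModel(pd, rx, setup$proteins, cfg, tc, lossConfig())
  lg <- trainingLog(m)
  expect_lt(lg$train_loss[200], 0.05)
  # decreasing after warmup
  expect_true(all(diff(lg$train_loss[50:200]) <= 1e-8))

  m2 <- trainModel(pd, rx, setup$proteins, cfg, tc, lossConfig())
  expect_identical(modelWeights(m), modelWeights(m2))
})

test_that("threshold selection maximizes F1 over score midpoints", {
  expect_equal(selectThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  # perfect separation: smallest midpoint inside the gap
  expect_equal(selectThreshold(c(0.1, 0.9), c(0, 1)), 0.5)
  expect_equal(selectThreshold(c(0.2, 0.3, 0.9), c(0, 1, 1)), 0.25)
  tau <- selectThreshold(c(0.4, 0.4, 0.4), c(0, 1, 1))
  expect_true(isTRUE(attr(tau, "degenerate")))
  expect_equal(as.numeric(tau), 0.2)  # midpoint with the 0 bound wins ties
  expect_error(selectThreshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("cross-validation returns per-cell tables and breaks ties first", {
  setup <- tinyTrainingSetup(seed = 25)
  small <- setup
  cfg <- encoderConfig("morgan", d = 8, nbits = 256, seed = 3)
  cv1 <- crossValidate(small$positives, small$reactions, small$proteins,
                       small$assignment, list(cfg), k = 2,
                       train = trainConfig(epochs = 3, batchSize = 64,
                                           lr = 5e-3, seed = 3),
                       seed = 6)
  expect_equal(cv1$bestIndex, 1)
  expect_equal(nrow(cv1$table), 1)
  expect_true(is.finite(cv1$table$mean_f1))

  cv2 <- crossValidate(small$positives, small$reactions, small$proteins,
                       small$assignment, list(cfg, cfg), k = 2,
                       train = trainConfig(epochs = 3, batchSize = 64,
                                           lr = 5e-3, seed = 3),
                       seed = 6)
  expect_equal(cv2$bestIndex, 1)  # identical cells: first in grid order
  expect_equal(cv2$table$mean_f1[1], cv2$table$mean_f1[2])
  expect_error(crossValidate(small$positives, small$reactions,
                             small$proteins, small$assignment, list(),
                             k = 2), "empty")
})

test_that("model JSON checkpoints round-trip", {
  cfg <- encoderConfig("rc_aggregated", M = 2, hidden = 5, d = 5, seed = 11)
  m <- rcnetModel(cfg, proteinDim = 12, threshold = 0.3)
  f <- tempfile(fileext = ".json")
  saveModelJson(m, f)
  m2 <- loadModelJson(f)
  expect_equal(modelWeights(m2), modelWeights(m), tolerance = 1e-12)
  expect_equal(decisionThreshold(m2), 0.3)
  r <- pyruvateLactate()
  e <- rnorm(12)
  expect_equal(scorePair(m2, r, e), scorePair(m, r, e), tolerance = 1e-12)
})
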