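test_that("cross-entropy matches closed forms and a brute-force sum", {
  # perfect one-hot prediction: zero loss
  p <- array(0, c(2, 2, 1, 2))
  lab <- array(c(0L, 1L, 1L, 0L), c(2, 2, 1))
  for (i in 1:2) for (j in 1:2)
    p[i, j, 1, ] <- if (lab[i, j, 1] == 1L) c(0, 1) else c(1, 0)
  expect_equal(crossEntropy(p, lab), 0, tolerance = 1e-6)
  # uniform two-class probabilities: log 2 per voxel
  pu <- array(0.5, c(3, 3, 3, 2))
  expect_equal(crossEntropy(pu, array(0L, c(3, 3, 3))), log(2))
  # random 4-voxel case equals the hand-summed mean
  set.seed(1)
  raw <- matrix(runif(8, 0.1, 1), 4, 2)
  raw <- raw / rowSums(raw)
  pr <- array(0, c(4, 1, 1, 2))
  pr[, 1, 1, ] <- raw
  labs <- array(c(0L, 1L, 1L, 0L), c(4, 1, 1))
  expected <- -mean(log(raw[cbind(1:4, as.integer(labs) + 1L)]))
  expect_equal(crossEntropy(pr, labs), expected)
  # errors
  expect_error(crossEntropy(pu, array(0L, c(2, 2, 2))), "mismatch")
  expect_error(crossEntropy(pu, array(5L, c(3, 3, 3))), "out of range")
})

test_that("cross-entropy falls when probability mass moves to the true class", {
  set.seed(21)
  for (i in 1:20) {
    p1 <- runif(1, 0.05, 0.9)
    lab <- array(1L, c(1, 1, 1))
    mk <- function(pfg) { a <- array(0, c(1, 1, 1, 2)); a[1, 1, 1, ] <- c(1 - pfg, pfg); a }
    expect_gt(crossEntropy(mk(p1), lab),
              crossEntropy(mk(min(p1 + 0.05, 0.999)), lab))
  }
})

test_that("cross-validation folds are balanced partitions", {
  f8 <- makeCVFolds(paste0("case", 1:8), k = 4, seed = 1)
  expect_identical(sort(as.integer(table(f8$foldOfCase))), rep(2L, 4))
  f9 <- makeCVFolds(1:9, k = 4, seed = 2)
  sizes <- sort(as.integer(table(f9$foldOfCase)), decreasing = TRUE)
  expect_identical(sizes, c(3L, 2L, 2L, 2L))
  expect_setequal(names(f9$foldOfCase), as.character(1:9))
  expect_error(makeCVFolds(1:3, k = 4), "fewer cases")
  # assignment frequency is uniform across seeds
  counts <- matrix(0, 8, 4)
  for (s in 1:400) {
    f <- makeCVFolds(1:8, k = 4, seed = s)
    for (i in 1:8) counts[i, f$foldOfCase[as.character(i)] + 1L] <-
        counts[i, f$foldOfCase[as.character(i)] + 1L] + 1
  }
  freq <- counts / 400
  expect_lt(max(abs(freq - 0.25)), 4 * sqrt(0.25 * 0.75 / 400))
})

test_that("training is a seeded no-op at zero epochs and reproducible", {
  cases <- list(phantomCase(41, shape = 40, nLesions = 2))
  fcfg <- tinyFnetConfig()
  t0 <- trainConfig(epochs = 0, patchesPerEpoch = 8, seed = 33)
  fit0 <- trainModel(cases, t0, fcfg, window = softTissueWindow(),
                     patchVoxels = 14)
  expect_length(fit0$history, 0L)
  ref <- buildFnet(fcfg, seed = 33) # same RNG stream position
  expect_identical(fit0$model@params, ref@params)

  tc <- trainConfig(epochs = 2, patchesPerEpoch = 16, seed = 7)
  fitA <- trainModel(cases, tc, fcfg, window = softTissueWindow(),
                     patchVoxels = 14)
  fitB <- trainModel(cases, tc, fcfg, window = softTissueWindow(),
                     patchVoxels = 14)
  expect_identical(fitA$history, fitB$history)
  expect_identical(fitA$model@params, fitB$model@params)
  expect_length(fitA$history, 2L)
  expect_true(all(is.finite(fitA$history)))
})

test_that("training reduces the loss on easy high-contrast phantoms", {
  cases <- list(phantomCase(51, shape = 40, nLesions = 3, noiseSD = 2))
  fcfg <- tinyFnetConfig()
  wins <- 0L
  for (seed in 1:5) {
    fit <- trainModel(cases, trainConfig(epochs = 4, patchesPerEpoch = 24,
                                         seed = seed),
                      fcfg, window = softTissueWindow(), patchVoxels = 14)
    if (tail(fit$history, 1) < fit$history[1]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("threshold selection equals an exhaustive independent grid search", {
  set.seed(99)
  grid <- seq(0.05, 0.95, by = 0.05)
  for (rep in 1:10) {
    d <- c(10, 10, 6)
    probs <- lapply(1:3, function(i) array(runif(prod(d)), d))
    masks <- lapply(1:3, function(i)
      array(as.integer(runif(prod(d)) < 0.3), d))
    # independent loop
    best <- -Inf; bestT <- NA
    for (t in grid) {
      dices <- mapply(function(p, g) {
        pred <- p >= t
        s <- sum(pred) + sum(g)
        if (s == 0) 1 else 2 * sum(pred & (g > 0)) / s
      }, probs, masks)
      if (mean(dices) > best + 1e-12) { best <- mean(dices); bestT <- t }
    }
    expect_equal(selectThreshold(probs, masks, grid), bestT)
  }
})

test_that("threshold selection honors a constructed 0.40 optimum and ties", {
  d <- c(12, 12, 4)
  gt <- array(0L, d); gt[3:6, 3:6, 2] <- 1L
  p <- array(0, d)
  p[gt == 1L] <- 0.41          # true lesion just above 0.4
  p[8:11, 8:11, 3] <- 0.38     # confounder swept in below 0.40
  expect_equal(selectThreshold(list(p), list(gt)), 0.40)
  # exact prediction: every grid value gives Dice 1 -> lowest wins
  pExact <- array(0, d); pExact[gt == 1L] <- 1
  expect_equal(selectThreshold(list(pExact), list(gt)), 0.05)
  expect_error(selectThreshold(list(), list()))
})
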