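test_that("component matching covers identity, disjoint and spanning cases", {
  d <- c(12, 12, 6)
  gt <- array(0L, d)
  gt[2:4, 2:4, 2:3] <- 1L
  gt[8:10, 8:10, 2:3] <- 2L
  gtCS <- labeledComponents(LabelMask(gt, 1.5))
  # identical prediction: everything detected and matched
  predCS <- connectedComponents(asBinaryMask(LabelMask(gt, 1.5)))
  m <- matchComponents(gtCS, predCS)
  expect_true(all(m$gtDetected))
  expect_true(all(m$predMatched))
  # disjoint prediction: nothing detected, all predictions unmatched
  pd <- array(0L, d); pd[6, 6, 5] <- 1L
  m2 <- matchComponents(gtCS, connectedComponents(LabelMask(pd, 1.5)))
  expect_false(any(m2$gtDetected))
  expect_false(any(m2$predMatched))
  # one predicted blob spanning both nodes: both detected, one matched
  span <- array(0L, d); span[2:10, 2:10, 2] <- 1L
  m3 <- matchComponents(gtCS, connectedComponents(LabelMask(span, 1.5)))
  expect_true(all(m3$gtDetected))
  expect_length(m3$predMatched, 1L)
  expect_true(m3$predMatched)
  # grid mismatch errors
  other <- connectedComponents(LabelMask(array(0L, c(4, 4, 4))))
  expect_error(matchComponents(gtCS, other), "different grids")
})

test_that("detection rate and FP/volume are exact ratios", {
  expect_equal(detectionRate(c(TRUE, TRUE, TRUE)), 1)
  expect_equal(detectionRate(c(FALSE, FALSE, FALSE)), 0)
  expect_equal(detectionRate(c(TRUE, TRUE, FALSE)), 2 / 3)
  expect_error(detectionRate(logical(0)), "zero ground-truth")
  expect_equal(falsePositivesPerVolume(logical(0), 3), 0)
  expect_equal(falsePositivesPerVolume(list(c(FALSE, FALSE, TRUE),
                                            c(FALSE, FALSE)), 2), 2)
})

test_that("matched-mask metrics match the hand-computed example", {
  d <- c(8, 8, 4)
  gt <- array(0L, d); gt[2:5, 2, 2] <- 1L # 4 voxels
  pred <- array(0L, d); pred[4:5, 2, 2] <- 1L # 2 voxels, both overlapping
  gtCS <- labeledComponents(LabelMask(gt, 1.5))
  prCS <- connectedComponents(LabelMask(pred, 1.5))
  sm <- matchedSegMetrics(gtCS, prCS)
  expect_equal(sm$dice, 2 * 2 / (4 + 2))
  expect_equal(sm$tpr, 0.5)
  expect_equal(sm$ppv, 1.0)
  # identical masks: all ones
  smi <- matchedSegMetrics(gtCS, connectedComponents(
    asBinaryMask(LabelMask(gt, 1.5))))
  expect_equal(unlist(smi), c(dice = 1, tpr = 1, ppv = 1))
  # everything missed: sentinel NA
  empty <- connectedComponents(LabelMask(array(0L, d), 1.5))
  smn <- matchedSegMetrics(gtCS, empty)
  expect_true(all(is.na(unlist(smn))))
})

test_that("SAD estimation recovers analytic shapes", {
  # digital sphere of radius 5 mm at 1 mm spacing -> SAD ~ 10 mm
  d <- c(24, 24, 24)
  ctr <- c(12, 12, 12)
  grid <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  inside <- rowSums(sweep(grid, 2, ctr)^2) <= 5^2
  sphere <- array(0L, d); sphere[grid[inside, ]] <- 1L
  sad <- sadOfComponent(which(sphere > 0), d, 1)
  expect_lte(abs(sad - 10), 1 + 1e-9) # within one voxel spacing
  # a single voxel at 1.5 mm spacing
  expect_equal(sadOfComponent(1L, c(2, 2, 2), 1.5), 1.5)
  # axis-aligned 4 x 10 voxel rectangle at 1.5 mm -> short side 6 mm
  rect <- array(0L, c(20, 20, 3))
  rect[4:7, 5:14, 2] <- 1L
  expect_lt(abs(sadOfComponent(which(rect > 0), dim(rect), 1.5) - 6), 0.76)
})

test_that("SAD stratification bins half-open groups and excludes < 5 mm", {
  nodes <- data.frame(sad_mm = c(6, 12, 25), detected = c(TRUE, TRUE, TRUE))
  r <- stratifyBySize(nodes)
  expect_equal(unname(r), c(1, 1, 1))
  # boundary: exactly 10 goes to the 10-20 group
  nodes2 <- data.frame(sad_mm = c(10, 9.999), detected = c(TRUE, FALSE))
  r2 <- stratifyBySize(nodes2)
  expect_equal(unname(r2["10-20"]), 1)
  expect_equal(unname(r2["5-10"]), 0)
  # nodes under 5 mm never count
  nodes3 <- data.frame(sad_mm = c(3, 7), detected = c(FALSE, TRUE))
  r3 <- stratifyBySize(nodes3)
  expect_equal(unname(r3["5-10"]), 1)
  # random tables equal a brute-force binning pass
  set.seed(8)
  for (i in 1:20) {
    tab <- data.frame(sad_mm = runif(40, 2, 30),
                      detected = runif(40) < 0.6)
    r <- stratifyBySize(tab)
    for (grp in list(c(5, 10, "5-10"), c(10, 20, "10-20"),
                     c(20, Inf, ">20"))) {
      lo <- as.numeric(grp[1]); hi <- as.numeric(grp[2])
      sel <- tab$sad_mm >= lo & tab$sad_mm < hi
      expected <- if (!any(sel)) NA_real_ else
        sum(tab$detected[sel]) / sum(sel)
      expect_equal(unname(r[grp[3]]), expected)
    }
  }
})

test_that("stratified rates recombine exactly to the overall rate", {
  set.seed(9)
  tab <- data.frame(sad_mm = runif(60, 5, 30), detected = runif(60) < 0.7)
  r <- stratifyBySize(tab)
  counts <- table(cut(tab$sad_mm, c(5, 10, 20, Inf), right = FALSE))
  weighted <- sum(r * as.integer(counts), na.rm = TRUE) / sum(counts)
  expect_equal(weighted, mean(tab$detected))
})

test_that("bootstrap rate SD is seeded and matches the binomial closed form", {
  expect_equal(bootstrapRateSD(rep(TRUE, 20), nSim = 200, seed = 1), 0)
  s1 <- bootstrapRateSD(c(1, 0, 1, 1, 0), nSim = 500, seed = 42)
  s2 <- bootstrapRateSD(c(1, 0, 1, 1, 0), nSim = 500, seed = 42)
  expect_identical(s1, s2)
  expect_error(bootstrapRateSD(logical(0)), "empty")
})

test_that("rate comparison is a symmetric two-sided Welch test", {
  a <- c(rep(1, 7), rep(0, 3))
  b <- c(rep(1, 4), rep(0, 6))
  p <- compareRates(a, b)
  # textbook Welch formula evaluated independently
  welch <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
  }
  expect_equal(p, welch(a, b), tolerance = 1e-12)
  expect_equal(compareRates(b, a), p)
  expect_equal(compareRates(a, a), 1)
  expect_warning(pNA <- compareRates(c(1, 1, 1), c(0, 0, 0)), "degenerate")
  expect_true(is.na(pNA))
  expect_error(compareRates(1, c(0, 1)), "at least 2")
})

test_that("removing FP components never lowers matched-mask PPV and adding
           an overlapping component never lowers the detection rate", {
  set.seed(17)
  for (rep in 1:10) {
    d <- c(14, 14, 8)
    gtBin <- randomBlobMask(d, 3, p = 0.5)
    gtLab <- bruteFloodFill(gtBin, 26)
    predBin <- randomBlobMask(d, 4, p = 0.5)
    gtCS <- labeledComponents(LabelMask(gtLab, 1.5))
    prCS <- connectedComponents(LabelMask(predBin, 1.5))
    m <- matchComponents(gtCS, prCS)
    ppv0 <- matchedSegMetrics(gtCS, prCS, m)$ppv
    # drop one FP component, if any
    fp <- which(!m$predMatched)
    if (length(fp)) {
      pred2 <- predBin
      pred2[prCS@components[[fp[1]]]$voxels] <- 0L
      prCS2 <- connectedComponents(LabelMask(pred2, 1.5))
      ppv1 <- matchedSegMetrics(gtCS, prCS2)$ppv
      if (!is.na(ppv0) && !is.na(ppv1)) expect_gte(ppv1, ppv0)
    }
    # add a component overlapping a missed node, if any
    missed <- which(!m$gtDetected)
    if (length(missed) && nComponents(gtCS) > 0) {
      rate0 <- detectionRate(m$gtDetected)
      vox <- gtCS@components[[missed[1]]]$voxels[1]
      pred3 <- predBin
      pred3[vox] <- 1L
      m3 <- matchComponents(gtCS,
                            connectedComponents(LabelMask(pred3, 1.5)))
      expect_gte(detectionRate(m3$gtDetected), rate0)
    }
  }
})

test_that("evaluateDetection aggregates volumes with node-table overrides", {
  phs <- lapply(c(61, 62), function(s)
    generatePhantom(phantomSpec(shape = 40, nLesions = 3,
                                sadRange = c(6, 14), seed = s)))
  gts <- lapply(phs, `[[`, "mask")
  # prediction: perfect for volume 1, empty plus one FP blob for volume 2
  pred1 <- asBinaryMask(gts[[1]])
  p2 <- array(0L, dim(volData(gts[[2]])))
  p2[2:3, 2:3, 2:3] <- 1L
  pred2 <- LabelMask(p2, voxelSpacing(gts[[2]]))
  rep <- evaluateDetection(gts, list(pred1, pred2),
                           lapply(phs, `[[`, "nodes"))
  expect_equal(rep@detectionRate, 0.5)
  expect_equal(rep@fpPerVolume, 0.5)
  expect_equal(rep@fpCount, c(0, 1))
  pn <- rep@perNode
  expect_identical(nrow(pn), 6L)
  # node-table SADs override computed ones exactly
  expect_equal(pn$sad_mm[pn$volume == 1], phs[[1]]$nodes$sad_mm)
  expect_equal(rep@segMetrics$dice[1], 1)
  expect_true(is.na(rep@segMetrics$dice[2]))
  # JSON + CSV output round-trips
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  writeDetectionReport(rep, jf, cf)
  js <- jsonlite::read_json(jf)
  expect_equal(js$detection_rate, 0.5)
  expect_identical(nrow(read.csv(cf)), 6L)
  unlink(c(jf, cf))
})
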