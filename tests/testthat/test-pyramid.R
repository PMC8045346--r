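test_that("a one-level pyramid equals the plain crop", {
  set.seed(3)
  vol <- CTVolume(array(rnorm(24^3), c(24, 24, 24)), spacing = 1.5)
  center <- (c(12, 12, 12) - 1) * 1.5 # voxel 12 exactly
  pyr <- extractPyramid(vol, center, patchVoxels = 8, levels = 1)
  expect_length(pyr@patches, 1L)
  crop <- volData(vol)[12 + (-3:4) - 0, 12 + (-3:4), 12 + (-3:4)]
  # patch grid: center voxel at index (P-1)/2 (0-based) = 3.5 -> the 8
  # samples land on voxels 12-3.5..12+3.5, i.e. between grid points
  expect_identical(dim(pyr@patches[[1]]), c(8L, 8L, 8L))
  # use an odd-size patch so samples land exactly on voxels
  pyr9 <- extractPyramid(vol, center, patchVoxels = 9, levels = 1)
  crop9 <- volData(vol)[12 + (-4:4), 12 + (-4:4), 12 + (-4:4)]
  expect_equal(pyr9@patches[[1]], crop9, ignore_attr = TRUE)
})

test_that("constant volumes give constant patches at every level", {
  vol <- CTVolume(array(5, c(32, 32, 32)), spacing = 1.5)
  pyr <- extractPyramid(vol, c(20, 20, 20), patchVoxels = 8, levels = 4,
                        pad = 5)
  for (p in pyr@patches) expect_lt(max(abs(p - 5)), 1e-12)
})

test_that("pyramid levels cover geometrically increasing physical extents", {
  # ramp volume f(x) = world x coordinate; trilinear sampling reproduces
  # the sample position, so patch corners reveal their world coordinates
  d <- c(96, 24, 24)
  sp <- 1.5
  ramp <- array(rep((seq_len(d[1]) - 1) * sp, times = d[2] * d[3]), d)
  vol <- CTVolume(ramp, spacing = sp)
  center <- c(70, 16, 16)
  P <- 8
  pyr <- extractPyramid(vol, center, patchVoxels = P, levels = 4, factor = 2,
                        pad = -9999)
  for (l in 1:4) {
    scale <- 2^(l - 1)
    firstX <- pyr@patches[[l]][1, 4, 4]
    lastX <- pyr@patches[[l]][P, 4, 4]
    expect_equal(firstX, center[1] - (P - 1) / 2 * scale * sp,
                 tolerance = 1e-8)
    expect_equal(lastX, center[1] + (P - 1) / 2 * scale * sp,
                 tolerance = 1e-8)
    # sample-to-sample physical step = scale * spacing; with the voxel
    # extent the level covers P * scale * sp mm: 12/24/48/96 mm here
    expect_equal(lastX - firstX + scale * sp, P * scale * sp)
  }
})

test_that("coarse pyramid levels match pyramids of pre-downscaled volumes", {
  # smooth field so the two interpolation supports agree closely
  d <- c(48, 48, 48)
  g <- (seq_len(48) - 1) * 1.5
  f <- outer(outer(sin(g / 9), cos(g / 7)), sin(g / 11) + 1)
  vol <- CTVolume(array(f, d), spacing = 1.5)
  half <- resampleIsotropic(vol, 3.0)
  set.seed(11)
  for (i in 1:10) {
    center <- runif(3, 24, 48)
    p2 <- extractPyramid(vol, center, 8, levels = 2, pad = 0)@patches[[2]]
    p1 <- extractPyramid(CTVolume(volData(half), spacing = 1.5),
                         center / 2, 8, levels = 1,
                         pad = 0)@patches[[1]]
    # level 2 of the full-res pyramid samples the same world points as
    # level 1 of a pyramid on the pre-downscaled volume
    expect_lt(max(abs(p2 - p1)), 0.1)
  }
})

test_that("out-of-volume pyramid regions use the pad value", {
  vol <- CTVolume(array(1, c(16, 16, 16)), spacing = 1.5)
  pyr <- extractPyramid(vol, c(0, 0, 0), patchVoxels = 8, levels = 2,
                        pad = -7)
  expect_true(any(pyr@patches[[1]] == -7))
  expect_true(any(pyr@patches[[2]] == -7))
  expect_true(all(pyr@patches[[1]] %in% c(-7, 1) |
                    (pyr@patches[[1]] > -7 & pyr@patches[[1]] < 1)))
})

test_that("sampleCenters honors the lesion fraction and is reproducible", {
  ph <- generatePhantom(phantomSpec(shape = 48, nLesions = 4,
                                    sadRange = c(6, 12), seed = 21))
  mask <- ph$mask
  containsLesion <- function(center) {
    lab <- extractLabelPatch(mask, center, patchVoxels = 16, outSize = 16,
                             outOffset = 0)
    any(lab > 0)
  }
  # fraction 1: every patch contains foreground
  c1 <- sampleCenters(mask, 50, lesionFraction = 1, innerVoxels = 16,
                      seed = 1)
  expect_true(all(apply(c1, 1, containsLesion)))
  # fraction 0.3 over n = 1000: post-hoc count meets the bound exactly
  c3 <- sampleCenters(mask, 1000, lesionFraction = 0.3, innerVoxels = 16,
                      seed = 2)
  frac <- mean(apply(c3, 1, containsLesion))
  expect_gte(frac, 0.3)
  # fraction 0 works on an empty mask; fraction > 0 errors
  empty <- LabelMask(array(0L, c(20, 20, 20)), 1.5)
  expect_silent(sampleCenters(empty, 10, lesionFraction = 0, seed = 3))
  expect_error(sampleCenters(empty, 10, lesionFraction = 0.3, seed = 3),
               "non-empty mask")
  # reproducibility
  expect_identical(sampleCenters(mask, 40, seed = 9),
                   sampleCenters(mask, 40, seed = 9))
})

test_that("augmentation transforms are bounded similarity maps", {
  set.seed(5)
  cfg <- augmentConfig(maxScale = 1.1, maxRotationDeg = 7)
  for (i in 1:50) {
    A <- drawAugmentTransform(cfg)
    s <- det(A)^(1 / 3)
    expect_gte(s, 1 / 1.1 - 1e-9)
    expect_lte(s, 1.1 + 1e-9)
    # A / s is a rotation: orthogonal with unit determinant
    R <- A / s
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    # rotation angle within 7 degrees
    ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    expect_lte(ang, 7 + 1e-6)
  }
  expect_identical(drawAugmentTransform(augmentConfig(enabled = FALSE)),
                   diag(3))
})

test_that("augmentation at zero magnitude is the identity and preserves ids", {
  ph <- generatePhantom(phantomSpec(shape = 40, nLesions = 3,
                                    sadRange = c(6, 10), seed = 31))
  img <- volData(ph$volume)[5:36, 5:36, 5:36]
  lab <- volData(ph$mask)[5:36, 5:36, 5:36]
  idcfg <- augmentConfig(maxScale = 1, maxRotationDeg = 0)
  out <- augmentPatch(img, lab, idcfg)
  expect_equal(out$image, img, ignore_attr = TRUE)
  expect_identical(as.integer(out$labels), as.integer(lab))
  set.seed(77)
  for (i in 1:20) {
    out <- augmentPatch(img, lab, augmentConfig())
    expect_true(all(unique(as.vector(out$labels)) %in%
                      unique(as.vector(lab))))
  }
})
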