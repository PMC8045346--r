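test_that("NIfTI and MetaImage round-trips preserve data and geometry", {
  vol <- CTVolume(array(rnorm(6 * 5 * 4, 40, 100), c(6, 5, 4)),
                  spacing = c(1, 1.5, 3), origin = c(10, -20, 5.5))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    writeVolume(vol, f)
    back <- readVolume(f)
    expect_equal(volData(back), volData(vol), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(voxelSpacing(back), voxelSpacing(vol), tolerance = 1e-6)
    expect_equal(volOrigin(back), volOrigin(vol), tolerance = 1e-5)
    unlink(f)
    if (ext == ".mhd") unlink(sub("\\.mhd$", ".raw", f))
  }
  # masks round-trip exactly (integer storage)
  mask <- LabelMask(array(sample(0:3, 60, TRUE), c(5, 4, 3)), 1.5)
  for (ext in c(".nii.gz", ".mha")) {
    f <- tempfile(fileext = ext)
    writeVolume(mask, f)
    back <- readVolume(f, mask = TRUE)
    expect_identical(volData(back), volData(mask))
    unlink(f)
  }
})

test_that("readVolume rejects missing files, non-3D data and unknown formats", {
  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2, 3))), f)
  expect_error(readVolume(f), "non-3D")
  f2 <- tempfile(fileext = ".txt")
  writeLines("hello", f2)
  expect_error(readVolume(f2), "unsupported format")
})

test_that("isotropic resampling honors the shape rule and preserves content", {
  # per-axis shape: round(n * s / 1.5)
  vol <- CTVolume(array(rnorm(90 * 90 * 45), c(90, 90, 45)),
                  spacing = c(1, 1, 3))
  out <- resampleIsotropic(vol, 1.5)
  expect_identical(dim(volData(out)), c(60L, 60L, 90L))
  expect_equal(voxelSpacing(out), rep(1.5, 3))

  # already at target spacing: interpolation identity
  v2 <- CTVolume(array(rnorm(10^3), c(10, 10, 10)), spacing = 1.5)
  expect_equal(volData(resampleIsotropic(v2, 1.5)), volData(v2))

  # constant volume stays constant at the new shape
  v3 <- CTVolume(array(7, c(9, 9, 9)), spacing = c(1, 2, 1))
  out3 <- resampleIsotropic(v3, 1.5)
  expect_identical(dim(volData(out3)), c(6L, 12L, 6L))
  expect_true(all(volData(out3) == 7))

  expect_error(resampleIsotropic(vol, -1), "positive")
})

test_that("nearest-neighbor resampling commutes with monotone pointwise maps", {
  set.seed(7)
  mask <- LabelMask(array(sample(0:4, 8 * 6 * 10, TRUE), c(8, 6, 10)),
                    spacing = c(1, 2, 1))
  f <- function(x) 3 * x + 1 # monotone
  a <- volData(resampleIsotropic(LabelMask(f(volData(mask)),
                                           voxelSpacing(mask)), 1.5))
  b <- f(volData(resampleIsotropic(mask, 1.5)))
  expect_identical(as.integer(a), as.integer(b))
})

test_that("window estimation matches brute-force statistics on enumerated voxels", {
  set.seed(42)
  for (rep in 1:50) {
    d <- c(sample(6:10, 1), sample(6:10, 1), sample(6:10, 1))
    vol <- CTVolume(array(rnorm(prod(d), 30, 50), d))
    m <- array(0L, d)
    m[sample(prod(d), sample(1:5, 1))] <- 1L
    mask <- LabelMask(m)
    # radius 0: labeled voxels only
    w0 <- estimateWindow(vol, mask, neighborhoodRadius = 0)
    vals <- volData(vol)[m > 0]
    expect_equal(windowLevel(w0), mean(vals))
    expect_equal(windowWidth(w0),
                 2 * 3 * (if (length(vals) > 1) sd(vals) else 0))
    # radius 1: explicit 26-neighborhood enumeration
    sel <- array(FALSE, d)
    for (v in which(m > 0)) {
      ci <- arrayInd(v, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        ni <- ci + c(dx, dy, dz)
        if (all(ni >= 1) && all(ni <= d)) sel[ni[1], ni[2], ni[3]] <- TRUE
      }
    }
    w1 <- estimateWindow(vol, mask, neighborhoodRadius = 1)
    expect_equal(windowLevel(w1), mean(volData(vol)[sel]))
    expect_equal(windowWidth(w1), 6 * sd(volData(vol)[sel]))
  }
})

test_that("window estimation handles zero variance and empty masks", {
  vol <- CTVolume(array(70, c(5, 5, 5)))
  mask <- LabelMask(array(1L, c(5, 5, 5)))
  w <- estimateWindow(vol, mask)
  expect_equal(windowLevel(w), 70)
  expect_equal(windowWidth(w), 0)
  expect_error(estimateWindow(vol, LabelMask(array(0L, c(5, 5, 5)))),
               "no labeled voxels")
})

test_that("windowing clips to the level +/- width/2 range and is idempotent", {
  w <- softTissueWindow() # level 70, width 750
  vol <- CTVolume(array(c(500, -400, 0, 70), c(4, 1, 1)))
  out <- volData(applyWindow(vol, w))
  expect_equal(out[1, 1, 1], 445) # 70 + 375
  expect_equal(out[2, 1, 1], -305) # 70 - 375
  expect_equal(out[3, 1, 1], 0) # inside the window
  expect_equal(out[4, 1, 1], 70)
  set.seed(1)
  v2 <- CTVolume(array(rnorm(200, 0, 600), c(10, 10, 2)))
  once <- applyWindow(v2, w)
  expect_identical(volData(applyWindow(once, w)), volData(once))
  # normalization maps the window to [-1, 1]
  nz <- normalizeToWindow(v2, w)
  expect_true(all(volData(nz) >= -1 & volData(nz) <= 1))
  expect_equal(volData(nz)[1], (volData(once)[1] - 70) / 375)
})
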