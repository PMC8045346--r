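#' Extract a multiscale foveal patch pyramid
#'
#' Builds `levels` co-centered 3D patches of identical voxel dimensions.
#' Level 1 (finest) is a direct crop of `patchVoxels^3` around `center`;
#' level `l` covers `factor^(l-1)` times the physical extent, downscaled
#' to the same voxel grid by trilinear sampling.  Regions outside the
#' volume are padded with `pad` (at training time, the window's lower
#' clamp value).
#'
#' An optional 3x3 `transform` (see [drawAugmentTransform()]) is applied
#' to the sampling grid about the patch center, which is how on-the-fly
#' augmentation reaches the network without border loss.
#'
#' @param vol an isotropic [CTVolume-class].
#' @param center world mm 3-vector of the patch center.
#' @param patchVoxels patch edge length in voxels (default 32).
#' @param levels number of resolution levels (default 4).
#' @param factor physical downscale factor between levels (default 2).
#' @param pad value for out-of-volume samples (default: volume minimum).
#' @param transform optional 3x3 matrix mapping patch-grid offsets to
#'   volume-grid offsets (default identity).
#' @return A [PatchPyramid-class].
#' @export
extractPyramid <- function(vol, center, patchVoxels = 32, levels = 4,
                           factor = 2, pad = NULL, transform = NULL) {
  stopifnot(is(vol, "CTVolume"), length(center) == 3L,
            .isCount(patchVoxels, 2), .isCount(levels, 1), factor > 1 ||
              levels == 1L)
  sp <- vol@spacing
  if (diff(range(sp)) > 1e-6 * sp[1])
    stop("extractPyramid requires an isotropic volume; resample first")
  if (is.null(pad)) pad <- min(vol@data)
  A <- if (is.null(transform)) diag(3) else transform
  d <- dim(vol@data)
  c0 <- (center - vol@origin) / sp          # 0-based continuous index
  half <- (patchVoxels - 1) / 2
  patches <- vector("list", levels)
  for (l in seq_len(levels)) {
    M <- A * factor^(l - 1)
    t0 <- c0 - M %*% rep(half, 3)
    patches[[l]] <- .affineSample(as.numeric(vol@data), as.integer(d),
                                  rep(as.integer(patchVoxels), 3L),
                                  M, as.numeric(t0), 0L, pad, 0L)
  }
  new("PatchPyramid", patches = patches, center = as.numeric(center),
      levelScale = factor^(seq_len(levels) - 1), spacing = sp,
      labelPatch = NULL)
}

#' Extract the label patch aligned with a network's valid-output region
#'
#' Samples the mask (nearest-neighbor, 0-padded) on the finest-level
#' patch grid restricted to the valid-output region of size `outSize`
#' starting `outOffset` voxels into the patch (see [fnetShapes()]).
#'
#' @param mask a [LabelMask-class].
#' @param center,patchVoxels,transform as in [extractPyramid()].
#' @param outSize valid-output edge length in voxels.
#' @param outOffset voxel offset of the valid-output region within the
#'   finest-level patch.
#' @return 3D integer array of size `outSize^3`.
#' @export
extractLabelPatch <- function(mask, center, patchVoxels, outSize, outOffset,
                              transform = NULL) {
  stopifnot(is(mask, "LabelMask"), length(center) == 3L)
  sp <- mask@spacing
  A <- if (is.null(transform)) diag(3) else transform
  d <- dim(mask@data)
  c0 <- (center - mask@origin) / sp
  half <- (patchVoxels - 1) / 2
  t0 <- c0 + A %*% rep(outOffset - half, 3)
  out <- .affineSample(as.numeric(mask@data), as.integer(d),
                       rep(as.integer(outSize), 3L), A, as.numeric(t0),
                       1L, 0, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Sample training patch centers under the lesion-fraction rule
#'
#' At least `ceiling(lesionFraction * n)` of the returned centers are
#' placed on (jittered around) foreground voxels, so their patch
#' contains at least one lesion voxel; the remaining centers are drawn
#' uniformly over the volume.  The jitter keeps the chosen foreground
#' voxel inside the central `innerVoxels` region of the patch (use the
#' network's valid-output size so lesion voxels fall in the supervised
#' region).
#'
#' @param mask a [LabelMask-class].
#' @param n number of centers.
#' @param lesionFraction minimum fraction of lesion-containing patches
#'   (default 0.3).
#' @param innerVoxels edge length of the region the foreground voxel is
#'   kept within (default 16).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return `n` x 3 matrix of world mm centers, in randomized order.
#' @export
sampleCenters <- function(mask, n, lesionFraction = 0.3, innerVoxels = 16,
                          seed = NULL) {
  stopifnot(is(mask, "LabelMask"), .isCount(n, 1),
            lesionFraction >= 0, lesionFraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(mask@data)
  sp <- mask@spacing
  fg <- which(mask@data > 0L)
  nLes <- min(n, ceiling(lesionFraction * n))
  if (nLes > 0 && !length(fg))
    stop("lesionFraction > 0 requires a non-empty mask")
  centers <- matrix(NA_real_, n, 3)
  if (nLes > 0) {
    pick <- fg[sample.int(length(fg), nLes, replace = TRUE)]
    coords <- arrayInd(pick, d) - 1L
    half <- max(0, floor(innerVoxels / 2) - 1)
    jit <- matrix(runif(3 * nLes, -half, half), nLes, 3)
    centers[seq_len(nLes), ] <-
      sweep((coords + jit) %*% diag(sp), 2, mask@origin, `+`)
  }
  if (n > nLes) {
    pick <- sample.int(prod(d), n - nLes, replace = TRUE)
    coords <- arrayInd(pick, d) - 1L
    centers[(nLes + 1):n, ] <-
      sweep(coords %*% diag(sp), 2, mask@origin, `+`)
  }
  centers[sample.int(n), , drop = FALSE]
}

#' Configure on-the-fly augmentation
#'
#' Bounded random similarity transforms: a scale factor drawn uniformly
#' in `[1/maxScale, maxScale]` and a rotation by an angle uniform in
#' `[-maxRotationDeg, maxRotationDeg]` about a uniformly random 3D axis.
#' The defaults are the training bounds: maximal scaling 1.1 and
#' maximal rotation 7 degrees (stronger augmentation degraded
#' performance in the source study and is deliberately not offered).
#'
#' @param maxScale maximal scale factor, `>= 1` (default 1.1).
#' @param maxRotationDeg maximal rotation in degrees (default 7).
#' @param enabled logical; `FALSE` yields the identity transform.
#' @return A list of class `"AugmentConfig"`.
#' @export
augmentConfig <- function(maxScale = 1.1, maxRotationDeg = 7,
                          enabled = TRUE) {
  stopifnot(maxScale >= 1, maxRotationDeg >= 0)
  structure(list(maxScale = maxScale, maxRotationDeg = maxRotationDeg,
                 enabled = isTRUE(enabled)), class = "AugmentConfig")
}

#' Draw one random augmentation transform
#'
#' @param cfg an [augmentConfig()].
#' @return 3x3 matrix combining the rotation and (isotropic) scaling;
#'   the identity when augmentation is disabled or both bounds are
#'   degenerate.
#' @export
drawAugmentTransform <- function(cfg) {
  stopifnot(inherits(cfg, "AugmentConfig"))
  if (!cfg$enabled) return(diag(3))
  s <- runif(1, 1 / cfg$maxScale, cfg$maxScale)
  theta <- runif(1, -cfg$maxRotationDeg, cfg$maxRotationDeg) * pi / 180
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  s * R
}

#' Augment an image/label patch pair in place
#'
#' Applies one randomly drawn bounded similarity transform about the
#' patch center, identically to the image (trilinear) and the labels
#' (nearest-neighbor), so label ids are preserved (no new ids can
#' appear).  With `maxScale = 1` and `maxRotationDeg = 0` the output
#' equals the input exactly.
#'
#' @param image 3D numeric array.
#' @param labels 3D integer array aligned with `image`, or `NULL`.
#' @param cfg an [augmentConfig()].
#' @param pad image padding value (default: image minimum); labels pad
#'   with 0.
#' @return List with `image`, `labels` and the 3x3 `transform` used.
#' @export
augmentPatch <- function(image, labels = NULL, cfg = augmentConfig(),
                         pad = NULL) {
  stopifnot(length(dim(image)) == 3L)
  if (!is.null(labels) && !identical(dim(labels), dim(image)))
    stop("image and label regions are not aligned")
  A <- drawAugmentTransform(cfg)
  d <- dim(image)
  ctr <- (d - 1) / 2
  t0 <- ctr - A %*% ctr
  if (is.null(pad)) pad <- min(image)
  img <- .affineSample(as.numeric(image), as.integer(d), as.integer(d),
                       A, as.numeric(t0), 0L, pad, 0L)
  lab <- NULL
  if (!is.null(labels)) {
    lab <- .affineSample(as.numeric(labels), as.integer(d), as.integer(d),
                         A, as.numeric(t0), 1L, 0, 0L)
    storage.mode(lab) <- "integer"
  }
  list(image = img, labels = lab, transform = A)
}
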