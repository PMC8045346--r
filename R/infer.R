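#' Configure whole-volume inference
#'
#' @param threshold probability threshold for the foreground class
#'   (default 0.4); voxels with probability `>= threshold` become
#'   foreground (boundary inclusive).
#' @param tileStride stride between tile valid-output regions, in
#'   voxels; `NULL` (default) uses the valid-output size, i.e.
#'   non-overlapping interiors.  Overlapping predictions are averaged.
#' @param connectivity 3D neighborhood for component extraction: 6, 18
#'   or 26 (default 26).
#' @param minComponentVoxels drop predicted components smaller than
#'   this (default 1 = keep everything; false positives are reported
#'   unfiltered by default).
#' @param patchVoxels inference patch edge length; `NULL` uses the
#'   model's training patch size.  Larger patches reduce tiling
#'   overhead (the network is fully convolutional).
#' @param batchTiles tiles per forward batch (default 16).
#' @return A list of class `"InferConfig"`.
#' @export
inferConfig <- function(threshold = 0.4, tileStride = NULL,
                        connectivity = 26, minComponentVoxels = 1,
                        patchVoxels = NULL, batchTiles = 16) {
  stopifnot(threshold > 0, threshold < 1,
            connectivity %in% c(6, 18, 26),
            .isCount(minComponentVoxels, 1), .isCount(batchTiles, 1))
  structure(list(threshold = threshold, tileStride = tileStride,
                 connectivity = as.integer(connectivity),
                 minComponentVoxels = as.integer(minComponentVoxels),
                 patchVoxels = patchVoxels,
                 batchTiles = as.integer(batchTiles)),
            class = "InferConfig")
}

#' Predict a whole-volume probability map by tiled inference
#'
#' The volume is resampled to the model's isotropic grid if needed,
#' windowed and normalized with the training-time window, and covered
#' by patch tiles whose valid-output regions span every voxel;
#' overlapping predictions are averaged.  Out-of-volume patch regions
#' are padded with the window's lower clamp value.
#'
#' @param model a trained [FnetModel-class] (or any [FnetModel-class];
#'   without preprocessing state the volume is used as-is).
#' @param vol a [CTVolume-class].
#' @param cfg an [inferConfig()].
#' @return A [ProbabilityMap-class] covering the full (resampled)
#'   volume.
#' @export
predictVolume <- function(model, vol, cfg = inferConfig()) {
  stopifnot(is(model, "FnetModel"), is(vol, "CTVolume"))
  fcfg <- structure(model@config, class = "FnetConfig")
  pp <- model@preprocess
  if (!is.null(pp$spacing) &&
      max(abs(vol@spacing - pp$spacing)) > 1e-6 * pp$spacing[1])
    vol <- resampleIsotropic(vol, pp$spacing[1])
  pad <- -1
  if (!is.null(pp$window)) {
    vol <- normalizeToWindow(vol, pp$window)
  } else {
    pad <- min(vol@data)
  }
  P <- cfg$patchVoxels %||% pp$patchVoxels %||% 32L
  sh <- fnetShapes(fcfg, P)
  O <- sh$outputSize
  d <- dim(vol@data)
  if (any(d < O))
    stop("volume (", paste(d, collapse = "x"),
         ") smaller than one valid tile (", O, "^3)")
  stride <- cfg$tileStride %||% O
  stride <- max(1L, min(as.integer(stride), O))
  starts <- lapply(d, function(n) {
    s <- seq(0L, n - O, by = stride)
    if (s[length(s)] != n - O) s <- c(s, n - O)
    s
  })
  tiles <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  sp <- vol@spacing
  half <- (P - 1) / 2
  probSum <- array(0, c(d, fcfg$nClasses))
  cnt <- array(0, d)
  L <- fcfg$levels
  for (g in split(seq_len(nrow(tiles)),
                  ceiling(seq_len(nrow(tiles)) / cfg$batchTiles))) {
    nb <- length(g)
    xlev <- lapply(seq_len(L), function(l) array(0, c(P, P, P, 1, nb)))
    for (j in seq_len(nb)) {
      s0 <- tiles[g[j], ] - sh$outputOffset
      center <- vol@origin + (s0 + half) * sp
      pyr <- extractPyramid(vol, center, P, L, fcfg$factor, pad = pad)
      for (l in seq_len(L)) xlev[[l]][, , , 1, j] <- pyr@patches[[l]]
    }
    fw <- .fnetForward(model@params, fcfg, xlev, train = FALSE)
    for (j in seq_len(nb)) {
      s <- tiles[g[j], ]
      ix <- s[1] + seq_len(O); iy <- s[2] + seq_len(O); iz <- s[3] + seq_len(O)
      probSum[ix, iy, iz, ] <- probSum[ix, iy, iz, ] +
        fw$probs[, , , , j, drop = TRUE]
      cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
    }
  }
  probs <- probSum / as.numeric(cnt)
  new("ProbabilityMap", data = probs, spacing = sp, origin = vol@origin,
      offset = c(0L, 0L, 0L))
}

#' Threshold a probability map into a binary mask
#'
#' A voxel is foreground iff its foreground-class probability is
#' `>= threshold` (boundary inclusive).  Monotone: raising the
#' threshold never adds foreground voxels.
#'
#' @param pm a [ProbabilityMap-class].
#' @param threshold scalar in (0, 1); default 0.4, the fixed operating
#'   threshold of the pipeline.
#' @return A binary [LabelMask-class].
#' @export
segmentProbability <- function(pm, threshold = 0.4) {
  stopifnot(is(pm, "ProbabilityMap"), threshold > 0, threshold < 1)
  fg <- .foregroundProb(pm)
  LabelMask(array(as.integer(fg >= threshold), dim(fg)), pm@spacing,
            pm@origin)
}

#' Connected components of a binary mask
#'
#' Maximal connected voxel sets under the chosen 3D connectivity, with
#' ids assigned in linear scan order.  Each component carries its voxel
#' list, volume, world centroid and estimated short-axis diameter.
#'
#' @param mask a binary [LabelMask-class] (values 0/1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param minVoxels discard components smaller than this (default 1).
#' @return A [ComponentSet-class].
#' @export
connectedComponents <- function(mask, connectivity = 26, minVoxels = 1) {
  stopifnot(is(mask, "LabelMask"), connectivity %in% c(6, 18, 26))
  if (any(mask@data > 1L))
    stop("non-binary input: use asBinaryMask() or labeledComponents()")
  lab <- .labelComponents(mask@data, as.integer(dim(mask@data)),
                          as.integer(connectivity))
  .componentsFromLabels(lab, mask@spacing, minVoxels)
}

#' Components of an integer-labeled ground-truth mask
#'
#' Uses the stored node ids directly (no connectivity analysis), so
#' annotated nodes stay distinct even when they touch.
#'
#' @param mask a [LabelMask-class] with positive node ids.
#' @return A [ComponentSet-class] with one component per id, in id
#'   order.
#' @export
labeledComponents <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  .componentsFromLabels(mask@data, mask@spacing, 1L)
}

.componentsFromLabels <- function(lab, spacing, minVoxels) {
  d <- dim(lab)
  fg <- which(lab > 0L)
  comps <- list()
  if (length(fg)) {
    byId <- split(fg, lab[fg])
    ids <- as.integer(names(byId))
    ord <- order(ids)
    newId <- 0L
    for (i in ord) {
      vox <- byId[[i]]
      if (length(vox) < minVoxels) next
      newId <- newId + 1L
      coords <- arrayInd(vox, d)
      comps[[newId]] <- list(
        id = newId, voxels = vox, nVoxels = length(vox),
        centroid = (colMeans(coords) - 1) * spacing,
        sad = sadOfComponent(vox, d, spacing))
    }
  }
  new("ComponentSet", components = comps, dim = as.integer(d),
      spacing = spacing)
}
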