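#' Configure network training
#'
#' Patch-based cross-entropy training with the AdaDelta optimizer.
#' The published schedule is 1000 epochs with minibatch size 8; the
#' default here keeps the minibatch and optimizer but a desk-scale
#' epoch count, since an "epoch" is `patchesPerEpoch` randomly drawn
#' patches rather than a full pass over a fixed patch set.
#'
#' @param epochs number of epochs (default 50).
#' @param minibatch minibatch size (default 8).
#' @param rho AdaDelta decay rate (default 0.95).
#' @param eps AdaDelta conditioning constant (default 1e-6).
#' @param patchesPerEpoch patches drawn per epoch (default 100).
#' @param lesionFraction minimum fraction of lesion-containing patches
#'   (default 0.3).
#' @param augment an [augmentConfig()].
#' @param classWeights optional per-class cross-entropy weights.
#' @param seed integer seed driving all training randomness.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 50, minibatch = 8, rho = 0.95, eps = 1e-6,
                        patchesPerEpoch = 100, lesionFraction = 0.3,
                        augment = augmentConfig(), classWeights = NULL,
                        seed = 1L) {
  stopifnot(.isCount(epochs), .isCount(minibatch, 1),
            .isCount(patchesPerEpoch, 1),
            lesionFraction >= 0, lesionFraction <= 1,
            rho > 0, rho < 1, eps > 0, inherits(augment, "AugmentConfig"))
  structure(list(epochs = as.integer(epochs),
                 minibatch = as.integer(minibatch), rho = rho, eps = eps,
                 patchesPerEpoch = as.integer(patchesPerEpoch),
                 lesionFraction = lesionFraction, augment = augment,
                 classWeights = classWeights, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Mean cross-entropy over a probability map
#'
#' `-log p(true class)` averaged over voxels, with probabilities clamped
#' at 1e-7 so the loss stays finite.  Uniform two-class probabilities
#' give `log(2)` per voxel; exact one-hot prediction gives 0.
#'
#' @param probs array of class probabilities whose last dimension (4th,
#'   or 4th-of-5 for batches stored as `(x, y, z, class, sample)`)
#'   indexes the class.
#' @param labels integer array of true classes in `0..nClasses-1`,
#'   matching the non-class dimensions of `probs`.
#' @param classWeights optional numeric length `nClasses`; the loss
#'   becomes the weighted mean with weight `classWeights[label + 1]`.
#' @return Non-negative scalar loss.
#' @export
crossEntropy <- function(probs, labels, classWeights = NULL) {
  dp <- dim(probs)
  if (length(dp) == 4L) {
    nc <- dp[4]
    pm <- matrix(aperm(probs, c(1, 2, 3, 4)), ncol = nc)
  } else if (length(dp) == 5L) {
    nc <- dp[4]
    pm <- matrix(aperm(probs, c(1, 2, 3, 5, 4)), ncol = nc)
  } else stop("probs must be a 4D or 5D array")
  lab <- as.integer(labels)
  if (length(lab) != nrow(pm)) stop("shape mismatch between probs and labels")
  if (any(lab < 0L | lab >= nc)) stop("label out of range 0..", nc - 1L)
  p <- pmax(pm[cbind(seq_len(nrow(pm)), lab + 1L)], 1e-7)
  if (is.null(classWeights)) return(mean(-log(p)))
  stopifnot(length(classWeights) == nc)
  w <- classWeights[lab + 1L]
  sum(w * -log(p)) / sum(w)
}

#' Random balanced cross-validation folds
#'
#' Randomly partitions case ids into `k` folds whose sizes differ by at
#' most one (the fourfold split of the training protocol by default).
#'
#' @param caseIds character or integer vector of case identifiers.
#' @param k number of folds (default 4).
#' @param seed optional seed.
#' @return A list of class `"CVSplit"` with `foldOfCase` (named integer
#'   vector of fold indices in `0..k-1`), `k` and `seed`.
#' @export
makeCVFolds <- function(caseIds, k = 4, seed = NULL) {
  n <- length(caseIds)
  if (n < k) stop("fewer cases (", n, ") than folds (", k, ")")
  if (anyDuplicated(caseIds)) stop("case ids must be unique")
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(floor(n / k), k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- rep.int(seq_len(k) - 1L, sizes)[sample.int(n)]
  names(fold) <- as.character(caseIds)
  structure(list(foldOfCase = fold, k = as.integer(k), seed = seed),
            class = "CVSplit")
}

# elementwise AdaDelta update on the nested parameter list; running
# statistics (buffers) are skipped.
.adadeltaUpdate <- function(params, grads, state, rho, eps) {
  step <- function(p, g, s) {
    s$Eg2 <- rho * s$Eg2 + (1 - rho) * g * g
    delta <- -sqrt(s$Ed2 + eps) / sqrt(s$Eg2 + eps) * g
    s$Ed2 <- rho * s$Ed2 + (1 - rho) * delta * delta
    list(p = p + delta, s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% c("runMean", "runVar")) next
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      if (is.null(names(p)))
        for (i in seq_along(p)) {
          r <- walk(p[[i]], g[[i]], s[[i]])
          p[[i]] <- r$p
          s[[i]] <- r$s
        }
      return(list(p = p, s = s))
    }
    step(p, g, s)
  }
  walk(params, grads, state)
}

.zeroState <- function(params) {
  walk <- function(p) {
    if (is.list(p)) {
      out <- lapply(seq_along(p), function(i) {
        nm <- names(p)[i]
        if (!is.null(nm) && nm %in% c("runMean", "runVar")) return(NULL)
        walk(p[[i]])
      })
      names(out) <- names(p)
      return(out)
    }
    list(Eg2 = p * 0, Ed2 = p * 0)
  }
  walk(params)
}

#' Train a foveal network on preprocessed volume/mask pairs
#'
#' Volumes must already be on the isotropic grid; they are windowed and
#' normalized internally (the window is estimated from the dataset's
#' labeled voxels when not supplied).  Each epoch draws
#' `patchesPerEpoch` patch centers under the lesion-fraction rule,
#' applies one bounded random similarity transform per patch, and
#' optimizes the voxel-wise cross-entropy with AdaDelta.  Fully
#' deterministic given `cfg$seed`.
#'
#' @param dataset list of cases, each a list with elements `volume`
#'   ([CTVolume-class]) and `mask` ([LabelMask-class]).
#' @param cfg a [trainConfig()].
#' @param fnetCfg an [fnetConfig()].
#' @param window a [WindowSpec-class], or `NULL` to estimate it from
#'   the training data via [estimateWindow()] statistics pooled over
#'   cases.
#' @param patchVoxels training patch edge length (default 32).
#' @return List with `model` (an [FnetModel-class] carrying the window,
#'   spacing, patch geometry and an unset threshold) and `history`
#'   (per-epoch mean minibatch loss, length `epochs`).
#' @export
trainModel <- function(dataset, cfg = trainConfig(), fnetCfg = fnetConfig(),
                       window = NULL, patchVoxels = 32) {
  stopifnot(inherits(cfg, "TrainConfig"), inherits(fnetCfg, "FnetConfig"),
            length(dataset) >= 1)
  for (cs in dataset) {
    stopifnot(is(cs$volume, "CTVolume"), is(cs$mask, "LabelMask"))
    if (!identical(dim(cs$volume@data), dim(cs$mask@data)))
      stop("volume/mask shape mismatch in dataset")
  }
  set.seed(cfg$seed)
  if (is.null(window)) window <- .estimateWindowPooled(dataset)
  sh <- fnetShapes(fnetCfg, patchVoxels)
  L <- fnetCfg$levels
  nvols <- lapply(dataset, function(cs) normalizeToWindow(cs$volume, window))
  masks <- lapply(dataset, function(cs) cs$mask)
  model <- buildFnet(fnetCfg)
  params <- model@params
  state <- .zeroState(params)
  nCases <- length(dataset)
  history <- numeric(cfg$epochs)
  nPatch <- cfg$patchesPerEpoch
  for (epoch in seq_len(cfg$epochs)) {
    caseIdx <- sample.int(nCases, nPatch, replace = TRUE)
    isLesion <- logical(nPatch)
    isLesion[sample.int(nPatch, min(nPatch, ceiling(cfg$lesionFraction *
                                                      nPatch)))] <- TRUE
    losses <- numeric(0)
    start <- 1L
    while (start <= nPatch) {
      idx <- start:min(nPatch, start + cfg$minibatch - 1L)
      nb <- length(idx)
      xlev <- lapply(seq_len(L), function(l)
        array(0, c(patchVoxels, patchVoxels, patchVoxels, 1, nb)))
      labels <- array(0L, c(sh$outputSize, sh$outputSize, sh$outputSize, nb))
      for (j in seq_len(nb)) {
        ci <- caseIdx[idx[j]]
        center <- .drawPatchCenter(masks[[ci]], isLesion[idx[j]],
                                   sh$outputSize)
        A <- drawAugmentTransform(cfg$augment)
        pyr <- extractPyramid(nvols[[ci]], center, patchVoxels, L,
                              fnetCfg$factor, pad = -1, transform = A)
        for (l in seq_len(L)) xlev[[l]][, , , 1, j] <- pyr@patches[[l]]
        labels[, , , j] <- pmin(extractLabelPatch(
          masks[[ci]], center, patchVoxels, sh$outputSize,
          sh$outputOffset, transform = A), fnetCfg$nClasses - 1L)
      }
      fw <- .fnetForward(params, fnetCfg, xlev, train = TRUE)
      params <- fw$params
      ce <- .ceLossGrad(fw$probs, as.integer(dim(fw$probs)),
                        as.integer(labels),
                        as.numeric(cfg$classWeights %||% numeric(0)))
      losses <- c(losses, ce$loss)
      grads <- .fnetBackward(params, fnetCfg, fw$cache, ce$dlogits)
      upd <- .adadeltaUpdate(params, grads, state, cfg$rho, cfg$eps)
      params <- upd$p
      state <- upd$s
      start <- start + cfg$minibatch
    }
    history[epoch] <- mean(losses)
  }
  preprocess <- list(window = window, spacing = nvols[[1]]@spacing,
                     patchVoxels = as.integer(patchVoxels),
                     levels = L, factor = fnetCfg$factor,
                     pad = -1, threshold = NA_real_)
  list(model = new("FnetModel", config = unclass(fnetCfg), params = params,
                   preprocess = preprocess),
       history = history)
}

# single training-patch center: a jittered foreground voxel for lesion
# patches, otherwise a uniformly drawn voxel
.drawPatchCenter <- function(mask, lesion, innerVoxels) {
  d <- dim(mask@data)
  sp <- mask@spacing
  if (lesion) {
    fg <- which(mask@data > 0L)
    if (!length(fg)) stop("lesionFraction > 0 requires a non-empty mask")
    pick <- fg[sample.int(length(fg), 1L)]
    half <- max(0, floor(innerVoxels / 2) - 1)
    jit <- runif(3, -half, half)
    as.numeric(mask@origin + ((arrayInd(pick, d)[1, ] - 1L) + jit) * sp)
  } else {
    pick <- sample.int(prod(d), 1L)
    as.numeric(mask@origin + (arrayInd(pick, d)[1, ] - 1L) * sp)
  }
}

.estimateWindowPooled <- function(dataset) {
  vals <- unlist(lapply(dataset, function(cs) {
    sel <- .windowVoxels(cs$mask@data, 1L)
    cs$volume@data[sel]
  }))
  if (!length(vals)) stop("no labeled voxels")
  windowSpec(level = mean(vals), width = 2 * 3 * sd(vals))
}

#' Dice-optimal probability threshold by exhaustive grid search
#'
#' For each grid value, the foreground probability is thresholded and
#' the per-sample foreground Dice against the ground truth computed
#' (both masks empty counts as Dice 1); the value maximizing the mean
#' Dice is returned, with ties broken toward the lowest grid value.
#'
#' @param probMaps list of [ProbabilityMap-class] (or plain 3D
#'   foreground-probability arrays).
#' @param gtMasks list of [LabelMask-class] (or arrays); any positive
#'   voxel is foreground.  Must align with each probability map's valid
#'   region.
#' @param grid candidate thresholds (default `seq(0.05, 0.95, 0.05)`).
#' @return The selected threshold (scalar).
#' @export
selectThreshold <- function(probMaps, gtMasks,
                            grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(probMaps) == length(gtMasks), length(probMaps) >= 1)
  fgProb <- lapply(probMaps, .foregroundProb)
  gt <- lapply(gtMasks, function(m) {
    a <- if (is(m, "LabelMask")) m@data else m
    a > 0
  })
  meanDice <- vapply(grid, function(t) {
    mean(mapply(function(p, g) .diceBinary(p >= t, g), fgProb, gt))
  }, numeric(1))
  grid[which.max(meanDice)]
}

.foregroundProb <- function(pm) {
  if (is(pm, "ProbabilityMap")) {
    d <- dim(pm@data)
    return(pm@data[, , , d[4], drop = TRUE])
  }
  pm
}

.diceBinary <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Optimize the segmentation threshold on a training set
#'
#' Predicts whole-volume probability maps for every case and selects
#' the Dice-optimal grid threshold via [selectThreshold()].  The
#' returned model carries the selected threshold for inference.
#'
#' @param model a trained [FnetModel-class].
#' @param dataset list of cases as in [trainModel()].
#' @param grid candidate thresholds.
#' @param inferCfg an [inferConfig()] controlling the tiled prediction.
#' @return The input model with `preprocess$threshold` set.
#' @export
optimizeThreshold <- function(model, dataset,
                              grid = seq(0.05, 0.95, by = 0.05),
                              inferCfg = inferConfig()) {
  stopifnot(is(model, "FnetModel"), length(dataset) >= 1)
  pms <- lapply(dataset, function(cs) predictVolume(model, cs$volume,
                                                    inferCfg))
  thr <- selectThreshold(pms, lapply(dataset, `[[`, "mask"), grid)
  model@preprocess$threshold <- thr
  model
}
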