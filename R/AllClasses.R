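#' @title Core S4 containers
#' @name fovealCT-classes
#' @description
#' S4 classes carrying the pipeline's data: [CTVolume] (scalar HU grid
#' with physical geometry), [LabelMask] (aligned integer node-id grid),
#' [WindowSpec] (HU display/clipping window), [PatchPyramid] (multiscale
#' co-centered network input), [ProbabilityMap] (per-voxel class
#' probabilities), [ComponentSet] (connected components of a binary
#' mask), [DetectionReport] (component-level evaluation result) and
#' [FnetModel] (network configuration plus parameters).
NULL

.validGrid <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector (mm)")
  if (length(msg)) msg else TRUE
}

#' CTVolume: a 3D CT grid with physical geometry
#'
#' Scalar 3D array of Hounsfield units together with voxel spacing and
#' world origin (both mm).  See the package help page for the axis and
#' world-coordinate convention.
#'
#' @slot data 3D numeric array (HU).
#' @slot spacing numeric length-3, mm per voxel, strictly positive.
#' @slot origin numeric length-3, world mm of the first voxel's center.
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = .validGrid)

#' LabelMask: integer node-id grid aligned with a CTVolume
#'
#' Voxel value 0 is background; positive integers identify individual
#' ground-truth nodes (or 1 everywhere foreground for binary masks).
#'
#' @slot data 3D integer array.
#' @slot spacing,origin as in [CTVolume-class].
#' @export
setClass("LabelMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- .validGrid(object)
    msg <- if (isTRUE(msg)) character() else msg
    if (any(object@data < 0) || any(object@data != floor(object@data)))
      msg <- c(msg, "mask values must be non-negative integers")
    if (length(msg)) msg else TRUE
  })

#' WindowSpec: an HU intensity window
#'
#' The window `level/width` covers `[level - width/2, level + width/2]`.
#' The soft-tissue default used throughout the pipeline is width 750 HU
#' at level 70 HU (the "750/70" convention read as width/level).
#'
#' @slot level window center (HU).
#' @slot width full window range (HU), non-negative.
#' @export
setClass("WindowSpec",
  representation(level = "numeric", width = "numeric"),
  validity = function(object) {
    if (length(object@level) != 1L || length(object@width) != 1L)
      return("level and width must be scalars")
    if (!is.finite(object@level) || !is.finite(object@width))
      return("level and width must be finite")
    if (object@width < 0) return("width must be >= 0")
    TRUE
  })

#' PatchPyramid: multiscale co-centered network input
#'
#' `levels` 3D patches with identical voxel dimensions; level `l`
#' (1-based, finest first) covers `levelScale[l]` times the physical
#' extent of level 1, downscaled to the same voxel grid.
#'
#' @slot patches list of 3D arrays with identical dimensions.
#' @slot center world mm 3-vector at the common patch center.
#' @slot levelScale per-level physical downscale factor (finest first).
#' @slot spacing finest-level voxel spacing (mm).
#' @slot labelPatch 3D integer array aligned with the finest level's
#'   valid-output region, or `NULL`.
#' @export
setClass("PatchPyramid",
  representation(patches = "list", center = "numeric",
                 levelScale = "numeric", spacing = "numeric",
                 labelPatch = "ANY"),
  validity = function(object) {
    dims <- lapply(object@patches, dim)
    if (!length(dims)) return("at least one level required")
    if (!all(vapply(dims, function(d)
          identical(d, dims[[1L]]), logical(1))))
      return("all levels must share voxel dimensions")
    if (length(object@levelScale) != length(object@patches))
      return("levelScale must have one entry per level")
    TRUE
  })

#' ProbabilityMap: per-voxel class probabilities
#'
#' 4D array `(x, y, z, class)`; the foreground (lesion) class is the
#' last channel.  `offset` is the voxel offset of the map's first voxel
#' relative to the grid it was predicted from (0 for whole-volume maps,
#' the valid-output crop for per-patch maps).
#'
#' @slot data 4D numeric array, per-voxel class values in `[0, 1]`
#'   summing to 1 across the last dimension.
#' @slot spacing voxel spacing (mm).
#' @slot origin world mm of the first voxel.
#' @slot offset integer length-3 voxel offset of the valid region.
#' @export
setClass("ProbabilityMap",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 offset = "integer"),
  validity = function(object) {
    if (length(dim(object@data)) != 4L)
      return("data must be a 4D (x, y, z, class) array")
    TRUE
  })

#' ComponentSet: connected components of a binary mask
#'
#' Each component records its 1-based linear voxel indices, voxel count,
#' world centroid (mm) and estimated short-axis diameter (mm).
#'
#' @slot components list; each element a list with entries `id`,
#'   `voxels`, `nVoxels`, `centroid`, `sad`.
#' @slot dim integer length-3, the source grid dimensions.
#' @slot spacing source voxel spacing (mm).
#' @export
setClass("ComponentSet",
  representation(components = "list", dim = "integer", spacing = "numeric"))

#' DetectionReport: component-level evaluation result
#'
#' @slot perNode data.frame with one row per ground-truth node:
#'   `volume`, `id`, `sad_mm`, `sad_group`, `station`, `detected`.
#' @slot fpCount numeric, unmatched predicted components per volume.
#' @slot detectionRate scalar, detected / total nodes.
#' @slot fpPerVolume scalar, mean false positives per volume.
#' @slot stratifiedRates named numeric, detection rate per SAD group.
#' @slot segMetrics data.frame with per-volume matched-mask `dice`,
#'   `tpr`, `ppv` (NA where both reduced masks are empty).
#' @export
setClass("DetectionReport",
  representation(perNode = "data.frame", fpCount = "numeric",
                 detectionRate = "numeric", fpPerVolume = "numeric",
                 stratifiedRates = "numeric", segMetrics = "data.frame"))

#' FnetModel: a foveal network with parameters and preprocessing state
#'
#' @slot config the [fnetConfig()] list the model was built from.
#' @slot params nested list of per-layer parameters (convolution
#'   weights/biases, batch-norm gain/shift and running statistics).
#' @slot preprocess list of training-time settings needed at inference:
#'   intensity window, voxel spacing, patch size, pyramid factor,
#'   valid-output geometry and the selected probability threshold.
#' @export
setClass("FnetModel",
  representation(config = "list", params = "list", preprocess = "list"))

# ---- constructors ---------------------------------------------------------

#' Construct a CTVolume
#' @param data 3D numeric array (HU).
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param origin world mm of the first voxel center (default 0,0,0).
#' @return A [CTVolume-class].
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelMask
#' @param data 3D array of non-negative integer node ids (0 background).
#' @param spacing,origin as in [CTVolume()].
#' @return A [LabelMask-class].
#' @export
LabelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "integer"
  new("LabelMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an HU window
#' @param level window center (HU).
#' @param width full window range (HU).
#' @return A [WindowSpec-class].
#' @export
windowSpec <- function(level, width) {
  new("WindowSpec", level = as.numeric(level), width = as.numeric(width))
}

#' The default soft-tissue window: width 750 HU at level 70 HU
#' @return A [WindowSpec-class] with level 70 and width 750.
#' @export
softTissueWindow <- function() windowSpec(level = 70, width = 750)

# ---- show methods ---------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing %s mm, HU range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  ids <- setdiff(unique(as.vector(object@data)), 0L)
  cat(sprintf("LabelMask %d x %d x %d voxels, %d labeled node(s), %d foreground voxel(s)\n",
              d[1], d[2], d[3], length(ids), sum(object@data > 0)))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec level %.4g HU, width %.4g HU -> [%.4g, %.4g]\n",
              object@level, object@width,
              object@level - object@width / 2, object@level + object@width / 2))
})

setMethod("show", "PatchPyramid", function(object) {
  d <- dim(object@patches[[1L]])
  cat(sprintf("PatchPyramid: %d level(s) of %d x %d x %d voxels, scales %s\n",
              length(object@patches), d[1], d[2], d[3],
              paste(object@levelScale, collapse = ", ")))
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityMap %d x %d x %d voxels, %d classes\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d component(s) on a %s grid\n",
              length(object@components), paste(object@dim, collapse = " x ")))
  if (length(object@components)) {
    tab <- componentTable(object)
    print(head(tab, 10))
    if (nrow(tab) > 10) cat("...\n")
  }
})

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf("DetectionReport: %d node(s) in %d volume(s)\n",
              nrow(object@perNode), length(object@fpCount)))
  cat(sprintf("  detection rate: %.4f   FP/volume: %.3f\n",
              object@detectionRate, object@fpPerVolume))
  if (length(object@stratifiedRates)) {
    cat("  by SAD group:\n")
    for (g in names(object@stratifiedRates))
      cat(sprintf("    %-8s %.4f\n", g, object@stratifiedRates[[g]]))
  }
})

setMethod("show", "FnetModel", function(object) {
  cfg <- object@config
  cat(sprintf("FnetModel: %d level(s), %d CBR block(s)/pathway, channels (%s), %d classes\n",
              cfg$levels, cfg$blocksPerPathway,
              paste(cfg$channels, collapse = ", "), cfg$nClasses))
  cat(sprintf("  %d trainable parameters\n", nParams(object)))
  pp <- object@preprocess
  if (!is.null(pp$patchVoxels))
    cat(sprintf("  trained on %d^3 patches at %.3g mm; threshold %s\n",
                pp$patchVoxels, pp$spacing[1],
                if (is.null(pp$threshold) || is.na(pp$threshold)) "unset"
                else sprintf("%.2f", pp$threshold)))
})
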