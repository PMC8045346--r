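#' Extract the voxel data array
#' @param x a [CTVolume-class], [LabelMask-class] or [ProbabilityMap-class].
#' @return The underlying array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' Voxel spacing in mm
#' @param x a grid-carrying object.
#' @return Numeric length-3 spacing.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' World origin in mm
#' @param x a grid-carrying object.
#' @return Numeric length-3 origin.
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' Resample a grid to a fixed isotropic spacing
#'
#' @param x a [CTVolume-class] or [LabelMask-class].
#' @param targetSpacing isotropic target spacing in mm (default 1.5).
#' @param mode interpolation: `"linear"` for intensities, `"nearest"`
#'   for labels.  Label masks always use nearest.
#' @return An object of the same class on the new grid.
#' @export
setGeneric("resampleIsotropic",
  function(x, targetSpacing = 1.5, mode = c("linear", "nearest"))
    standardGeneric("resampleIsotropic"))

#' @rdname volData
#' @export
setMethod("volData", "CTVolume", function(x) x@data)
#' @rdname volData
#' @export
setMethod("volData", "LabelMask", function(x) x@data)
#' @rdname volData
#' @export
setMethod("volData", "ProbabilityMap", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ProbabilityMap", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ComponentSet", function(x) x@spacing)

#' @rdname volOrigin
#' @export
setMethod("volOrigin", "CTVolume", function(x) x@origin)
#' @rdname volOrigin
#' @export
setMethod("volOrigin", "LabelMask", function(x) x@origin)
#' @rdname volOrigin
#' @export
setMethod("volOrigin", "ProbabilityMap", function(x) x@origin)

#' Window level and width accessors
#' @param w a [WindowSpec-class].
#' @return Scalar HU value; `windowRange()` returns `c(lower, upper)`.
#' @export
windowLevel <- function(w) w@level

#' @rdname windowLevel
#' @export
windowWidth <- function(w) w@width

#' @rdname windowLevel
#' @export
windowRange <- function(w) c(w@level - w@width / 2, w@level + w@width / 2)

#' Binary view of a label mask
#' @param mask a [LabelMask-class].
#' @return A [LabelMask-class] with values 0/1.
#' @export
asBinaryMask <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  LabelMask(array(as.integer(mask@data > 0), dim(mask@data)),
            mask@spacing, mask@origin)
}

#' Number of components in a ComponentSet
#' @param x a [ComponentSet-class].
#' @return Integer count.
#' @export
nComponents <- function(x) {
  stopifnot(is(x, "ComponentSet"))
  length(x@components)
}

#' Tabulate a ComponentSet
#' @param x a [ComponentSet-class].
#' @return data.frame with `id`, `nVoxels`, centroid (mm) and `sad_mm`.
#' @export
componentTable <- function(x) {
  stopifnot(is(x, "ComponentSet"))
  if (!length(x@components))
    return(data.frame(id = integer(), nVoxels = integer(),
                      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                      sad_mm = numeric()))
  do.call(rbind, lapply(x@components, function(cc)
    data.frame(id = cc$id, nVoxels = cc$nVoxels,
               x_mm = cc$centroid[1], y_mm = cc$centroid[2],
               z_mm = cc$centroid[3], sad_mm = cc$sad)))
}
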