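#' Read a 3D volume or label mask from NIfTI or MetaImage
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`) via RNifti and
#' MetaImage (`.mha`, `.mhd`).  Spacing and origin are taken from the
#' file header; intensities are returned as stored (no rescaling beyond
#' the header's slope/intercept, which RNifti applies itself).
#'
#' @param path path to a readable volume file.
#' @param mask logical; if `TRUE` return a [LabelMask-class] (values are
#'   rounded to integer), otherwise a [CTVolume-class].
#' @return A [CTVolume-class] or [LabelMask-class].
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- .volExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    data <- array(as.numeric(data), dim(data)) # plain array, no nifti class
    if (length(dim(data)) != 3L)
      stop("non-3D data: expected 3 dimensions, got ", length(dim(data)))
    sp <- abs(RNifti::pixdim(img))[1:3]
    xf <- RNifti::xform(img)
    org <- as.numeric(xf[1:3, 4])
  } else if (ext %in% c("mha", "mhd")) {
    mi <- .readMetaImage(path)
    data <- mi$data
    if (length(dim(data)) != 3L)
      stop("non-3D data: expected 3 dimensions, got ", length(dim(data)))
    sp <- mi$spacing
    org <- mi$origin
  } else {
    stop("unsupported format: .", ext,
         " (supported: .nii, .nii.gz, .mha, .mhd)")
  }
  if (mask) LabelMask(round(data), sp, org) else CTVolume(data, sp, org)
}

#' Write a volume or mask to NIfTI or MetaImage
#'
#' The output format follows the file extension.  Spacing and origin are
#' stored in the header (NIfTI qform, code 2) and round-trip through
#' [readVolume()] within format precision.
#'
#' @param vol a [CTVolume-class] or [LabelMask-class].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume") || is(vol, "LabelMask"))
  ext <- .volExt(path)
  isMask <- is(vol, "LabelMask")
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(c(vol@spacing, 1))
    m[1:3, 4] <- vol@origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path,
                       datatype = if (isMask) "int32" else "float")
  } else if (ext %in% c("mha", "mhd")) {
    .writeMetaImage(vol@data, path, vol@spacing, vol@origin,
                    type = if (isMask) "MET_INT" else "MET_FLOAT")
  } else {
    stop("unsupported format: .", ext)
  }
  invisible(path)
}

.volExt <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(tools::file_ext(path))
}

#' @rdname resampleIsotropic
#' @details
#' The output grid keeps the first voxel's world position and has
#' `round(n * spacing / targetSpacing)` voxels per axis (round half away
#' from zero, minimum 1), so the physical extent is preserved within one
#' voxel.  Intensities are interpolated trilinearly (edge-clamped);
#' label masks use nearest-neighbor so ids are preserved.
#' @export
setMethod("resampleIsotropic", "CTVolume",
  function(x, targetSpacing = 1.5, mode = c("linear", "nearest")) {
    mode <- match.arg(mode)
    r <- .resampleGrid(x@data, x@spacing, targetSpacing, mode)
    CTVolume(r$data, r$spacing, x@origin)
  })

#' @rdname resampleIsotropic
#' @export
setMethod("resampleIsotropic", "LabelMask",
  function(x, targetSpacing = 1.5, mode = "nearest") {
    if (!identical(mode, "nearest"))
      stop("label masks must be resampled with mode = 'nearest'")
    r <- .resampleGrid(x@data, x@spacing, targetSpacing, "nearest")
    LabelMask(r$data, r$spacing, x@origin)
  })

.resampleGrid <- function(data, spacing, targetSpacing, mode) {
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
  if (any(targetSpacing <= 0)) stop("target spacing must be positive")
  d <- dim(data)
  outDim <- pmax(1L, as.integer(.roundHalfUp(d * spacing / targetSpacing)))
  M <- diag(targetSpacing / spacing)
  out <- .affineSample(as.numeric(data), as.integer(d), outDim, M,
                       c(0, 0, 0), if (mode == "nearest") 1L else 0L,
                       0, 1L)
  if (mode == "nearest") storage.mode(out) <- storage.mode(data)
  list(data = out, spacing = targetSpacing)
}

#' Estimate the soft-tissue window from labeled voxels
#'
#' Computes the mean and standard deviation of the intensities of all
#' labeled voxels together with their direct neighborhood (a box
#' dilation of `neighborhoodRadius` voxels; radius 1 is the 26-connected
#' neighborhood) and maps them to a window as `level = mean`,
#' `width = 2 * kSigma * sd`.  With the defaults, node-like voxels
#' distributed around 70 HU with a 125 HU spread reproduce the 750/70
#' soft-tissue window.
#'
#' @param vol a [CTVolume-class].
#' @param mask a [LabelMask-class] aligned with `vol`.
#' @param neighborhoodRadius box dilation radius in voxels (default 1;
#'   0 restricts to the labeled voxels themselves).
#' @param kSigma number of standard deviations on each side (default 3).
#' @return A [WindowSpec-class].
#' @export
estimateWindow <- function(vol, mask, neighborhoodRadius = 1, kSigma = 3) {
  stopifnot(is(vol, "CTVolume"), is(mask, "LabelMask"))
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("volume and mask shapes differ")
  sel <- .windowVoxels(mask@data, neighborhoodRadius)
  if (!any(sel)) stop("no labeled voxels")
  vals <- vol@data[sel]
  s <- if (length(vals) > 1L) sd(vals) else 0
  windowSpec(level = mean(vals), width = 2 * kSigma * s)
}

# logical selection: foreground union its box dilation
.windowVoxels <- function(maskData, radius) {
  fg <- maskData > 0
  if (radius <= 0) return(fg)
  .boxDilate(fg, as.integer(dim(maskData)), as.integer(radius))
}

#' Clip a volume to an HU window
#'
#' Every voxel is clamped to `[level - width/2, level + width/2]`.
#' Idempotent; shape and spacing are unchanged.
#'
#' @param vol a [CTVolume-class].
#' @param w a [WindowSpec-class].
#' @return A clipped [CTVolume-class].
#' @export
applyWindow <- function(vol, w) {
  stopifnot(is(vol, "CTVolume"), is(w, "WindowSpec"))
  rng <- windowRange(w)
  CTVolume(pmin(pmax(vol@data, rng[1]), rng[2]), vol@spacing, vol@origin)
}

#' Clip and rescale a volume to the window's [-1, 1] range
#'
#' Network input normalization: clamp to the window, then map
#' `level - width/2 -> -1` and `level + width/2 -> +1`.
#'
#' @inheritParams applyWindow
#' @return A [CTVolume-class] with values in `[-1, 1]`.
#' @export
normalizeToWindow <- function(vol, w) {
  stopifnot(is(vol, "CTVolume"), is(w, "WindowSpec"))
  if (w@width <= 0) stop("window width must be positive for normalization")
  clipped <- pmin(pmax(vol@data, w@level - w@width / 2),
                  w@level + w@width / 2)
  CTVolume((clipped - w@level) / (w@width / 2), vol@spacing, vol@origin)
}
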