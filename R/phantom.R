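#' Specify a synthetic CT phantom
#'
#' Parameters of a contrast-CT-like phantom: a noisy soft-tissue
#' background, ellipsoidal lymph-node-like lesions at soft-tissue
#' intensity, and bright tubular vessel confounders.  The defaults
#' emulate the structure of contrast-enhanced thoracic CT after lesion
#' annotation: lesions at 70 HU (the soft-tissue window level) on a
#' 20 +/- 15 HU background with ~250 HU vessels, on a 64^3 grid at the
#' pipeline's 1.5 mm isotropic spacing, lesion short-axis diameters
#' (SAD) drawn uniformly from 6-20 mm.
#'
#' @param shape integer length-3 (or scalar) grid size in voxels.
#' @param spacing isotropic voxel spacing in mm.
#' @param nLesions number of lesions (ground-truth nodes).
#' @param sadRange `c(min, max)` lesion SAD in mm; the minimum must be
#'   at least `2 * spacing` so lesions span two in-plane voxels.
#' @param lesionHU lesion intensity (HU).
#' @param backgroundHU,backgroundSD background mean and SD (HU).
#' @param nVessels number of straight tubular vessel confounders.
#' @param vesselHU vessel intensity (HU).
#' @param vesselRadiusRange `c(min, max)` vessel radius in mm.
#' @param noiseSD additive Gaussian noise SD (HU), applied last.
#' @param allowClusters logical; if `TRUE`, some lesions are built from
#'   2-4 merged ellipsoids (kept as a single ground-truth id) to emulate
#'   bulky disease, and lesions may touch.
#' @param seed integer seed; the phantom is fully deterministic given it.
#' @return A validated list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = 1.5,
                        nLesions = 6, sadRange = c(6, 20),
                        lesionHU = 70, backgroundHU = 20, backgroundSD = 15,
                        nVessels = 3, vesselHU = 250,
                        vesselRadiusRange = c(2, 5), noiseSD = 5,
                        allowClusters = FALSE, seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  stopifnot(length(shape) == 3L, all(shape >= 8),
            length(spacing) == 1L, spacing > 0,
            .isCount(nLesions), .isCount(nVessels),
            length(sadRange) == 2L, sadRange[1] <= sadRange[2],
            backgroundSD >= 0, noiseSD >= 0,
            length(vesselRadiusRange) == 2L,
            vesselRadiusRange[1] <= vesselRadiusRange[2])
  if (sadRange[1] < 2 * spacing)
    stop("sadRange minimum must be >= 2 * spacing (lesions must span ",
         "at least 2 in-plane voxels)")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 nLesions = as.integer(nLesions), sadRange = sadRange,
                 lesionHU = lesionHU, backgroundHU = backgroundHU,
                 backgroundSD = backgroundSD, nVessels = as.integer(nVessels),
                 vesselHU = vesselHU, vesselRadiusRange = vesselRadiusRange,
                 noiseSD = noiseSD, allowClusters = isTRUE(allowClusters),
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a synthetic CT phantom with ground-truth node masks
#'
#' Draws the background, places `nLesions` non-overlapping ellipsoidal
#' lesions (random in-plane orientation, axis ratios in `[1, 1.6]` with
#' the short axis in-plane so the drawn SAD is the in-plane short-axis
#' diameter), adds vessel tubes, and applies additive noise last.  The
#' generator stream order is fixed (background, then per-lesion
#' geometry, then vessels, then noise), so results are bit-reproducible
#' given `spec$seed`.
#'
#' @param spec a [phantomSpec()].
#' @return A list with elements `volume` ([CTVolume-class]), `mask`
#'   ([LabelMask-class] with ids `1..nLesions`) and `nodes` (data.frame
#'   with `id`, `x_mm`, `y_mm`, `z_mm`, `sad_mm`, `sad_group`,
#'   `station`).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  n <- prod(d)
  vol <- array(rnorm(n, spec$backgroundHU, spec$backgroundSD), d)
  mask <- array(0L, d)
  nodes <- list()
  maxAttempts <- 200L
  placed <- 0L
  for (id in seq_len(spec$nLesions)) {
    sad <- runif(1, spec$sadRange[1], spec$sadRange[2])
    ratios <- runif(2, 1, 1.6)
    phi <- runif(1, 0, 2 * pi)
    semi <- c(sad / 2, sad / 2 * ratios[1], sad / 2 * ratios[2]) # mm
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      ctr <- .drawLesionCenter(d, sp, semi)
      vox <- .ellipsoidVoxels(d, sp, ctr, semi, phi)
      if (!length(vox)) next
      if (!spec$allowClusters && .touchesExisting(mask, vox, d)) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could only place %d of %d lesions without overlap",
                   placed, spec$nLesions))
    mask[vox] <- id
    if (spec$allowClusters && runif(1) < 0.35) {
      for (k in seq_len(sample(1:3, 1))) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        off <- dir * semi[1] * runif(1, 0.6, 1.0)
        sadE <- sad * runif(1, 0.5, 0.9)
        semiE <- c(sadE / 2, sadE / 2 * runif(1, 1, 1.6),
                   sadE / 2 * runif(1, 1, 1.6))
        voxE <- .ellipsoidVoxels(d, sp, ctr + off, semiE, runif(1, 0, 2 * pi))
        voxE <- voxE[mask[voxE] == 0L]
        mask[voxE] <- id
      }
      vox <- which(mask == id)
    }
    placed <- placed + 1L
    coords <- arrayInd(vox, d)
    centroid <- (colMeans(coords) - 1) * sp
    nodes[[id]] <- data.frame(
      id = id, x_mm = centroid[1], y_mm = centroid[2], z_mm = centroid[3],
      sad_mm = sad, sad_group = .sadGroupLabel(sad),
      station = NA_character_, stringsAsFactors = FALSE)
  }
  # paint lesions before vessels so vessels never overwrite (or label) them
  vol[mask > 0L] <- spec$lesionHU
  for (v in seq_len(spec$nVessels)) {
    radius <- runif(1, spec$vesselRadiusRange[1], spec$vesselRadiusRange[2])
    anchor <- runif(3, 0, (d - 1) * sp)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    sel <- .tubeVoxels(d, sp, anchor, dir, radius)
    sel <- sel[mask[sel] == 0L]
    vol[sel] <- spec$vesselHU
  }
  if (spec$noiseSD > 0) vol <- vol + rnorm(n, 0, spec$noiseSD)
  list(volume = CTVolume(vol, sp),
       mask = LabelMask(mask, sp),
       nodes = if (length(nodes)) do.call(rbind, nodes) else
         data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                    z_mm = numeric(), sad_mm = numeric(),
                    sad_group = character(), station = character(),
                    stringsAsFactors = FALSE))
}

.drawLesionCenter <- function(d, sp, semi) {
  marginVox <- ceiling(max(semi) / sp) + 1
  lo <- rep(marginVox * sp, 3L)
  hi <- (d - 1 - marginVox) * sp
  if (any(hi <= lo)) stop("lesion too large for the phantom grid")
  c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
}

# linear voxel indices inside an ellipsoid with in-plane rotation phi;
# center in mm (0-based world, origin at first voxel), semi-axes in mm
.ellipsoidVoxels <- function(d, sp, center, semi, phi) {
  rad <- max(semi)
  lo <- pmax(1L, floor((center - rad) / sp) + 1L)
  hi <- pmin(d, ceiling((center + rad) / sp) + 1L)
  if (any(hi < lo)) return(integer())
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  x <- (ii - 1) * sp - center[1]
  y <- (jj - 1) * sp - center[2]
  z <- (kk - 1) * sp - center[3]
  X <- array(rep(x, times = length(jj) * length(kk)),
             c(length(ii), length(jj), length(kk)))
  Y <- array(rep(rep(y, each = length(ii)), times = length(kk)),
             c(length(ii), length(jj), length(kk)))
  Z <- array(rep(z, each = length(ii) * length(jj)),
             c(length(ii), length(jj), length(kk)))
  u <- cos(phi) * X + sin(phi) * Y
  v <- -sin(phi) * X + cos(phi) * Y
  inside <- (u / semi[1])^2 + (v / semi[2])^2 + (Z / semi[3])^2 <= 1
  idx <- which(inside)
  if (!length(idx)) return(integer())
  loc <- arrayInd(idx, dim(inside))
  gi <- loc[, 1] + lo[1] - 1L
  gj <- loc[, 2] + lo[2] - 1L
  gk <- loc[, 3] + lo[3] - 1L
  gi + d[1] * (gj - 1L) + d[1] * d[2] * (gk - 1L)
}

# would the candidate voxel set touch an existing label (within a
# 1-voxel guard band, so components stay separate under 26-connectivity)?
.touchesExisting <- function(mask, vox, d) {
  coords <- arrayInd(vox, d)
  lo <- pmax(1L, apply(coords, 2, min) - 1L)
  hi <- pmin(d, apply(coords, 2, max) + 1L)
  any(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] > 0L)
}

.tubeVoxels <- function(d, sp, anchor, dir, radius) {
  x <- (seq_len(d[1]) - 1) * sp - anchor[1]
  y <- (seq_len(d[2]) - 1) * sp - anchor[2]
  z <- (seq_len(d[3]) - 1) * sp - anchor[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  dot <- X * dir[1] + Y * dir[2] + Z * dir[3]
  dist2 <- (X - dot * dir[1])^2 + (Y - dot * dir[2])^2 + (Z - dot * dir[3])^2
  which(dist2 <= radius^2)
}

.sadGroupLabel <- function(sad, edges = c(5, 10, 20)) {
  labels <- c(sprintf("%g-%g", edges[1], edges[2]),
              sprintf("%g-%g", edges[2], edges[3]),
              sprintf(">%g", edges[3]))
  ifelse(sad < edges[1], NA_character_,
         ifelse(sad < edges[2], labels[1],
                ifelse(sad < edges[3], labels[2], labels[3])))
}

#' Write a phantom bundle to disk
#'
#' Writes the volume and mask as NIfTI and the node table as CSV with
#' header `id, x_mm, y_mm, z_mm, sad_mm, sad_group, station`.
#'
#' @param phantom a list as returned by [generatePhantom()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Named character vector of the three paths written.
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  paths <- c(volume = file.path(dir, paste0(prefix, "_volume.nii.gz")),
             mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
             nodes = file.path(dir, paste0(prefix, "_nodes.csv")))
  writeVolume(phantom$volume, paths[["volume"]])
  writeVolume(phantom$mask, paths[["mask"]])
  write.csv(phantom$nodes, paths[["nodes"]], row.names = FALSE)
  paths
}

#' Read a phantom node table
#' @param path CSV path written by [writePhantom()].
#' @return data.frame with the node columns.
#' @export
readNodeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
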