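#' Match predicted components against ground-truth nodes
#'
#' A ground-truth node is detected iff at least one of its voxels lies
#' in any predicted component; a predicted component is matched iff it
#' overlaps any node.  Many-to-many overlaps are allowed: one predicted
#' blob can detect several nodes and one node can be detected by
#' several blobs.
#'
#' @param gt a [ComponentSet-class] of ground-truth nodes (see
#'   [labeledComponents()]).
#' @param pred a [ComponentSet-class] of predicted components on the
#'   same grid.
#' @return List with `gtDetected` and `predMatched` logical vectors.
#' @export
matchComponents <- function(gt, pred) {
  stopifnot(is(gt, "ComponentSet"), is(pred, "ComponentSet"))
  if (!identical(gt@dim, pred@dim))
    stop("component sets come from different grids")
  n <- prod(gt@dim)
  predFG <- logical(n)
  for (cc in pred@components) predFG[cc$voxels] <- TRUE
  gtFG <- logical(n)
  for (cc in gt@components) gtFG[cc$voxels] <- TRUE
  list(gtDetected = vapply(gt@components,
                           function(cc) any(predFG[cc$voxels]), logical(1)),
       predMatched = vapply(pred@components,
                            function(cc) any(gtFG[cc$voxels]), logical(1)))
}

#' Detection rate
#'
#' Number of detected nodes divided by the total number of nodes.
#'
#' @param detected logical vector of per-node detected flags.
#' @return Scalar in `[0, 1]`.
#' @export
detectionRate <- function(detected) {
  if (!length(detected)) stop("zero ground-truth nodes")
  sum(detected) / length(detected)
}

#' False positives per volume
#'
#' Mean number of predicted components without ground-truth overlap per
#' volume.
#'
#' @param predMatched logical vector (or list of per-volume vectors) of
#'   per-predicted-component matched flags.
#' @param nVolumes number of volumes the predictions came from.
#' @return Scalar mean FP count per volume.
#' @export
falsePositivesPerVolume <- function(predMatched, nVolumes) {
  stopifnot(.isCount(nVolumes, 1))
  flags <- unlist(predMatched)
  sum(!flags) / nVolumes
}

#' Matched-mask segmentation metrics
#'
#' Removes all missed nodes from the ground-truth mask and all false
#' positive components from the predicted mask, then computes Dice,
#' true-positive rate and positive predictive value voxel-wise on the
#' reduced masks.  When both reduced masks are empty (nothing was
#' detected) the metrics are undefined and `NA` is returned; callers
#' exclude such volumes from means.
#'
#' @param gt,pred the [ComponentSet-class] pair of one volume.
#' @param match the result of [matchComponents()] for them.
#' @return List with `dice`, `tpr`, `ppv`.
#' @export
matchedSegMetrics <- function(gt, pred, match = matchComponents(gt, pred)) {
  n <- prod(gt@dim)
  g <- logical(n)
  for (i in which(match$gtDetected)) g[gt@components[[i]]$voxels] <- TRUE
  p <- logical(n)
  for (i in which(match$predMatched)) p[pred@components[[i]]$voxels] <- TRUE
  sg <- sum(g); sp <- sum(p)
  if (sg + sp == 0)
    return(list(dice = NA_real_, tpr = NA_real_, ppv = NA_real_))
  tp <- sum(g & p)
  list(dice = 2 * tp / (sg + sp), tpr = tp / sg, ppv = tp / sp)
}

#' Short-axis diameter of a component
#'
#' On the axial slice with the largest cross-sectional area (ties:
#' lowest slice), the minimal caliper width of the in-plane convex hull
#' of the component's voxel footprints (voxel centers expanded to their
#' four in-plane corners), in mm.  A single voxel therefore has SAD
#' equal to the in-plane spacing.
#'
#' @param voxels 1-based linear voxel indices of the component (or a
#'   component list as stored in a [ComponentSet-class]).
#' @param dim integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm (scalar or length 3; the first
#'   two components are the in-plane spacing).
#' @return SAD in mm.
#' @export
sadOfComponent <- function(voxels, dim, spacing) {
  if (is.list(voxels)) voxels <- voxels$voxels
  if (!length(voxels)) stop("empty component")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  coords <- arrayInd(voxels, dim)
  zcount <- table(coords[, 3])
  zbest <- as.integer(names(zcount)[which.max(zcount)])
  inpl <- coords[coords[, 3] == zbest, , drop = FALSE]
  x <- inpl[, 1] * spacing[1]
  y <- inpl[, 2] * spacing[2]
  px <- c(x - spacing[1] / 2, x - spacing[1] / 2,
          x + spacing[1] / 2, x + spacing[1] / 2)
  py <- c(y - spacing[2] / 2, y + spacing[2] / 2,
          y - spacing[2] / 2, y + spacing[2] / 2)
  .minCaliperWidth(px, py)
}

# minimal width over all directions of the convex hull of 2D points
# (rotating calipers: the minimum is attained perpendicular to an edge)
.minCaliperWidth <- function(x, y) {
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  if (nh == 1L) return(0)
  if (nh == 2L) return(0) # degenerate segment has zero width
  best <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    nx <- -ey / len; ny <- ex / len
    w <- max(abs((hx - hx[i]) * nx + (hy - hy[i]) * ny))
    if (w < best) best <- w
  }
  if (is.finite(best)) best else 0
}

#' Detection rates stratified by SAD group
#'
#' Nodes are binned into half-open SAD groups `[5, 10)`, `[10, 20)` and
#' `[20, Inf)` mm by default; nodes below the lowest edge are excluded
#' from the evaluation entirely.
#'
#' @param nodes data.frame with columns `sad_mm` and `detected`.
#' @param edges increasing bin edges in mm (default `c(5, 10, 20)`).
#' @return Named numeric vector of per-group detection rates (`NA` for
#'   empty groups).
#' @export
stratifyBySize <- function(nodes, edges = c(5, 10, 20)) {
  stopifnot(is.data.frame(nodes), all(c("sad_mm", "detected") %in%
                                        names(nodes)),
            length(edges) >= 2, !is.unsorted(edges))
  labels <- c(sprintf("%g-%g", edges[-length(edges)], edges[-1]),
              sprintf(">%g", edges[length(edges)]))
  keep <- nodes$sad_mm >= edges[1]
  grp <- findInterval(nodes$sad_mm[keep], edges)
  det <- nodes$detected[keep]
  out <- vapply(seq_along(labels), function(i) {
    sel <- grp == i
    if (!any(sel)) NA_real_ else sum(det[sel]) / sum(sel)
  }, numeric(1))
  names(out) <- labels
  out
}

#' Bootstrap standard deviation of a detection rate
#'
#' Resamples the per-node detected flags with replacement at full
#' sample size `nSim` times and returns the standard deviation of the
#' resampled rates.  For i.i.d. flags with rate p this approaches
#' `sqrt(p (1 - p) / n)`.
#'
#' @param detected logical (or 0/1) vector of per-node flags.
#' @param nSim number of bootstrap resamples (default 10000).
#' @param seed optional seed; the result is deterministic given it.
#' @return Scalar standard deviation.
#' @export
bootstrapRateSD <- function(detected, nSim = 10000, seed = NULL) {
  n <- length(detected)
  if (!n) stop("empty input")
  stopifnot(.isCount(nSim, 1))
  if (!is.null(seed)) set.seed(seed)
  flags <- as.numeric(detected)
  rates <- vapply(seq_len(nSim), function(i)
    mean(flags[sample.int(n, n, replace = TRUE)]), numeric(1))
  sd(rates)
}

#' Compare two detection rates with a two-sided unpaired t-test
#'
#' Welch's t-test on the per-node 0/1 detection indicators of the two
#' groups.  When both groups have zero variance the statistic is
#' undefined: equal means return p = 1, unequal means return `NA` with
#' a warning (the documented sentinel).
#'
#' @param flagsA,flagsB logical (or 0/1) vectors, length >= 2 each.
#' @return Two-sided p-value.
#' @export
compareRates <- function(flagsA, flagsB) {
  a <- as.numeric(flagsA); b <- as.numeric(flagsB)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    warning("degenerate zero-variance groups with unequal means; ",
            "p-value undefined")
    return(NA_real_)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Evaluate predicted segmentations against ground truth
#'
#' Runs the full component-level protocol over one or more volumes:
#' components, overlap matching, detection rate, false positives per
#' volume, matched-mask segmentation metrics and SAD stratification.
#' Ground-truth SADs from a node table override the computed ones when
#' provided.
#'
#' @param gtMasks [LabelMask-class] (or list of them) with positive
#'   node ids.
#' @param predMasks binary [LabelMask-class] (or list) aligned with the
#'   ground truth.
#' @param nodeTables optional data.frame (or list) with `id`, `sad_mm`
#'   and optionally `station` per node, as written by [writePhantom()].
#' @param connectivity connectivity for predicted components.
#' @param minVoxels minimum predicted component size.
#' @param edges SAD group edges in mm.
#' @return A [DetectionReport-class].
#' @export
evaluateDetection <- function(gtMasks, predMasks, nodeTables = NULL,
                              connectivity = 26, minVoxels = 1,
                              edges = c(5, 10, 20)) {
  if (is(gtMasks, "LabelMask")) gtMasks <- list(gtMasks)
  if (is(predMasks, "LabelMask")) predMasks <- list(predMasks)
  if (is.data.frame(nodeTables)) nodeTables <- list(nodeTables)
  stopifnot(length(gtMasks) == length(predMasks))
  nVol <- length(gtMasks)
  perNode <- list()
  fpCount <- numeric(nVol)
  seg <- list()
  for (v in seq_len(nVol)) {
    gt <- labeledComponents(gtMasks[[v]])
    pred <- connectedComponents(asBinaryMask(predMasks[[v]]),
                                connectivity, minVoxels)
    match <- matchComponents(gt, pred)
    fpCount[v] <- sum(!match$predMatched)
    sm <- matchedSegMetrics(gt, pred, match)
    seg[[v]] <- data.frame(volume = v, dice = sm$dice, tpr = sm$tpr,
                           ppv = sm$ppv)
    nt <- if (!is.null(nodeTables)) nodeTables[[v]] else NULL
    rows <- lapply(seq_along(gt@components), function(i) {
      cc <- gt@components[[i]]
      sad <- cc$sad
      station <- NA_character_
      if (!is.null(nt)) {
        hit <- match(cc$id, nt$id)
        if (!is.na(hit)) {
          sad <- nt$sad_mm[hit]
          if ("station" %in% names(nt))
            station <- as.character(nt$station[hit])
        }
      }
      data.frame(volume = v, id = cc$id, sad_mm = sad,
                 sad_group = .sadGroupLabel(sad, edges), station = station,
                 detected = match$gtDetected[i], stringsAsFactors = FALSE)
    })
    perNode[[v]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  perNode <- do.call(rbind, perNode)
  if (is.null(perNode) || !nrow(perNode)) stop("zero ground-truth nodes")
  new("DetectionReport",
      perNode = perNode,
      fpCount = fpCount,
      detectionRate = detectionRate(perNode$detected),
      fpPerVolume = sum(fpCount) / nVol,
      stratifiedRates = stratifyBySize(perNode, edges),
      segMetrics = do.call(rbind, seg))
}

#' Write a detection report to JSON and CSV
#'
#' @param report a [DetectionReport-class].
#' @param jsonPath summary JSON path (aggregate rates, FP counts, mean
#'   segmentation metrics), or `NULL` to skip.
#' @param csvPath per-node CSV path, or `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
writeDetectionReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "DetectionReport"))
  if (!is.null(jsonPath)) {
    summary <- list(
      detection_rate = report@detectionRate,
      fp_per_volume = report@fpPerVolume,
      n_nodes = nrow(report@perNode),
      n_volumes = length(report@fpCount),
      fp_count = report@fpCount,
      stratified_rates = as.list(report@stratifiedRates),
      mean_dice = mean(report@segMetrics$dice, na.rm = TRUE),
      mean_tpr = mean(report@segMetrics$tpr, na.rm = TRUE),
      mean_ppv = mean(report@segMetrics$ppv, na.rm = TRUE),
      n_volumes_excluded_from_seg = sum(is.na(report@segMetrics$dice)))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csvPath))
    write.csv(report@perNode, csvPath, row.names = FALSE)
  invisible(c(json = jsonPath, csv = csvPath))
}
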