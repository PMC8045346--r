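# Independent brute-force oracles used across the test files.  These are
# deliberately written with plain R loops and no calls into the package's
# own component/metric machinery.

# BFS flood fill labeling of a binary 3D array
bruteFloodFill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(off))
  off <- off[manh > 0 & manh <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
             drop = FALSE]
  lab <- array(0L, d)
  nextId <- 0L
  for (v in which(mask > 0)) {
    if (lab[v] != 0L) next
    nextId <- nextId + 1L
    queue <- v
    lab[v] <- nextId
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        ni <- ci + off[r, ]
        if (any(ni < 1L) || any(ni > d)) next
        u <- ni[1] + d[1] * (ni[2] - 1L) + d[1] * d[2] * (ni[3] - 1L)
        if (mask[u] > 0 && lab[u] == 0L) {
          lab[u] <- nextId
          queue <- c(queue, u)
        }
      }
    }
  }
  lab
}

# full component-level evaluation of one volume by nested loops:
# detection flags, FP count and matched-mask Dice/TPR/PPV
bruteEvalVolume <- function(gtLab, predBin, connectivity = 26) {
  predLab <- bruteFloodFill(predBin, connectivity)
  gtIds <- sort(setdiff(unique(as.vector(gtLab)), 0L))
  predIds <- sort(setdiff(unique(as.vector(predLab)), 0L))
  detected <- logical(length(gtIds))
  for (i in seq_along(gtIds))
    detected[i] <- any(predBin[gtLab == gtIds[i]] > 0)
  matched <- logical(length(predIds))
  for (j in seq_along(predIds))
    matched[j] <- any(gtLab[predLab == predIds[j]] > 0)
  gRed <- array(FALSE, dim(gtLab))
  for (i in seq_along(gtIds))
    if (detected[i]) gRed[gtLab == gtIds[i]] <- TRUE
  pRed <- array(FALSE, dim(gtLab))
  for (j in seq_along(predIds))
    if (matched[j]) pRed[predLab == predIds[j]] <- TRUE
  sg <- sum(gRed); sp <- sum(pRed); tp <- sum(gRed & pRed)
  list(nGt = length(gtIds), detected = detected, fp = sum(!matched),
       rate = if (length(gtIds)) mean(detected) else NA_real_,
       dice = if (sg + sp == 0) NA_real_ else 2 * tp / (sg + sp),
       tpr = if (sg + sp == 0) NA_real_ else tp / sg,
       ppv = if (sg + sp == 0) NA_real_ else tp / sp)
}

# independent layer-by-layer walk of the network's spatial sizes
walkOutputSize <- function(levels, blocks, patch) {
  s <- patch
  for (b in seq_len(blocks)) s <- s - 2L
  stopifnot(s >= 1)
  if (levels == 1L) return(s - 2L)
  sz <- s
  for (l in seq(levels - 1L, 1L)) {
    up <- 2L * sz
    m <- min(s, up)
    sz <- m - 2L
  }
  sz
}

# random binary mask with a few blob seeds grown by dilation-like noise
randomBlobMask <- function(d, nSeeds, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- array(0L, d)
  for (s in seq_len(nSeeds)) {
    c0 <- sapply(d, function(n) sample.int(n, 1))
    r <- sample(1:3, 1)
    rng <- lapply(1:3, function(a) max(1, c0[a] - r):min(d[a], c0[a] + r))
    sub <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
    keep <- runif(nrow(sub)) < p
    idx <- as.matrix(sub[keep, , drop = FALSE])
    m[idx] <- 1L
  }
  m
}

# small in-memory phantom training/test case
phantomCase <- function(seed, shape = 48, nLesions = 3, sadRange = c(6, 14),
                        ...) {
  ph <- generatePhantom(phantomSpec(shape = shape, nLesions = nLesions,
                                    sadRange = sadRange, seed = seed, ...))
  list(volume = ph$volume, mask = ph$mask, nodes = ph$nodes)
}

# small network/training configs used by several files
tinyFnetConfig <- function(levels = 2)
  fnetConfig(levels = levels, blocksPerPathway = 2, channels = c(4, 4),
             integrationChannels = 4)
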