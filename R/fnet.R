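#' Configure a foveal network
#'
#' The f-net processes each resolution level of a [PatchPyramid-class]
#' in its own feature-extraction pathway of `blocksPerPathway` CBR
#' blocks (valid 3^3 convolution, batch normalization, ReLU), then
#' integrates levels coarse-to-fine: the coarser integration output is
#' upsampled by the pyramid factor, center-cropped to align valid
#' regions, concatenated with the current level's pathway output and
#' passed through one integration CBR block.  A 1x1x1 projection and a
#' channel-wise softmax yield per-voxel pseudo class probabilities at
#' the finest resolution.
#'
#' @param levels number of resolution levels / pathways (default 4).
#' @param blocksPerPathway CBR blocks per pathway (default 3).
#' @param channels per-block channel widths, length `blocksPerPathway`
#'   (default 16, 32, 64).
#' @param integrationChannels channels of each integration CBR block
#'   (default 32).
#' @param nClasses number of output classes (default 2; the foreground
#'   class is the last).
#' @param upsampleMode `"nearest"` (default) or `"trilinear"`.
#' @param kernel convolution kernel size; only 3 is supported.
#' @return A validated list of class `"FnetConfig"`.
#' @export
fnetConfig <- function(levels = 4, blocksPerPathway = 3,
                       channels = c(16, 32, 64), integrationChannels = 32,
                       nClasses = 2, upsampleMode = c("nearest", "trilinear"),
                       kernel = 3) {
  upsampleMode <- match.arg(upsampleMode)
  stopifnot(.isCount(levels, 1), .isCount(blocksPerPathway, 1),
            .isCount(nClasses, 2), .isCount(integrationChannels, 1))
  if (kernel != 3) stop("only kernel size 3 is supported")
  if (length(channels) != blocksPerPathway)
    stop("channels must list one width per pathway block (",
         blocksPerPathway, ")")
  structure(list(levels = as.integer(levels),
                 blocksPerPathway = as.integer(blocksPerPathway),
                 channels = as.integer(channels),
                 integrationChannels = as.integer(integrationChannels),
                 nClasses = as.integer(nClasses),
                 upsampleMode = upsampleMode, kernel = 3L,
                 factor = 2L),
            class = "FnetConfig")
}

#' Valid-convolution pathway output size
#'
#' Each valid 3^3 convolution shrinks every spatial dimension by 2, so a
#' pathway of `blocks` blocks maps `inputSize` to
#' `inputSize - blocks * (kernel - 1)`.
#'
#' @param inputSize patch edge length in voxels.
#' @param blocks number of CBR blocks (default 3).
#' @param kernel kernel size (default 3).
#' @return The output edge length.
#' @export
pathwayOutputSize <- function(inputSize, blocks = 3, kernel = 3) {
  out <- inputSize - blocks * (kernel - 1)
  if (any(out < 1)) stop("patch too small: ", inputSize, " voxels leave ",
                         out, " after ", blocks, " valid convolutions")
  out
}

#' Spatial shape arithmetic of the network
#'
#' Computes, for a given patch size, the pathway output size, the
#' integration output size at every level, the final valid-output size
#' and its voxel offset within the finest-level patch.
#'
#' @param cfg an [fnetConfig()].
#' @param patchVoxels patch edge length in voxels.
#' @return List with `patchVoxels`, `pathwayOut`, `integrationSizes`
#'   (finest first), `outputSize` and `outputOffset`.
#' @export
fnetShapes <- function(cfg, patchVoxels) {
  stopifnot(inherits(cfg, "FnetConfig"))
  L <- cfg$levels
  S <- pathwayOutputSize(patchVoxels, cfg$blocksPerPathway, cfg$kernel)
  I <- integer(L)
  if (L == 1L) {
    I[1] <- S - 2L
    off <- cfg$blocksPerPathway + 1L
  } else {
    I[L] <- S
    m1 <- NA_integer_
    for (l in seq(L - 1L, 1L)) {
      up <- cfg$factor * I[l + 1L]
      m <- min(S, up)
      I[l] <- m - 2L
      if (l == 1L) m1 <- m
    }
    off <- cfg$blocksPerPathway + floor((S - m1) / 2) + 1L
  }
  if (any(I < 1L)) stop("patch too small for the integration pathway")
  list(patchVoxels = as.integer(patchVoxels), pathwayOut = as.integer(S),
       integrationSizes = as.integer(I), outputSize = as.integer(I[1]),
       outputOffset = as.integer(off))
}

#' Build a foveal network with freshly initialized parameters
#'
#' Convolution weights use He initialization (`sd = sqrt(2 / fanIn)`),
#' biases start at 0, batch-norm gains at 1 and running statistics at
#' (0, 1).  Two builds from the same configuration and seed produce
#' identical parameters.
#'
#' @param cfg an [fnetConfig()].
#' @param seed optional integer seed for the initialization.
#' @return An [FnetModel-class].
#' @export
buildFnet <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "FnetConfig"))
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$levels; B <- cfg$blocksPerPathway
  ch <- cfg$channels; ci <- cfg$integrationChannels
  mkConv <- function(cin, cout) {
    list(W = matrix(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
                    27 * cin, cout),
         b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
         runMean = numeric(cout), runVar = rep(1, cout))
  }
  pathways <- lapply(seq_len(L), function(l) {
    lapply(seq_len(B), function(b)
      mkConv(if (b == 1L) 1L else ch[b - 1L], ch[b]))
  })
  cB <- ch[B]
  integration <- if (L == 1L) list(mkConv(cB, ci)) else
    lapply(seq_len(L - 1L), function(i)
      mkConv(cB + if (i == 1L) cB else ci, ci))
  head <- list(W = matrix(rnorm(ci * cfg$nClasses, sd = sqrt(1 / ci)),
                          ci, cfg$nClasses),
               b = numeric(cfg$nClasses))
  new("FnetModel", config = unclass(cfg),
      params = list(pathways = pathways, integration = integration,
                    head = head),
      preprocess = list())
}

#' Count trainable parameters
#' @param model an [FnetModel-class].
#' @return Integer: entries of all convolution weights/biases, batch
#'   norm gains/shifts and the projection head (running statistics are
#'   buffers, not parameters).
#' @export
nParams <- function(model) {
  stopifnot(is(model, "FnetModel"))
  cnt <- 0L
  for (pw in model@params$pathways) for (bl in pw)
    cnt <- cnt + length(bl$W) + length(bl$b) + length(bl$gamma) +
      length(bl$beta)
  for (bl in model@params$integration)
    cnt <- cnt + length(bl$W) + length(bl$b) + length(bl$gamma) +
      length(bl$beta)
  cnt + length(model@params$head$W) + length(model@params$head$b)
}

# ---- layer primitives -----------------------------------------------------

.bnEps <- 1e-5
.bnMomentum <- 0.1

# One CBR block: valid 3^3 convolution, batch norm, ReLU (the BN/ReLU
# pair runs in a fused C++ kernel).  x: 5D (D,H,W,C,N).
.cbrForward <- function(x, par, train) {
  z <- .conv3dForward(x, as.integer(dim(x)), par$W, par$b)
  bn <- .bnReluForward(z, as.integer(dim(z)), par$gamma, par$beta,
                       par$runMean, par$runVar, .bnMomentum, .bnEps,
                       as.integer(train))
  list(a = bn$y,
       cache = list(x = x, y = bn$y, xhat = bn$xhat, invstd = bn$invstd),
       runMean = bn$runMean, runVar = bn$runVar)
}

.cbrBackward <- function(da, par, cache) {
  bn <- .bnReluBackward(da, cache$y, cache$xhat,
                        as.integer(dim(cache$y)), cache$invstd, par$gamma)
  cv <- .conv3dBackward(cache$x, as.integer(dim(cache$x)), par$W, bn$dx)
  list(dx = cv$dx,
       grads = list(W = cv$dw, b = cv$db, gamma = bn$dgamma,
                    beta = bn$dbeta))
}

# per-axis upsampling matrix (factor 2); rows = output positions
.upMat <- function(n, mode) {
  out <- 2L * n
  W <- matrix(0, out, n)
  if (mode == "nearest") {
    W[cbind(seq_len(out), floor((seq_len(out) - 1) / 2) + 1L)] <- 1
  } else { # trilinear: out o (0-based) samples src at (o - 0.5) / 2
    p <- ((seq_len(out) - 1) - 0.5) / 2
    i0 <- pmin(pmax(floor(p), 0), n - 1)
    i1 <- pmin(i0 + 1, n - 1)
    f <- pmin(pmax(p - floor(p), 0), 1)
    f[floor(p) < 0] <- 0
    W[cbind(seq_len(out), i0 + 1L)] <- W[cbind(seq_len(out), i0 + 1L)] + (1 - f)
    W[cbind(seq_len(out), i1 + 1L)] <- W[cbind(seq_len(out), i1 + 1L)] + f
  }
  W
}

.applyAxis <- function(x, axis, Wm) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- Wm %*% matrix(xp, nrow = dp[1])
  dim(y) <- c(nrow(Wm), dp[-1])
  aperm(y, order(perm))
}

.upsample2 <- function(x, mode) {
  if (mode == "nearest")
    return(.upsample2Nearest(x, as.integer(dim(x))))
  for (ax in 1:3) x <- .applyAxis(x, ax, .upMat(dim(x)[ax], mode))
  x
}

.upsample2Backward <- function(dy, mode) {
  if (mode == "nearest")
    return(.upsample2NearestBackward(dy, as.integer(dim(dy))))
  for (ax in 1:3) dy <- .applyAxis(dy, ax, t(.upMat(dim(dy)[ax] / 2L, mode)))
  dy
}

.centerCrop <- function(x, m) {
  S <- dim(x)[1]
  o <- floor((S - m) / 2)
  x[o + seq_len(m), o + seq_len(m), o + seq_len(m), , , drop = FALSE]
}

.centerUncrop <- function(dx, S) {
  m <- dim(dx)[1]
  o <- floor((S - m) / 2)
  out <- array(0, c(S, S, S, dim(dx)[4], dim(dx)[5]))
  out[o + seq_len(m), o + seq_len(m), o + seq_len(m), , ] <- dx
  out
}

# ---- full network forward / backward -------------------------------------

# xlev: list of L arrays (P,P,P,1,N).  Returns probs, logits, cache and
# (in training mode) parameters with updated running statistics.
.fnetForward <- function(params, cfg, xlev, train = FALSE) {
  L <- cfg$levels
  cache <- list(pathways = vector("list", L),
                integration = vector("list", length(params$integration)))
  pathOut <- vector("list", L)
  for (l in seq_len(L)) {
    a <- xlev[[l]]
    bcaches <- vector("list", cfg$blocksPerPathway)
    for (b in seq_len(cfg$blocksPerPathway)) {
      r <- .cbrForward(a, params$pathways[[l]][[b]], train)
      a <- r$a
      bcaches[[b]] <- r$cache
      if (train) {
        params$pathways[[l]][[b]]$runMean <- r$runMean
        params$pathways[[l]][[b]]$runVar <- r$runVar
      }
    }
    cache$pathways[[l]] <- bcaches
    pathOut[[l]] <- a
  }
  if (L == 1L) {
    r <- .cbrForward(pathOut[[1]], params$integration[[1]], train)
    cur <- r$a
    cache$integration[[1]] <- list(cbr = r$cache, level = 1L,
                                   mode = "single")
    if (train) {
      params$integration[[1]]$runMean <- r$runMean
      params$integration[[1]]$runVar <- r$runVar
    }
  } else {
    cur <- pathOut[[L]]
    for (i in seq_len(L - 1L)) {
      l <- L - i
      up <- .upsample2(cur, cfg$upsampleMode)
      S <- dim(pathOut[[l]])[1]
      m <- min(S, dim(up)[1])
      a <- .centerCrop(pathOut[[l]], m)
      u <- .centerCrop(up, m)
      cB <- dim(a)[4]
      xcat <- array(0, c(m, m, m, cB + dim(u)[4], dim(a)[5]))
      xcat[, , , seq_len(cB), ] <- a
      xcat[, , , cB + seq_len(dim(u)[4]), ] <- u
      r <- .cbrForward(xcat, params$integration[[i]], train)
      cache$integration[[i]] <- list(cbr = r$cache, level = l, S = S,
                                     upDim = dim(up), m = m, cB = cB,
                                     mode = "merge")
      if (train) {
        params$integration[[i]]$runMean <- r$runMean
        params$integration[[i]]$runVar <- r$runVar
      }
      cur <- r$a
    }
  }
  # 1x1x1 projection + channel-wise softmax
  d <- dim(cur)
  xp <- aperm(cur, c(1, 2, 3, 5, 4))
  xm <- matrix(xp, ncol = d[4])
  logits <- sweep(xm %*% params$head$W, 2, params$head$b, `+`)
  mx <- logits[, 1]
  for (j in seq_len(ncol(logits))[-1]) mx <- pmax(mx, logits[, j])
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  outDim <- c(d[1:3], d[5], cfg$nClasses)
  probsArr <- aperm(array(probs, outDim), c(1, 2, 3, 5, 4))
  cache$head <- list(xm = xm, curDim = d, probs = probs)
  list(probs = probsArr, cache = cache, params = params)
}

# dlogits: 5D (O,O,O,nClasses,N) gradient w.r.t. the pre-softmax logits
.fnetBackward <- function(params, cfg, cache, dlogits) {
  L <- cfg$levels
  grads <- list(pathways = vector("list", L),
                integration = vector("list", length(params$integration)),
                head = NULL)
  d <- cache$head$curDim
  dlm <- matrix(aperm(dlogits, c(1, 2, 3, 5, 4)),
                ncol = dim(dlogits)[4])
  grads$head <- list(W = crossprod(cache$head$xm, dlm), b = colSums(dlm))
  dxm <- tcrossprod(dlm, params$head$W)
  dcur <- aperm(array(dxm, c(d[1:3], d[5], d[4])), c(1, 2, 3, 5, 4))

  dPathOut <- vector("list", L)
  if (L == 1L) {
    r <- .cbrBackward(dcur, params$integration[[1]],
                      cache$integration[[1]]$cbr)
    grads$integration[[1]] <- r$grads
    dPathOut[[1]] <- r$dx
  } else {
    for (i in seq(L - 1L, 1L)) {
      st <- cache$integration[[i]]
      r <- .cbrBackward(dcur, params$integration[[i]], st$cbr)
      grads$integration[[i]] <- r$grads
      dxcat <- r$dx
      da <- dxcat[, , , seq_len(st$cB), , drop = FALSE]
      du <- dxcat[, , , st$cB + seq_len(dim(dxcat)[4] - st$cB), ,
                  drop = FALSE]
      dPathOut[[st$level]] <- .centerUncrop(da, st$S)
      dup <- .centerUncrop(du, st$upDim[1])
      dcur <- .upsample2Backward(dup, cfg$upsampleMode)
    }
    dPathOut[[L]] <- dcur
  }
  for (l in seq_len(L)) {
    da <- dPathOut[[l]]
    gl <- vector("list", cfg$blocksPerPathway)
    for (b in seq(cfg$blocksPerPathway, 1L)) {
      r <- .cbrBackward(da, params$pathways[[l]][[b]],
                        cache$pathways[[l]][[b]])
      gl[[b]] <- r$grads
      da <- r$dx
    }
    grads$pathways[[l]] <- gl
  }
  grads
}

#' Run the network on a batch of patch pyramids
#'
#' Evaluation-mode forward pass (batch statistics frozen to the running
#' values).  The output spatial size and its offset within the finest
#' level patch follow [fnetShapes()] for the pyramids' patch size.
#'
#' @param model an [FnetModel-class].
#' @param pyramids a [PatchPyramid-class] or list of them (all with the
#'   same patch size and `model@config$levels` levels).
#' @return A list of [ProbabilityMap-class], one per pyramid, in input
#'   order.
#' @export
forwardFnet <- function(model, pyramids) {
  stopifnot(is(model, "FnetModel"))
  if (is(pyramids, "PatchPyramid")) pyramids <- list(pyramids)
  cfg <- structure(model@config, class = "FnetConfig")
  L <- cfg$levels
  if (length(pyramids[[1]]@patches) != L)
    stop("pyramid has ", length(pyramids[[1]]@patches),
         " levels but the model expects ", L)
  P <- dim(pyramids[[1]]@patches[[1]])[1]
  sh <- fnetShapes(cfg, P)
  N <- length(pyramids)
  xlev <- lapply(seq_len(L), function(l) {
    arr <- array(0, c(P, P, P, 1, N))
    for (n in seq_len(N)) arr[, , , 1, n] <- pyramids[[n]]@patches[[l]]
    arr
  })
  fw <- .fnetForward(model@params, cfg, xlev, train = FALSE)
  lapply(seq_len(N), function(n) {
    sp <- pyramids[[n]]@spacing
    new("ProbabilityMap",
        data = fw$probs[, , , , n, drop = TRUE],
        spacing = sp,
        origin = pyramids[[n]]@center -
          (P - 1) / 2 * sp + sh$outputOffset * sp,
        offset = rep(sh$outputOffset, 3L))
  })
}

#' Save / load a foveal network
#'
#' A model is stored as a single RDS file holding a tagged plain list
#' (`format`, `config`, `params`, `preprocess`) that round-trips the
#' configuration, all parameters and the preprocessing state.
#'
#' @param model an [FnetModel-class].
#' @param path file path.
#' @return `saveFnet` returns `path` invisibly; `loadFnet` returns the
#'   [FnetModel-class].
#' @export
saveFnet <- function(model, path) {
  stopifnot(is(model, "FnetModel"))
  saveRDS(list(format = "fovealCT-fnet-1", config = model@config,
               params = model@params, preprocess = model@preprocess),
          path)
  invisible(path)
}

#' @rdname saveFnet
#' @export
loadFnet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fovealCT-fnet-1"))
    stop("not a fovealCT model checkpoint: ", path)
  new("FnetModel", config = obj$config, params = obj$params,
      preprocess = obj$preprocess)
}
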