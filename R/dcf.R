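# Dilated convolution framework (DCF): two parallel sub-frameworks of 4
# blocks whose kernels are distance-tied and corner/center-masked so each
# spot pixel's embedding reads only its closest lattice neighbours.
#
# Tied weights are parameterized directly: each tie group is one trainable
# scalar per (out, in) channel pair, broadcast into the kernel at forward
# time. Zero positions simply have no parameter. The mask/tie invariants
# therefore hold bitwise after every optimizer step, which is the "extra
# trainable parameter substitution" expressed as a parameterization.

#' Kernel specifications for a platform
#'
#' Returns the pair of constrained kernel specs the two sub-frameworks use.
#' \itemize{
#'   \item visium: a 3x3 kernel with dilation 2 (corners zeroed; tie
#'     groups \{center\} and \{4 edge midpoints\}) and a 2x2 kernel with
#'     dilation 2 centered on offsets (+-1, +-1) (all 4 taps tied), so a
#'     spot pixel reads itself and its 8 closest spot pixels;
#'   \item stereo: an undilated 3x3 kernel (ties \{center\}, \{edges\},
#'     \{corners\}) and a 3x3 kernel with dilation 2 whose corners and
#'     center are zeroed (ties \{edge midpoints\}), so a spot pixel reads
#'     itself and its 12 closest neighbours.
#' }
#'
#' @param platform `"visium"` or `"stereo"`.
#' @param tie_weights if FALSE (ablation "no considering distance"), every
#'   active tap gets its own weight.
#' @param zero_corners if FALSE (ablation "containing corners"), the 3x3
#'   corner taps become active weights instead of constant zeros.
#' @return list of two kernel specs; each spec has `size`, `dilation`,
#'   `taps` (data.frame of active offsets dy, dx and their tie `group`),
#'   `n_groups` and `zero_offsets`.
#' @export
makeKernelSpecs <- function(platform = c("visium", "stereo"),
                            tie_weights = TRUE, zero_corners = TRUE) {
  platform <- match.arg(platform)
  mk <- function(size, dilation, active, groups, zero, name) {
    taps <- data.frame(dy = active[, 1], dx = active[, 2], group = groups)
    if (!tie_weights) taps$group <- seq_len(nrow(taps))
    list(size = size, dilation = dilation, taps = taps,
         n_groups = max(taps$group),
         zero_offsets = zero, name = name)
  }
  corners2 <- cbind(c(-2, -2, 2, 2), c(-2, 2, -2, 2))
  edges2 <- cbind(c(0, 0, -2, 2), c(-2, 2, 0, 0))
  if (platform == "visium") {
    if (zero_corners) {
      s1 <- mk(3L, 2L, rbind(c(0, 0), edges2), c(1, 2, 2, 2, 2),
               corners2, "3x3-d2")
    } else {
      s1 <- mk(3L, 2L, rbind(c(0, 0), edges2, corners2),
               c(1, 2, 2, 2, 2, 3, 3, 3, 3),
               cbind(integer(0), integer(0)), "3x3-d2-corners")
    }
    diag1 <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
    s2 <- mk(2L, 2L, diag1, c(1, 1, 1, 1),
             cbind(integer(0), integer(0)), "2x2-d2")
    list(s1, s2)
  } else {
    edges1 <- cbind(c(0, 0, -1, 1), c(-1, 1, 0, 0))
    corners1 <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
    s1 <- mk(3L, 1L, rbind(c(0, 0), edges1, corners1),
             c(1, 2, 2, 2, 2, 3, 3, 3, 3),
             cbind(integer(0), integer(0)), "3x3-d1")
    zero2 <- rbind(corners2, c(0, 0))
    if (!zero_corners) {
      s2 <- mk(3L, 2L, rbind(edges2, corners2),
               c(1, 1, 1, 1, 2, 2, 2, 2), rbind(c(0, 0)), "3x3-d2-corners")
    } else {
      s2 <- mk(3L, 2L, edges2, c(1, 1, 1, 1), zero2, "3x3-d2-hollow")
    }
    list(s1, s2)
  }
}

.spec1x1 <- function() {
  list(size = 1L, dilation = 1L,
       taps = data.frame(dy = 0L, dx = 0L, group = 1L),
       n_groups = 1L, zero_offsets = cbind(integer(0), integer(0)),
       name = "1x1")
}

# source-pixel index map for one tap offset on an h x w canvas
.tapIndexMap <- function(h, w, dy, dx) {
  r <- rep(seq_len(h), w)
  cc <- rep(seq_len(w), each = h)
  sr <- r + dy
  sc <- cc + dx
  valid <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  list(idx = sr + h * (sc - 1L), valid = valid)
}

.convCtx <- function(spec, h, w) {
  lapply(seq_len(nrow(spec$taps)), function(t)
    .tapIndexMap(h, w, spec$taps$dy[t], spec$taps$dx[t]))
}

# Materialize the size x size kernel grid from free (tied) parameters.
# Zero positions are structurally zero; tie-group members are bitwise
# identical copies of the one free scalar.
#' Full kernel tensor from free tied parameters
#'
#' @param W free-parameter array out x in x n_groups.
#' @param spec a kernel spec from \code{\link{makeKernelSpecs}}.
#' @return array out x in x size x size, zeros at masked positions.
#' @export
kernelTensor <- function(W, spec) {
  d <- dim(W)
  K <- array(0, c(d[1], d[2], spec$size, spec$size))
  ctr <- (spec$size + 1) / 2
  for (t in seq_len(nrow(spec$taps))) {
    ki <- spec$taps$dy[t] / spec$dilation + ctr
    kj <- spec$taps$dx[t] / spec$dilation + ctr
    K[, , ki, kj] <- W[, , spec$taps$group[t]]
  }
  K
}

#' Enforce zero-mask and tie-group constraints on a full kernel tensor
#'
#' Sets masked positions to exactly 0 and substitutes, within each tie
#' group, the value at the group's first position into all members (the
#' "extra trainable parameter" substitution applied after a gradient
#' update). Idempotent.
#'
#' @param K array out x in x size x size.
#' @param spec a kernel spec.
#' @export
enforceConstraints <- function(K, spec) {
  ctr <- (spec$size + 1) / 2
  if (nrow(spec$zero_offsets))
    for (z in seq_len(nrow(spec$zero_offsets))) {
      ki <- spec$zero_offsets[z, 1] / spec$dilation + ctr
      kj <- spec$zero_offsets[z, 2] / spec$dilation + ctr
      K[, , ki, kj] <- 0
    }
  for (g in seq_len(spec$n_groups)) {
    members <- which(spec$taps$group == g)
    rep_t <- members[1]
    ki <- spec$taps$dy[rep_t] / spec$dilation + ctr
    kj <- spec$taps$dx[rep_t] / spec$dilation + ctr
    val <- K[, , ki, kj]
    for (t in members[-1]) {
      ti <- spec$taps$dy[t] / spec$dilation + ctr
      tj <- spec$taps$dx[t] / spec$dilation + ctr
      K[, , ti, tj] <- val
    }
  }
  K
}

# ---- layer primitives (feature maps are channels x npix matrices, ----
# ---- pixels in column-major order over the h x w canvas)          ----

.convForward <- function(X, layer, spec, ctx) {
  outC <- dim(layer$W)[1]; inC <- dim(layer$W)[2]
  nT <- nrow(spec$taps); npix <- ncol(X)
  M <- matrix(0, nT * inC, npix)
  Wmat <- matrix(0, outC, nT * inC)
  for (t in seq_len(nT)) {
    rows <- (t - 1L) * inC + seq_len(inC)
    v <- ctx[[t]]$valid
    M[rows, v] <- X[, ctx[[t]]$idx[v], drop = FALSE]
    Wmat[, rows] <- layer$W[, , spec$taps$group[t]]
  }
  list(out = Wmat %*% M + layer$b, M = M, Wmat = Wmat)
}

.convBackward <- function(dOut, cache, layer, spec, ctx, input_grad = TRUE) {
  outC <- dim(layer$W)[1]; inC <- dim(layer$W)[2]
  nT <- nrow(spec$taps); npix <- ncol(dOut)
  db <- rowSums(dOut)
  dWmat <- tcrossprod(dOut, cache$M)          # outC x (nT*inC)
  dW <- array(0, dim(layer$W))
  dX <- if (input_grad) matrix(0, inC, npix) else NULL
  dM <- if (input_grad) crossprod(cache$Wmat, dOut) else NULL
  for (t in seq_len(nT)) {
    rows <- (t - 1L) * inC + seq_len(inC)
    g <- spec$taps$group[t]
    dW[, , g] <- dW[, , g] + dWmat[, rows]
    if (input_grad) {
      v <- ctx[[t]]$valid
      idx <- ctx[[t]]$idx[v]
      dX[, idx] <- dX[, idx, drop = FALSE] + dM[rows, v, drop = FALSE]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

.bnForward <- function(X, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    m <- rowMeans(X)
    xc <- X - m
    v <- rowMeans(xc^2)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * m
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v
  } else {
    m <- bn$rmean
    v <- bn$rvar
    xc <- X - m
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = xhat * bn$gamma + bn$beta, bn = bn,
       cache = list(xhat = xhat, istd = istd, training = training))
}

.bnBackward <- function(dOut, cache, bn) {
  dgamma <- rowSums(dOut * cache$xhat)
  dbeta <- rowSums(dOut)
  dxhat <- dOut * bn$gamma
  if (cache$training) {
    dX <- cache$istd * (dxhat - rowMeans(dxhat) -
                          cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dX <- dxhat * cache$istd
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' Initialize DCF parameters
#'
#' Two sub-frameworks of 4 blocks: three (constrained conv, batch norm,
#' ReLU) units with `hidden` channels, then a 1x1 conv to `n` channels.
#' Free weights get fan-in uniform init under a fixed seed.
#'
#' @param in_channels input channel count (15 in the default pipeline).
#' @param n cluster number (output channels).
#' @param platform `"visium"` or `"stereo"`.
#' @param hidden hidden channels (default 100).
#' @param seed RNG seed for the initialization.
#' @param sub_weights weights combining the two sub-framework outputs;
#'   default 0.7/0.3 (visium: 3x3 branch first) or 0.9/0.1 (stereo:
#'   undilated branch first).
#' @param tie_weights,zero_corners kernel-constraint switches (ablations).
#' @return parameter list consumed by \code{\link{dcfForward}}.
#' @export
dcfInit <- function(in_channels, n, platform = c("visium", "stereo"),
                    hidden = 100L, seed = 0,
                    sub_weights = NULL, tie_weights = TRUE,
                    zero_corners = TRUE) {
  platform <- match.arg(platform)
  if (is.null(sub_weights))
    sub_weights <- if (platform == "visium") c(0.7, 0.3) else c(0.9, 0.1)
  specs <- makeKernelSpecs(platform, tie_weights, zero_corners)
  withr::with_seed(seed, {
    subs <- lapply(1:2, function(f) {
      spec <- specs[[f]]
      chans <- c(in_channels, hidden, hidden, hidden)
      conv <- vector("list", 4)
      bn <- vector("list", 3)
      for (j in 1:3) {
        nT <- nrow(spec$taps)
        bound <- 1 / sqrt(chans[j] * nT)
        conv[[j]] <- list(
          W = array(stats::runif(chans[j + 1] * chans[j] * spec$n_groups,
                                 -bound, bound),
                    c(chans[j + 1], chans[j], spec$n_groups)),
          b = stats::runif(chans[j + 1], -bound, bound))
        bn[[j]] <- list(gamma = rep(1, chans[j + 1]),
                        beta = rep(0, chans[j + 1]),
                        rmean = rep(0, chans[j + 1]),
                        rvar = rep(1, chans[j + 1]))
      }
      bound <- 1 / sqrt(hidden)
      conv[[4]] <- list(W = array(stats::runif(n * hidden, -bound, bound),
                                  c(n, hidden, 1L)),
                        b = stats::runif(n, -bound, bound))
      list(conv = conv, bn = bn, spec = spec)
    })
    list(sub = subs, sub_weights = sub_weights, n = as.integer(n),
         hidden = as.integer(hidden), in_channels = as.integer(in_channels),
         platform = platform)
  })
}

#' Forward pass of the DCF
#'
#' @param params parameters from \code{\link{dcfInit}}.
#' @param img a \linkS4class{VirtualImage}.
#' @param training TRUE uses batch statistics in the normalization layers
#'   (and updates the running statistics); FALSE uses running statistics.
#' @return list with `O` (n x h x w feature image as an n x npix matrix
#'   plus `dims`), `E` (spots x n embeddings read at the spot pixels),
#'   updated `params`, and a `cache` for \code{\link{dcfBackward}}.
#' @export
dcfForward <- function(params, img, training = TRUE) {
  d <- dim(img@X)
  if (d[1] != params$in_channels)
    stop("image has ", d[1], " channels; model expects ", params$in_channels)
  h <- d[2]; w <- d[3]
  Xmat <- matrix(img@X, nrow = d[1])
  caches <- vector("list", 2)
  Os <- vector("list", 2)
  for (f in 1:2) {
    spec <- params$sub[[f]]$spec
    ctx <- .convCtx(spec, h, w)
    ctx1 <- .convCtx(.spec1x1(), h, w)
    A <- Xmat
    lay <- vector("list", 4)
    for (j in 1:3) {
      cv <- .convForward(A, params$sub[[f]]$conv[[j]], spec, ctx)
      bnf <- .bnForward(cv$out, params$sub[[f]]$bn[[j]], training)
      params$sub[[f]]$bn[[j]] <- bnf$bn
      mask <- bnf$out > 0
      A <- bnf$out * mask
      lay[[j]] <- list(conv = cv[c("M", "Wmat")], bn = bnf$cache,
                       relu = mask)
    }
    cv4 <- .convForward(A, params$sub[[f]]$conv[[4]], .spec1x1(), ctx1)
    lay[[4]] <- list(conv = cv4[c("M", "Wmat")])
    Os[[f]] <- cv4$out
    caches[[f]] <- list(lay = lay, ctx = ctx, ctx1 = ctx1)
  }
  O <- params$sub_weights[1] * Os[[1]] + params$sub_weights[2] * Os[[2]]
  E <- t(O[, .spotLinearIndex(img), drop = FALSE])
  list(O = O, dims = c(params$n, h, w), E = E, params = params,
       cache = caches)
}

#' Backward pass of the DCF
#'
#' @param params parameter list.
#' @param cache cache returned by \code{\link{dcfForward}} (training mode).
#' @param dO gradient of the loss w.r.t. the combined feature image, as an
#'   n x npix matrix.
#' @param input_grad also return the gradient w.r.t. the input image.
#' @return list with `grads` mirroring the trainable parameters and,
#'   optionally, `dX` (in_channels x npix).
#' @export
dcfBackward <- function(params, cache, dO, input_grad = FALSE) {
  grads <- list(sub = vector("list", 2))
  dXtot <- NULL
  for (f in 1:2) {
    spec <- params$sub[[f]]$spec
    lay <- cache[[f]]$lay
    dA <- params$sub_weights[f] * dO
    g <- list(conv = vector("list", 4), bn = vector("list", 3))
    bk4 <- .convBackward(dA, lay[[4]]$conv, params$sub[[f]]$conv[[4]],
                         .spec1x1(), cache[[f]]$ctx1, input_grad = TRUE)
    g$conv[[4]] <- list(W = bk4$dW, b = bk4$db)
    dA <- bk4$dX
    for (j in 3:1) {
      dA <- dA * lay[[j]]$relu
      bnb <- .bnBackward(dA, lay[[j]]$bn, params$sub[[f]]$bn[[j]])
      g$bn[[j]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
      need_in <- j > 1 || input_grad
      cvb <- .convBackward(bnb$dX, lay[[j]]$conv, params$sub[[f]]$conv[[j]],
                           spec, cache[[f]]$ctx, input_grad = need_in)
      g$conv[[j]] <- list(W = cvb$dW, b = cvb$db)
      dA <- cvb$dX
    }
    grads$sub[[f]] <- g
    if (input_grad)
      dXtot <- if (is.null(dXtot)) dA else dXtot + dA
  }
  list(grads = grads, dX = dXtot)
}

#' Apply one constrained convolution layer (audit helper)
#'
#' Runs a single conv layer with the given spec over an image-shaped
#' input; with `grad_at`, also returns the gradient of that output pixel
#' and channel w.r.t. the input, for receptive-field audits.
#'
#' @param X channels x h x w array.
#' @param layer list with free weights `W` (out x in x n_groups) and `b`.
#' @param spec a kernel spec.
#' @param grad_at optional c(channel, row, col) (1-based) output position.
#' @return list with `out` (out-channels x h x w) and optionally `dX`.
#' @export
constrainedConv <- function(X, layer, spec, grad_at = NULL) {
  d <- dim(X)
  ctx <- .convCtx(spec, d[2], d[3])
  cv <- .convForward(matrix(X, nrow = d[1]), layer, spec, ctx)
  out <- array(cv$out, c(dim(layer$W)[1], d[2], d[3]))
  res <- list(out = out)
  if (!is.null(grad_at)) {
    dOut <- matrix(0, dim(layer$W)[1], d[2] * d[3])
    dOut[grad_at[1], grad_at[2] + d[2] * (grad_at[3] - 1L)] <- 1
    bk <- .convBackward(dOut, cv, layer, spec, ctx, input_grad = TRUE)
    res$dX <- array(bk$dX, c(d[1], d[2], d[3]))
  }
  res
}

# ---- flat parameter traversal (for the optimizer) ----

.paramPaths <- function(params) {
  out <- character(0)
  for (f in 1:2) {
    for (j in 1:4)
      out <- c(out, paste0("sub.", f, ".conv.", j, ".W"),
               paste0("sub.", f, ".conv.", j, ".b"))
    for (j in 1:3)
      out <- c(out, paste0("sub.", f, ".bn.", j, ".gamma"),
               paste0("sub.", f, ".bn.", j, ".beta"))
  }
  out
}

.getPath <- function(x, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    ik <- suppressWarnings(as.integer(k))
    x <- if (!is.na(ik)) x[[ik]] else x[[k]]
  }
  x
}

.setPath <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    ik <- suppressWarnings(as.integer(keys))
    if (!is.na(ik)) x[[ik]] <- value else x[[keys]] <- value
    return(x)
  }
  k <- keys[1]
  ik <- suppressWarnings(as.integer(k))
  rest <- paste(keys[-1], collapse = ".")
  if (!is.na(ik)) x[[ik]] <- .setPath(x[[ik]], rest, value)
  else x[[k]] <- .setPath(x[[k]], rest, value)
  x
}

#' Adam optimizer state
#' @param params parameter list (DCF params, optionally with extra flat
#'   entries such as the centroid matrix).
#' @param paths character vector of parameter paths to optimize.
#' @export
adamInit <- function(params, paths = .paramPaths(params)) {
  st <- lapply(paths, function(p) {
    v <- .getPath(params, p)
    list(m = 0 * v, v = 0 * v)  # zeros with the parameter's own shape
  })
  names(st) <- paths
  list(state = st, t = 0L, paths = paths)
}

#' One Adam step
#' @param params parameter list.
#' @param grads gradient list with the same structure.
#' @param opt state from \code{\link{adamInit}}.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam constants.
#' @return list(params, opt) with updated values.
#' @export
adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (p in opt$paths) {
    g <- .getPath(grads, p)
    if (is.null(g)) next
    s <- opt$state[[p]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    opt$state[[p]] <- s
    val <- .getPath(params, p)
    val <- val - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    params <- .setPath(params, p, val)
  }
  list(params = params, opt = opt)
}
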