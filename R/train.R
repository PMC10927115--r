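# Training of the DCF: cross-entropy pre-training on AGC pseudo-labels,
# then the composite objective L_t = w_kl*L1 + w_ce*L2 + w_cont*L3 with
# DEC-style soft assignment Q, sharpened target P (refreshed every 4
# iterations and treated as a constant), high-confidence cross-entropy,
# and a lattice continuity penalty on the embeddings.

.EPS <- 1e-12

#' Default training configuration
#'
#' All constants of the method with their platform defaults: loss weights
#' 0.78 (KL), 0.71 (high-confidence cross-entropy), 1 (continuity);
#' continuity direction weights 0.62 (orthogonal) and 0.58/0 (diagonal,
#' visium/stereo); q_cut 0.5; learning rates 0.05/0.01 (visium) or
#' 0.005/0.001 (stereo) for pre-training/training; at most 200
#' pre-training and 400 training iterations; P refreshed every 4
#' iterations; stop when unique labels drop below n, a cluster's share
#' drops below 0.01, or the label-change ratio at a P refresh falls below
#' 0.001.
#'
#' @param platform `"visium"` or `"stereo"`.
#' @param n cluster number.
#' @return a named list; fields can be overridden before use.
#' @export
trainConfig <- function(platform = c("visium", "stereo"), n) {
  platform <- match.arg(platform)
  list(platform = platform, n = as.integer(n),
       q_cut = 0.5,
       loss_weights = c(kl = 0.78, ce = 0.71, cont = 1.0),
       cont_weights = c(ortho = 0.62,
                        diag = if (platform == "visium") 0.58 else 0.0),
       lr_pre = if (platform == "visium") 0.05 else 0.005,
       lr_train = if (platform == "visium") 0.01 else 0.001,
       max_pre = 200L, max_train = 400L,
       p_refresh = 4L, min_frac = 0.01, change_tol = 0.001,
       hidden = 100L, seed = 0L,
       tie_weights = TRUE, zero_corners = TRUE,
       stop_in_pretrain = TRUE)
}

#' Student-t soft assignment Q
#'
#' q_ij = (1 + ||E_i - mu_j||^2)^-1, row-normalized.
#'
#' @param E spots x n embeddings.
#' @param mu n x n centroid matrix.
#' @export
softAssign <- function(E, mu) {
  d2 <- outer(rowSums(E^2), rowSums(mu^2), "+") - 2 * tcrossprod(E, mu)
  U <- 1 / (1 + pmax(d2, 0))
  U / rowSums(U)
}

#' Sharpened target distribution P
#'
#' p_ij = (q_ij^2 / f_j) row-normalized, f_j the soft cluster frequency.
#'
#' @param Q row-stochastic soft assignment.
#' @export
targetDistribution <- function(Q) {
  f <- colSums(Q)
  if (any(f <= 0)) stop("cluster with zero total soft mass")
  W <- sweep(Q^2, 2, f, "/")
  W / rowSums(W)
}

#' KL divergence KL(P || Q)
#'
#' sum_ij p_ij ln(p_ij / q_ij) with 0 ln 0 = 0 and an epsilon guard inside
#' the logs. P is a constant target: gradients flow only through Q.
#'
#' @param P,Q matched row-stochastic matrices.
#' @export
klLoss <- function(P, Q) {
  sum(P * (log(P + .EPS) - log(Q + .EPS)))
}

#' High-confidence cross-entropy
#'
#' Over spots whose top soft-assignment probability exceeds `q_cut`, the
#' mean of -ln(q at the argmax). q_cut = 0 includes every spot (the "ce"
#' ablation); an empty high-confidence set returns 0.
#'
#' @param Q row-stochastic soft assignment.
#' @param q_cut confidence threshold (default 0.5).
#' @export
highConfCE <- function(Q, q_cut = 0.5) {
  qmax <- apply(Q, 1, max)
  keep <- qmax > q_cut
  if (!any(keep)) return(0)
  mean(-log(qmax[keep] + .EPS))
}

# lattice-neighbour spot pairs at the platform's closest offsets
.neighborPairs <- function(spot_index, platform) {
  key <- paste(spot_index[, 1], spot_index[, 2])
  lookup <- seq_len(nrow(spot_index))
  names(lookup) <- key
  offs <- if (platform == "visium")
    list(ortho = rbind(c(0, 2), c(2, 0)),
         diag = rbind(c(1, 1), c(1, -1)))
  else
    list(ortho = rbind(c(0, 1), c(1, 0)),
         diag = rbind(c(1, 1), c(1, -1)))
  pairs <- function(om) {
    a <- integer(0); b <- integer(0)
    for (r in seq_len(nrow(om))) {
      nk <- paste(spot_index[, 1] + om[r, 1], spot_index[, 2] + om[r, 2])
      j <- lookup[nk]
      ok <- !is.na(j)
      a <- c(a, which(ok)); b <- c(b, unname(j[ok]))
    }
    cbind(a, b)
  }
  list(ortho = pairs(offs$ortho), diag = pairs(offs$diag))
}

#' Spatial continuity loss on spot embeddings
#'
#' Weighted sum of the mean embedding distance over closest lattice
#' neighbours in the orthogonal (longitudinal + transverse) directions and
#' in the diagonal directions. On a staggered Visium array the closest
#' orthogonal pairs sit at lattice offsets (0, +-2)/(+-2, 0) and diagonal
#' pairs at (+-1, +-1); on a dense stereo grid orthogonal pairs are
#' (0, +-1)/(+-1, 0) and the diagonal weight is 0.
#'
#' @param E spots x n embeddings.
#' @param spot_index spots x 2 lattice coordinates (0-based).
#' @param platform `"visium"` or `"stereo"`.
#' @param cont_weights c(ortho =, diag =) direction weights.
#' @param pairs optional precomputed pair sets (from repeated calls).
#' @param grad if TRUE also return dL/dE.
#' @export
continuityLoss <- function(E, spot_index, platform,
                           cont_weights = c(ortho = 0.62, diag = 0.58),
                           pairs = NULL, grad = FALSE) {
  if (is.null(pairs)) pairs <- .neighborPairs(spot_index, platform)
  dE <- if (grad) matrix(0, nrow(E), ncol(E)) else NULL
  total <- 0
  for (dir in c("ortho", "diag")) {
    w <- cont_weights[[dir]]
    pp <- pairs[[dir]]
    if (w == 0 || nrow(pp) == 0) next
    diff <- E[pp[, 1], , drop = FALSE] - E[pp[, 2], , drop = FALSE]
    dist <- sqrt(rowSums(diff^2))
    total <- total + w * mean(dist)
    if (grad) {
      unit <- diff / pmax(dist, .EPS)
      unit[dist == 0, ] <- 0
      gg <- w * unit / nrow(pp)
      for (cidx in seq_len(ncol(E))) {
        dE[, cidx] <- dE[, cidx] +
          tabulateSum(pp[, 1], gg[, cidx], nrow(E)) -
          tabulateSum(pp[, 2], gg[, cidx], nrow(E))
      }
    }
  }
  if (grad) list(loss = total, dE = dE) else total
}

# scatter-add helper: sum values by index into a length-n vector
tabulateSum <- function(index, values, n) {
  as.vector(tapplySum(index, values, n))
}

tapplySum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Weighted total loss
#' @param L1,L2,L3 loss components (KL, high-confidence CE, continuity).
#' @param loss_weights c(kl =, ce =, cont =); defaults 0.78, 0.71, 1.
#' @export
totalLoss <- function(L1, L2, L3,
                      loss_weights = c(kl = 0.78, ce = 0.71, cont = 1.0)) {
  loss_weights[["kl"]] * L1 + loss_weights[["ce"]] * L2 +
    loss_weights[["cont"]] * L3
}

#' Termination check for (pre-)training
#'
#' TRUE if (i) fewer unique labels than n, (ii) some cluster's share of
#' spots is below `min_frac`, or (iii) on an iteration where P was
#' refreshed, the label-change ratio since the previous iteration is below
#' `change_tol`.
#'
#' @param C current labels.
#' @param prev_C labels of the previous iteration (NULL skips (iii)).
#' @param n pre-specified cluster number.
#' @param min_frac minimal cluster share (default 0.01).
#' @param p_updated whether this iteration refreshed P.
#' @param change_tol label-change ratio threshold (default 0.001).
#' @return list(stop = logical, reason = character).
#' @export
stopCheck <- function(C, prev_C, n, min_frac = 0.01, p_updated = FALSE,
                      change_tol = 0.001) {
  if (length(unique(C)) < n)
    return(list(stop = TRUE, reason = "fewer unique labels than n"))
  shares <- tabulate(C + 1L, nbins = max(n, max(C) + 1L)) / length(C)
  if (min(shares[shares > 0]) < min_frac)
    return(list(stop = TRUE, reason = "cluster share below min_frac"))
  if (p_updated && !is.null(prev_C) &&
      mean(C != prev_C) < change_tol)
    return(list(stop = TRUE, reason = "label-change ratio below tolerance"))
  list(stop = FALSE, reason = "")
}

# gradient of a generic loss through the student-t soft assignment:
# gQ = dL/dQ; returns dL/dE and dL/dmu
.softAssignBackward <- function(E, mu, gQ) {
  d2 <- outer(rowSums(E^2), rowSums(mu^2), "+") - 2 * tcrossprod(E, mu)
  U <- 1 / (1 + pmax(d2, 0))
  rs <- rowSums(U)
  Q <- U / rs
  rowdot <- rowSums(gQ * Q)
  dU <- (gQ - rowdot) / rs
  cc <- -2 * dU * U^2
  crs <- rowSums(cc)
  dE <- crs * E - cc %*% mu
  dmu <- -(crossprod(cc, E) - colSums(cc) * mu)
  list(dE = dE, dmu = dmu)
}

.softmaxRows <- function(E) {
  m <- apply(E, 1, max)
  ex <- exp(E - m)
  ex / rowSums(ex)
}

#' Pre-train the DCF on AGC pseudo-labels
#'
#' Minimizes the cross-entropy between the row-softmax of the spot
#' embeddings E and the pre-clustering labels C0, enforcing the kernel
#' constraints (structurally) after every Adam step, until `max_iter` or a
#' \code{\link{stopCheck}} condition.
#'
#' @param params DCF parameters from \code{\link{dcfInit}}.
#' @param img the \linkS4class{VirtualImage}.
#' @param C0 0-based pseudo-labels, one per spot.
#' @param cfg configuration from \code{\link{trainConfig}}.
#' @return list(params, trace = per-iteration loss, stopped_at, reason).
#' @export
pretrainDcf <- function(params, img, C0, cfg) {
  s <- nrow(img@spot_index)
  if (length(C0) != s) stop("C0 length ", length(C0), " != spots ", s)
  if (cfg$max_pre == 0)
    return(list(params = params, trace = numeric(0), stopped_at = 0L,
                reason = "max_iter 0"))
  opt <- adamInit(params)
  lin <- .spotLinearIndex(img)
  onehot <- matrix(0, s, params$n)
  onehot[cbind(seq_len(s), C0 + 1L)] <- 1
  trace <- numeric(0)
  prev_C <- NULL
  reason <- "max_iter reached"
  iter_done <- cfg$max_pre
  for (iter in seq_len(cfg$max_pre)) {
    fw <- dcfForward(params, img, training = TRUE)
    params <- fw$params
    probs <- .softmaxRows(fw$E)
    loss <- -mean(log(probs[cbind(seq_len(s), C0 + 1L)] + .EPS))
    trace <- c(trace, loss)
    dE <- (probs - onehot) / s
    dO <- matrix(0, params$n, ncol(fw$O))
    dO[, lin] <- t(dE)
    bk <- dcfBackward(params, fw$cache, dO)
    st <- adamStep(params, bk$grads, opt, cfg$lr_pre)
    params <- st$params; opt <- st$opt
    C <- relabelless_argmax(probs)
    if (isTRUE(cfg$stop_in_pretrain)) {
      chk <- stopCheck(C, prev_C, params$n, cfg$min_frac,
                       p_updated = iter %% cfg$p_refresh == 1L,
                       change_tol = cfg$change_tol)
      if (chk$stop) { reason <- chk$reason; iter_done <- iter; break }
    }
    prev_C <- C
  }
  list(params = params, trace = trace, stopped_at = iter_done,
       reason = reason)
}

# argmax labels, 0-based, without renumbering
relabelless_argmax <- function(P) {
  max.col(P, ties.method = "first") - 1L
}

#' Train the DCF with the composite self-supervised objective
#'
#' Initializes the centroid matrix mu as the per-cluster mean of the
#' (inference-mode) embeddings under C0, then iterates: forward, soft
#' assignment Q, target refresh P (every `p_refresh` iterations, counted
#' from 1, held constant in between), losses L1 (KL), L2 (high-confidence
#' CE), L3 (continuity), Adam step on network weights and mu, label update
#' C = argmax Q, stop check.
#'
#' @param params pre-trained DCF parameters.
#' @param img the \linkS4class{VirtualImage}.
#' @param C0 0-based pseudo-labels (for the centroid initialization).
#' @param cfg configuration from \code{\link{trainConfig}}.
#' @return list(labels, params, mu, Q, traces (L1, L2, L3, Lt,
#'   change_ratio per iteration), stopped_at, reason).
#' @export
trainDcf <- function(params, img, C0, cfg) {
  s <- nrow(img@spot_index)
  lin <- .spotLinearIndex(img)
  # centroids from the same (batch-statistics) embeddings the loop uses;
  # inference-mode running stats are still warming up after pre-training
  fw <- dcfForward(params, img, training = TRUE)
  mu <- do.call(rbind, lapply(seq_len(params$n) - 1L, function(l) {
    i <- which(C0 == l)
    if (!length(i)) stats::runif(params$n, -0.1, 0.1)
    else colMeans(fw$E[i, , drop = FALSE])
  }))
  params$mu <- mu
  opt <- adamInit(params, paths = c(.paramPaths(params), "mu"))
  pairs <- .neighborPairs(img@spot_index, cfg$platform)
  traces <- list(L1 = numeric(0), L2 = numeric(0), L3 = numeric(0),
                 Lt = numeric(0), change = numeric(0))
  P <- NULL
  prev_C <- C0
  C <- C0
  reason <- "max_iter reached"
  iter_done <- cfg$max_train
  w <- cfg$loss_weights
  for (iter in seq_len(cfg$max_train)) {
    fw <- dcfForward(params, img, training = TRUE)
    params <- fw$params
    E <- fw$E
    Q <- softAssign(E, params$mu)
    p_updated <- iter %% cfg$p_refresh == 1L || is.null(P)
    if (p_updated) P <- targetDistribution(Q)
    L1 <- klLoss(P, Q)
    L2 <- highConfCE(Q, cfg$q_cut)
    cont <- continuityLoss(E, img@spot_index, cfg$platform,
                           cfg$cont_weights, pairs = pairs, grad = TRUE)
    L3 <- cont$loss
    Lt <- totalLoss(L1, L2, L3, w)

    # dLt/dQ from the KL and high-confidence CE terms
    gQ <- -w[["kl"]] * P / (Q + .EPS)
    if (w[["ce"]] != 0) {
      qmax <- apply(Q, 1, max)
      keep <- which(qmax > cfg$q_cut)
      if (length(keep)) {
        jmax <- max.col(Q, ties.method = "first")[keep]
        gQ[cbind(keep, jmax)] <- gQ[cbind(keep, jmax)] -
          w[["ce"]] / (length(keep) * (qmax[keep] + .EPS))
      }
    }
    sb <- .softAssignBackward(E, params$mu, gQ)
    dE <- sb$dE + w[["cont"]] * cont$dE
    dO <- matrix(0, params$n, ncol(fw$O))
    dO[, lin] <- t(dE)
    bk <- dcfBackward(params, fw$cache, dO)
    bk$grads$mu <- sb$dmu
    st <- adamStep(params, bk$grads, opt, cfg$lr_train)
    params <- st$params; opt <- st$opt

    C <- relabelless_argmax(Q)
    change <- mean(C != prev_C)
    traces$L1 <- c(traces$L1, L1); traces$L2 <- c(traces$L2, L2)
    traces$L3 <- c(traces$L3, L3); traces$Lt <- c(traces$Lt, Lt)
    traces$change <- c(traces$change, change)
    chk <- stopCheck(C, prev_C, params$n, cfg$min_frac,
                     p_updated = p_updated, change_tol = cfg$change_tol)
    if (chk$stop) { reason <- chk$reason; iter_done <- iter; break }
    prev_C <- C
  }
  list(labels = C, params = params, mu = params$mu, Q = Q,
       traces = traces, stopped_at = iter_done, reason = reason)
}
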