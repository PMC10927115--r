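#' Iterative Laplacian smoothing
#'
#' H_t = (I - L/lambda)^t F, computed by repeated multiplication. lambda
#' approximates the largest Laplacian eigenvalue; 1.5 is the conventional
#' value for a self-looped normalized Laplacian.
#'
#' @param F_mat spots x p feature matrix (typically the top 50 PC scores).
#' @param L normalized Laplacian.
#' @param lambda smoothing divisor (default 1.5).
#' @param t number of smoothing steps (t = 0 returns F unchanged).
#' @export
smoothFeatures <- function(F_mat, L, lambda = 1.5, t) {
  if (t < 0) stop("t must be >= 0")
  if (lambda <= 0) stop("lambda must be positive")
  H <- as.matrix(F_mat)
  for (i in seq_len(t)) H <- H - (L %*% H) / lambda
  H
}

#' Spectral embedding of the smoothed features
#'
#' The top `dim` eigenvectors of the similarity matrix H H^T, obtained as
#' the left singular vectors of H (identical since H H^T is PSD).
#' Deterministic: each column's largest-magnitude entry is made positive.
#'
#' @param H spots x p matrix.
#' @param dim embedding dimension (default 26).
#' @export
spectralEmbed <- function(H, dim = 26) {
  H <- as.matrix(H)
  if (dim > min(dim(H)))
    stop("dim = ", dim, " exceeds min(s, p) = ", min(dim(H)))
  sv <- svd(H, nu = dim, nv = 0)
  rk <- sum(sv$d > max(dim(H)) * .Machine$double.eps * max(sv$d, 0))
  if (dim > rk) stop("dim = ", dim, " exceeds rank(H) = ", rk)
  .fixSigns(sv$u)$loadings
}

#' Seeded k-means assignment
#'
#' Hartigan-Wong k-means with 10 restarts under a fixed seed; labels are
#' renumbered by first occurrence (spot 1 gets label 0) so the output is
#' deterministic and 0-based.
#'
#' @param R spots x dim embedding.
#' @param n number of clusters.
#' @param seed integer RNG seed.
#' @param nstart restarts (default 10).
#' @return integer vector of labels in [0, n).
#' @export
kmeansAssign <- function(R, n, seed, nstart = 10) {
  R <- as.matrix(R)
  if (n > nrow(R)) stop("more clusters than spots")
  if (n == 1) return(integer(nrow(R)))
  cl <- withr::with_seed(seed,
    stats::kmeans(R, centers = n, nstart = nstart, iter.max = 100)$cluster)
  relabelByFirstOccurrence(cl)
}

#' Renumber labels by order of first appearance (0-based)
#' @param labels any integer/factor labelling.
#' @export
relabelByFirstOccurrence <- function(labels) {
  u <- unique(labels)
  match(labels, u) - 1L
}

#' Intra-cluster distance of an assignment
#'
#' Mean over cluster labels of the average pairwise embedding distance
#' within the cluster, i.e. (1/|C|) sum_l [1/(|l|(|l|-1))] sum_{i != j in
#' l} ||H_i - H_j||_2. Singleton clusters have no pairs and contribute 0
#' (but still count in |C|).
#'
#' @param H spots x p embedding.
#' @param C cluster labels (any coding).
#' @export
intraClusterDistance <- function(H, C) {
  if (length(C) == 0) stop("empty assignment")
  H <- as.matrix(H)
  labs <- unique(C)
  per <- vapply(labs, function(l) {
    i <- which(C == l)
    if (length(i) < 2) return(0)
    mean(stats::dist(H[i, , drop = FALSE]))
  }, numeric(1))
  mean(per)
}

#' Adaptive graph convolution pre-clustering
#'
#' Iterates: one more smoothing step, spectral embedding, k-means, and the
#' intra-cluster distance of the assignment. The first time the
#' intra-cluster distance increases over the previous iteration, the loop
#' stops and the previous assignment is adopted; if no increase occurs by
#' `max_t`, the assignment with minimal intra-cluster distance is adopted.
#'
#' @param F_mat spots x p feature matrix (top 50 PCs).
#' @param L normalized Laplacian of the spot graph.
#' @param n pre-specified cluster number.
#' @param seed RNG seed; the iteration index is folded in per k-means call.
#' @param lambda smoothing divisor (default 1.5).
#' @param dim spectral embedding dimension (default 26, clipped to the
#'   feasible range).
#' @param max_t iteration cap (default 60).
#' @return a \linkS4class{PreClusterResult}.
#' @export
runAGC <- function(F_mat, L, n, seed = 0, lambda = 1.5, dim = 26,
                   max_t = 60) {
  F_mat <- as.matrix(F_mat)
  s <- nrow(F_mat)
  dim <- min(dim, s, ncol(F_mat))
  if (n == 1) {
    H <- smoothFeatures(F_mat, L, lambda, 1)
    R <- spectralEmbed(H, dim)
    return(new("PreClusterResult", labels = integer(s), stop_t = 1L,
               intra_trace = intraClusterDistance(R, integer(s)),
               embeddings = R))
  }
  H <- F_mat
  trace <- numeric(0)
  assigns <- list()
  embeds <- list()
  for (t in seq_len(max_t)) {
    H <- smoothFeatures(H, L, lambda, 1)
    R <- spectralEmbed(H, dim)
    C <- kmeansAssign(R, n, seed + t)
    it <- intraClusterDistance(R, C)
    trace <- c(trace, it)
    assigns[[t]] <- C
    embeds[[t]] <- R
    if (t >= 2 && it > trace[t - 1]) {
      best <- t - 1L
      return(new("PreClusterResult", labels = assigns[[best]],
                 stop_t = best, intra_trace = trace,
                 embeddings = embeds[[best]]))
    }
  }
  best <- which.min(trace)
  new("PreClusterResult", labels = assigns[[best]], stop_t = as.integer(best),
      intra_trace = trace, embeddings = embeds[[best]])
}
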