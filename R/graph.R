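#' Pairwise Euclidean distances between spots
#'
#' @param pixel_xy spots x 2 matrix of pixel coordinates.
#' @return symmetric s x s distance matrix with zero diagonal.
#' @export
pairwiseDistances <- function(pixel_xy) {
  pixel_xy <- as.matrix(pixel_xy)
  if (nrow(pixel_xy) < 2) stop("need at least 2 spots")
  as.matrix(stats::dist(pixel_xy))
}

#' Gaussian-kernel adjacency
#'
#' A_ij = exp(-d_ij^2 / (2 sigma^2)); the diagonal is exactly 1 (self
#' loop, e^0).
#'
#' @param D distance matrix.
#' @param sigma positive bandwidth.
#' @export
gaussianAdjacency <- function(D, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  A <- exp(-D^2 / (2 * sigma^2))
  diag(A) <- 1
  A
}

.rowsumGap <- function(D, sigma) {
  mean(rowSums(gaussianAdjacency(D, sigma)) - 1)
}

#' Calibrate the Gaussian bandwidth sigma
#'
#' Finds sigma so the mean over spots of (row sum of A minus 1) equals
#' `target` (default 0.5). The mean excess row sum is monotone increasing
#' in sigma, so a bisection over [1e-6 d_max, 10 d_max] converges; the
#' contract is |mean - target| <= `tol`.
#'
#' @param D distance matrix.
#' @param target desired mean excess row sum (default 0.5).
#' @param tol tolerance on the mean (default 1e-3).
#' @return calibrated sigma (positive scalar).
#' @export
calibrateSigma <- function(D, target = 0.5, tol = 1e-3) {
  if (target <= 0) stop("target must be positive")
  if (nrow(D) < 2) stop("sigma calibration needs at least 2 spots")
  dmax <- max(D)
  if (dmax <= 0) stop("all spots coincide; sigma calibration unattainable")
  lo <- 1e-6 * dmax
  hi <- 10 * dmax
  if (.rowsumGap(D, hi) < target)
    stop("target row sum ", target, " unattainable: even a flat kernel ",
         "yields mean excess ", signif(.rowsumGap(D, hi), 4))
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    g <- .rowsumGap(D, mid)
    if (abs(g - target) <= tol / 10) break
    if (g < target) lo <- mid else hi <- mid
  }
  if (abs(.rowsumGap(D, mid) - target) > tol)
    stop("sigma search did not converge")
  mid
}

#' Symmetrically normalized Laplacian
#'
#' L = I - Deg^{-1/2} A Deg^{-1/2}, Deg = diag(row sums of A). Its
#' eigenvalues lie in [0, 2].
#'
#' @param A symmetric adjacency with positive row sums.
#' @export
normalizedLaplacian <- function(A) {
  rs <- rowSums(A)
  if (any(rs <= 0)) stop("zero row sum in adjacency")
  dm <- 1 / sqrt(rs)
  L <- -A * tcrossprod(dm)
  diag(L) <- diag(L) + 1
  L
}

#' Build the calibrated spot graph
#'
#' Distances from pixel coordinates, sigma calibration, Gaussian
#' adjacency and normalized Laplacian in one step.
#'
#' @param d a SpotDataset (or a spots x 2 coordinate matrix).
#' @param target mean excess row sum for the sigma search (default 0.5).
#' @return a \linkS4class{SpotGraph}.
#' @export
buildSpotGraph <- function(d, target = 0.5) {
  xy <- if (is(d, "SpotDataset")) pixelCoords(d) else as.matrix(d)
  D <- pairwiseDistances(xy)
  sigma <- calibrateSigma(D, target)
  A <- gaussianAdjacency(D, sigma)
  new("SpotGraph", D = D, A = A, L = normalizedLaplacian(A), sigma = sigma,
      target_rowsum = target)
}
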