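#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData rowData rowData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

.PLATFORMS <- c("visium", "stereo")

#' SpotDataset: spot-level expression with chip coordinates
#'
#' Extends \linkS4class{SummarizedExperiment}. Genes are rows and spots are
#' columns, the Bioconductor convention. `colData` carries one pixel
#' coordinate pair (floats, image pixels) and one lattice coordinate pair
#' (0-based integer array row/column) per spot, plus an `in_tissue` flag.
#' The platform tag (`"visium"` for staggered arrays, `"stereo"` for dense
#' grids) lives in `metadata(x)$platform`.
#'
#' @slot ... inherited from SummarizedExperiment.
#' @export
setClass("SpotDataset", contains = "SummarizedExperiment")

.validSpotDataset <- function(object) {
  msg <- NULL
  cd <- colData(object)
  need <- c("spot_id", "array_row", "array_col", "pixel_x", "pixel_y",
            "in_tissue")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData column(s): ",
                         paste(miss, collapse = ", ")))
  plat <- metadata(object)$platform
  if (is.null(plat) || !plat %in% .PLATFORMS)
    msg <- c(msg, "metadata(x)$platform must be 'visium' or 'stereo'")
  if (!length(miss)) {
    rc <- cbind(cd$array_row, cd$array_col)
    if (any(rc < 0) || any(rc != round(rc)))
      msg <- c(msg, "lattice coordinates must be nonnegative integers")
  }
  if ("counts" %in% assayNames(object)) {
    cnt <- assay(object, "counts")
    v <- if (inherits(cnt, "sparseMatrix")) cnt@x else as.vector(cnt)
    if (length(v) && (any(v < 0) || any(v != round(v))))
      msg <- c(msg, "counts must be nonnegative integers")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SpotDataset", .validSpotDataset)

#' Principal component model with reusable projection
#'
#' Stores the gene-wise mean vector and orthonormal loadings so arbitrary
#' expression vectors (including the all-zero "empty" expression used for
#' null/background pixels of the virtual image) can be projected later.
#'
#' @slot mean numeric vector, one entry per gene in scope.
#' @slot loadings genes-in-scope x k matrix with orthonormal columns.
#' @slot scores spots x k score matrix.
#' @slot k integer, number of components.
#' @slot genes character, the gene names in scope (order matches `mean`).
#' @export
setClass("PcaModel",
  representation(mean = "numeric", loadings = "matrix", scores = "matrix",
                 k = "integer", genes = "character"))

setValidity("PcaModel", function(object) {
  msg <- NULL
  if (ncol(object@loadings) != object@k) msg <- c(msg, "k != ncol(loadings)")
  if (ncol(object@scores) != object@k) msg <- c(msg, "k != ncol(scores)")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(object@k))) > 1e-6)
    msg <- c(msg, "loadings columns not orthonormal")
  if (is.null(msg)) TRUE else msg
})

#' Gaussian-kernel spot graph
#'
#' Pairwise pixel-coordinate distances D, the Gaussian adjacency
#' A_ij = exp(-d_ij^2 / (2 sigma^2)) (so A_ii = 1, a self loop), and the
#' symmetrically normalized Laplacian L = I - Deg^{-1/2} A Deg^{-1/2}.
#' sigma is calibrated so the mean over spots of (row sum of A minus 1)
#' equals `target_rowsum` (default 0.5).
#'
#' @export
setClass("SpotGraph",
  representation(D = "matrix", A = "matrix", L = "matrix", sigma = "numeric",
                 target_rowsum = "numeric"))

setValidity("SpotGraph", function(object) {
  msg <- NULL
  if (!isSymmetric(unname(object@D), tol = 1e-8)) msg <- c(msg, "D not symmetric")
  if (any(diag(object@D) != 0)) msg <- c(msg, "D diagonal not zero")
  if (any(diag(object@A) != 1)) msg <- c(msg, "A diagonal not 1")
  if (any(object@A < 0) || any(object@A > 1))
    msg <- c(msg, "A entries must lie in [0, 1]")  # exp() may underflow to 0
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Virtual image of the chip lattice
#'
#' A channels x h x w array. Spot pixels carry the spot's PC scores; null
#' pixels (the stagger gaps of a Visium array) and background pixels carry
#' the projection of the zero-expression vector. `spot_index` maps each
#' spot to its (0-based) lattice row/col.
#'
#' @export
setClass("VirtualImage",
  representation(X = "array", pixel_class = "matrix", spot_index = "matrix",
                 platform = "character"))

setValidity("VirtualImage", function(object) {
  msg <- NULL
  if (length(dim(object@X)) != 3) msg <- c(msg, "X must be channels x h x w")
  d <- dim(object@X)
  if (!all(dim(object@pixel_class) == d[2:3]))
    msg <- c(msg, "pixel_class shape mismatch")
  if (!all(object@pixel_class %in% c("spot", "null", "background")))
    msg <- c(msg, "pixel_class entries must be spot/null/background")
  if (nrow(object@spot_index) != sum(object@pixel_class == "spot"))
    msg <- c(msg, "#spot pixels != #spots")
  if (!object@platform %in% .PLATFORMS) msg <- c(msg, "bad platform")
  if (is.null(msg)) TRUE else msg
})

#' Adaptive graph convolution pre-clustering result
#'
#' @slot labels 0-based integer cluster assignment (the pseudo-labels C0).
#' @slot stop_t iteration whose assignment was adopted.
#' @slot intra_trace intra-cluster distance per smoothing iteration.
#' @slot embeddings spectral embedding at the adopted iteration.
#' @export
setClass("PreClusterResult",
  representation(labels = "integer", stop_t = "integer",
                 intra_trace = "numeric", embeddings = "matrix"))

#' @describeIn SpotDataset-class number of spots / quick summary.
#' @param object a SpotDataset.
#' @export
setMethod("show", "SpotDataset", function(object) {
  cat("SpotDataset (", metadata(object)$platform, "): ",
      nrow(object), " genes x ", ncol(object), " spots\n", sep = "")
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  hv <- metadata(object)$hvg_index
  if (!is.null(hv)) cat("highly variable genes:", length(hv), "\n")
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel: k =", object@k, "components over", length(object@genes),
      "genes;", nrow(object@scores), "spots scored\n")
})

setMethod("show", "SpotGraph", function(object) {
  cat("SpotGraph:", nrow(object@A), "spots; sigma =",
      signif(object@sigma, 5), "; target row-sum =", object@target_rowsum, "\n")
})

setMethod("show", "VirtualImage", function(object) {
  d <- dim(object@X)
  tab <- table(factor(object@pixel_class,
                      levels = c("spot", "null", "background")))
  cat("VirtualImage (", object@platform, "): ", d[1], " channels, ",
      d[2], "x", d[3], " pixels (", tab[["spot"]], " spot, ", tab[["null"]],
      " null, ", tab[["background"]], " background)\n", sep = "")
})

setMethod("show", "PreClusterResult", function(object) {
  cat("PreClusterResult:", length(object@labels), "spots,",
      length(unique(object@labels)), "clusters; adopted iteration t =",
      object@stop_t, "\n")
})
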