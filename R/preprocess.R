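#' Construct a SpotDataset from in-memory pieces
#'
#' @param counts genes x spots matrix of nonnegative integer UMI counts
#'   (dense or sparse).
#' @param spot_ids character vector of spot identifiers.
#' @param lattice_rc spots x 2 integer matrix of array (row, col),
#'   0- or 1-based; anchored internally to 0-based by subtracting the
#'   column-wise minimum (a shift of both coordinates preserves the
#'   stagger parity of a Visium array).
#' @param pixel_xy spots x 2 numeric matrix of image-pixel coordinates.
#' @param platform `"visium"` or `"stereo"`.
#' @param in_tissue logical flags; spots flagged FALSE are dropped.
#' @param true_labels optional integer vector of ground-truth domains
#'   (kept in colData for benchmarking against planted structure).
#' @return a \linkS4class{SpotDataset}.
#' @export
SpotDataset <- function(counts, spot_ids, lattice_rc, pixel_xy,
                        platform = c("visium", "stereo"),
                        in_tissue = rep(TRUE, length(spot_ids)),
                        true_labels = NULL) {
  platform <- match.arg(platform)
  if (is.null(dim(counts)) || ncol(counts) != length(spot_ids))
    stop("counts must be a genes x spots matrix matching spot_ids")
  lattice_rc <- as.matrix(lattice_rc)
  pixel_xy <- as.matrix(pixel_xy)
  if (nrow(lattice_rc) != length(spot_ids) || ncol(lattice_rc) != 2)
    stop("format error: one lattice (row, col) pair per spot is required")
  if (nrow(pixel_xy) != length(spot_ids) || ncol(pixel_xy) != 2)
    stop("format error: one pixel (x, y) pair per spot is required")
  if (any(lattice_rc != round(lattice_rc)))
    stop("validation error: lattice coordinates must be integers")
  lattice_rc <- sweep(lattice_rc, 2, apply(lattice_rc, 2, min))
  cd <- DataFrame(spot_id = as.character(spot_ids),
                  array_row = as.integer(lattice_rc[, 1]),
                  array_col = as.integer(lattice_rc[, 2]),
                  pixel_x = as.numeric(pixel_xy[, 1]),
                  pixel_y = as.numeric(pixel_xy[, 2]),
                  in_tissue = as.logical(in_tissue))
  if (!is.null(true_labels)) cd$true_domain <- as.integer(true_labels)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  colnames(counts) <- cd$spot_id
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = list(platform = platform))
  obj <- new("SpotDataset", se)
  validObject(obj)
  obj[, colData(obj)$in_tissue]
}

#' Load a spot dataset from disk
#'
#' Reads a directory holding a Matrix Market count matrix plus a
#' coordinate table:
#' \itemize{
#'   \item `matrix.mtx` — genes x spots sparse counts;
#'   \item `genes.tsv` — one gene name per line;
#'   \item `coords.csv` — columns `spot_id,row,col,px,py,in_tissue`.
#' }
#' A dense `counts.csv` (genes x spots, first column gene names) may stand
#' in for the MTX pair. 1-based array rows/cols are normalized to 0-based.
#' For stereo data whose coordinate table lacks `row`/`col`, the lattice is
#' derived by snapping pixel coordinates to their minimal positive gap.
#'
#' @param path directory containing the files above.
#' @param platform `"visium"` or `"stereo"`.
#' @return a \linkS4class{SpotDataset} restricted to in-tissue spots.
#' @export
loadSpotDataset <- function(path, platform = c("visium", "stereo")) {
  platform <- match.arg(platform)
  if (!dir.exists(path)) stop("format error: '", path, "' is not a directory")
  coord_file <- file.path(path, "coords.csv")
  if (!file.exists(coord_file))
    stop("format error: missing coordinate table coords.csv")
  co <- utils::read.csv(coord_file, stringsAsFactors = FALSE)
  if (!all(c("px", "py") %in% colnames(co)))
    stop("format error: coords.csv lacks pixel coordinate columns px/py")
  if (!all(c("row", "col") %in% colnames(co))) {
    if (platform == "stereo") {
      grid <- discretizePixelGrid(cbind(co$px, co$py))
      co$row <- grid[, 1]; co$col <- grid[, 2]
    } else {
      stop("format error: coords.csv lacks lattice coordinate columns ",
           "row/col (required for platform 'visium')")
    }
  }
  if (!"spot_id" %in% colnames(co)) co$spot_id <- paste0("spot", seq_len(nrow(co)))
  if (!"in_tissue" %in% colnames(co)) co$in_tissue <- TRUE

  mtx <- file.path(path, "matrix.mtx")
  if (file.exists(mtx)) {
    counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
    gf <- file.path(path, "genes.tsv")
    if (file.exists(gf))
      rownames(counts) <- readLines(gf)
  } else {
    cf <- file.path(path, "counts.csv")
    if (!file.exists(cf))
      stop("format error: neither matrix.mtx nor counts.csv found")
    tab <- utils::read.csv(cf, row.names = 1, check.names = FALSE)
    counts <- as.matrix(tab)
  }
  if (ncol(counts) != nrow(co))
    stop("format error: count matrix has ", ncol(counts),
         " spots but coords.csv has ", nrow(co))
  if (any(counts != round(counts)) || any(counts < 0))
    stop("validation error: counts must be nonnegative integers")
  SpotDataset(counts, co$spot_id, cbind(co$row, co$col), cbind(co$px, co$py),
              platform = platform, in_tissue = co$in_tissue,
              true_labels = if ("true_domain" %in% colnames(co)) co$true_domain)
}

#' Write a SpotDataset back to disk (MTX + coordinate CSV)
#'
#' @param d a SpotDataset.
#' @param path output directory (created if absent). Writes `matrix.mtx`,
#'   `genes.tsv`, `coords.csv` and, when present, the normalized values as
#'   `logcounts.csv`.
#' @return `path`, invisibly.
#' @export
writeSpotDataset <- function(d, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::Matrix(assay(d, "counts"), sparse = TRUE),
                     "generalMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(d), file.path(path, "genes.tsv"))
  cd <- colData(d)
  co <- data.frame(spot_id = cd$spot_id, row = cd$array_row,
                   col = cd$array_col, px = cd$pixel_x, py = cd$pixel_y,
                   in_tissue = cd$in_tissue)
  if (!is.null(cd$true_domain)) co$true_domain <- cd$true_domain
  utils::write.csv(co, file.path(path, "coords.csv"), row.names = FALSE)
  if ("logcounts" %in% assayNames(d))
    utils::write.csv(as.matrix(assay(d, "logcounts")),
                     file.path(path, "logcounts.csv"))
  invisible(path)
}

#' Snap near-regular pixel coordinates to an integer grid
#'
#' Divides each axis by its minimal positive coordinate gap and rounds.
#' Used for dense (stereo-style) lattices delivered as pixel coordinates.
#'
#' @param xy spots x 2 numeric matrix.
#' @return spots x 2 integer matrix of 0-based (row, col); collisions error.
#' @export
discretizePixelGrid <- function(xy) {
  snap <- function(v) {
    u <- sort(unique(v))
    gaps <- diff(u)
    gaps <- gaps[gaps > 1e-9]
    step <- if (length(gaps)) min(gaps) else 1
    as.integer(round((v - min(v)) / step))
  }
  rc <- cbind(snap(xy[, 2]), snap(xy[, 1]))  # row from y, col from x
  if (anyDuplicated(rc))
    stop("two spots map to one lattice position after discretization")
  rc
}

#' Filter genes (and, for stereo, spots)
#'
#' Genes detected in fewer than `min_spots` spots are removed; afterwards,
#' for the stereo platform only, spots in which fewer than `min_genes`
#' genes are detected are removed. The gene filter runs first.
#'
#' @param d a SpotDataset with a `counts` assay.
#' @param min_spots gene-level cutoff (default 3: a gene must be seen in
#'   at least 3 spots).
#' @param min_genes spot-level cutoff for stereo data (default 20).
#' @return the filtered SpotDataset.
#' @export
filterSpots <- function(d, min_spots = 3, min_genes = 20) {
  cnt <- assay(d, "counts")
  detected_in <- Matrix::rowSums(cnt > 0)
  d <- d[detected_in >= min_spots, ]
  if (platformOf(d) == "stereo") {
    genes_per_spot <- Matrix::colSums(assay(d, "counts") > 0)
    d <- d[, genes_per_spot >= min_genes]
  }
  if (nrow(d) == 0 || ncol(d) == 0)
    stop("filtering removed all genes or all spots")
  d
}

#' Library-size normalization with log transform
#'
#' Each count is divided by the spot's total UMI count, scaled by 10,000
#' and log-transformed as ln(1 + x) (the +1 keeps zero counts finite and
#' maps them to 0). Adds a dense `logcounts` assay.
#'
#' @param d a filtered SpotDataset.
#' @param scale scale factor (default 1e4).
#' @return `d` with a `logcounts` assay.
#' @export
normalizeSpots <- function(d, scale = 1e4) {
  cnt <- assay(d, "counts")
  tot <- Matrix::colSums(cnt)
  if (any(tot == 0)) stop("spot(s) with zero total count: ",
                          paste(which(tot == 0)[1:min(3, sum(tot == 0))],
                                collapse = ", "))
  lc <- log1p(sweep(as.matrix(cnt), 2, tot, "/") * scale)
  assay(d, "logcounts") <- lc
  d
}

#' Select highly variable genes by normalized dispersion
#'
#' Ranks genes by the dispersion (variance / mean) of their normalized
#' values, z-scored within 20 equal-frequency mean-expression bins, and
#' keeps the top `n`. Stores the selected row indices in
#' `metadata(d)$hvg_index` and a logical `rowData(d)$hvg` flag.
#' Deterministic: ties break by gene order.
#'
#' @param d a SpotDataset with `logcounts`.
#' @param n number of genes to keep (default 3000, clipped to the gene
#'   count).
#' @return `d` annotated with the HVG selection.
#' @export
selectHVG <- function(d, n = 3000) {
  lc <- assay(d, "logcounts")
  mu <- rowMeans(lc)
  v <- apply(lc, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- min(20L, floor(nrow(lc) / 5))
  bins <- if (nb >= 2)
    cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  else rep(1L, nrow(lc))
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  n <- min(n, nrow(lc))
  idx <- order(-z, seq_along(z))[seq_len(n)]
  idx <- sort(idx)
  metadata(d)$hvg_index <- idx
  rowData(d)$hvg <- seq_len(nrow(d)) %in% idx
  d
}

.fixSigns <- function(loadings, scores = NULL) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      if (!is.null(scores)) scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Fit a PCA model on normalized expression
#'
#' PCA over spots (observations) of the `logcounts` assay, restricted to
#' the highly variable genes (`gene_scope = "hvg"`, requires
#' \code{\link{selectHVG}}) or all genes. Deterministic: the
#' largest-magnitude loading of every component is forced positive.
#'
#' @param d a SpotDataset with `logcounts`.
#' @param k number of components.
#' @param gene_scope `"hvg"` or `"all"`.
#' @return a \linkS4class{PcaModel}.
#' @export
fitPCA <- function(d, k, gene_scope = c("hvg", "all")) {
  gene_scope <- match.arg(gene_scope)
  lc <- assay(d, "logcounts")
  if (gene_scope == "hvg") {
    idx <- metadata(d)$hvg_index
    if (is.null(idx)) stop("run selectHVG() before gene_scope = 'hvg'")
    lc <- lc[idx, , drop = FALSE]
  }
  xm <- t(as.matrix(lc))                      # spots x genes
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  sv <- svd(xc, nu = 0, nv = min(dim(xc)))
  rk <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (k > rk) stop("k = ", k, " exceeds the rank (", rk, ") of the input")
  load <- sv$v[, seq_len(k), drop = FALSE]
  sc <- xc %*% load
  fx <- .fixSigns(load, sc)
  rownames(fx$loadings) <- colnames(xm)
  new("PcaModel", mean = mu, loadings = fx$loadings, scores = fx$scores,
      k = as.integer(k), genes = colnames(xm))
}

#' Project expression vectors through a fitted PCA model
#'
#' @param p a PcaModel.
#' @param x a numeric vector (length = genes in scope) or a spots x genes
#'   matrix on the same normalized scale the model was fitted on.
#' @return score vector/matrix (x - mean) \%*\% loadings.
#' @export
projectPCA <- function(p, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(p@mean))
    stop("expected ", length(p@mean), " genes, got ", ncol(x))
  sc <- sweep(x, 2, p@mean) %*% p@loadings
  if (nrow(sc) == 1) drop(sc) else sc
}
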