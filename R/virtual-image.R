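#' Channel values for null and background pixels
#'
#' Projects the all-zero expression vector through the fitted PCA model:
#' (0 - mean) %*% loadings. Lattice positions with no spot carry no
#' transcripts, so their "expression" is the zero vector on the normalized
#' scale; this is its PC representation.
#'
#' @param p a \linkS4class{PcaModel} (the pipeline uses k = 15 fitted on
#'   the 3000 HVGs).
#' @return numeric vector of length `p@k`.
#' @export
emptyPixelValue <- function(p) {
  drop(crossprod(p@loadings, -p@mean))
}

#' Build the virtual image of the chip lattice
#'
#' Arranges each spot's PC score vector at its lattice (row, col); the
#' canvas spans the lattice bounding box, height = max row + 1 and width =
#' max col + 1. Remaining pixels are filled with the zero-expression
#' projection and classed:
#' \itemize{
#'   \item visium: positions whose (row+col) parity differs from the
#'     spots' parity are `null` (the stagger gaps); same-parity positions
#'     with no spot are `background`;
#'   \item stereo: the lattice is dense, so every non-spot position is
#'     `background` and there are no null pixels.
#' }
#'
#' @param d a SpotDataset carrying lattice coordinates.
#' @param p a fitted PcaModel whose scores rows match the spots of `d`
#'   (the pipeline default is k = 15 on the top 3000 HVGs).
#' @return a \linkS4class{VirtualImage} with X of shape k x h x w.
#' @export
buildVirtualImage <- function(d, p) {
  rc <- latticeCoords(d)
  sc <- pcaScores(p)
  if (nrow(sc) != nrow(rc))
    stop("PCA scores rows (", nrow(sc), ") != spots (", nrow(rc), ")")
  platform <- platformOf(d)
  h <- max(rc[, 1]) + 1L
  w <- max(rc[, 2]) + 1L
  lin <- rc[, 1] + 1L + h * rc[, 2]          # column-major pixel index
  if (anyDuplicated(lin))
    stop("two spots map to one pixel at lattice ",
         paste(rc[which(duplicated(lin))[1], ], collapse = ","))
  k <- ncol(sc)
  empty <- emptyPixelValue(p)
  Xmat <- matrix(empty, nrow = k, ncol = h * w)
  Xmat[, lin] <- t(sc)

  cls <- matrix("background", h, w)
  if (platform == "visium") {
    par0 <- (rc[, 1] + rc[, 2]) %% 2
    par0 <- as.integer(round(mean(par0)))    # the parity the data carries
    grid_par <- outer(0:(h - 1), 0:(w - 1), "+") %% 2
    cls[grid_par != par0] <- "null"
  }
  cls[lin] <- "spot"
  new("VirtualImage", X = array(Xmat, dim = c(k, h, w)), pixel_class = cls,
      spot_index = rc, platform = platform)
}

#' Read per-spot channel vectors back out of an image-shaped array
#'
#' @param img a VirtualImage (supplies the spot -> pixel map).
#' @param arr optional channels x h x w array to read instead of the
#'   image's own X (e.g. the network's feature image O).
#' @return spots x channels matrix, rows in spot order.
#' @export
spotPixelValues <- function(img, arr = NULL) {
  if (is.null(arr)) arr <- img@X
  d <- dim(arr)
  h <- d[2]
  rc <- img@spot_index
  lin <- rc[, 1] + 1L + h * rc[, 2]
  t(matrix(arr, nrow = d[1])[, lin, drop = FALSE])
}

# linear (column-major over h x w) pixel indices of the spot pixels
.spotLinearIndex <- function(img) {
  h <- dim(img@X)[2]
  img@spot_index[, 1] + 1L + h * img@spot_index[, 2]
}
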