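#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table: (sum_ij C(n_ij,2) - E) / (max - E) with
#' E = sum_i C(n_i.,2) sum_j C(n_.j,2) / C(n,2) and
#' max = [sum_i C(n_i.,2) + sum_j C(n_.j,2)] / 2. Equals 1 iff the
#' partitions are identical up to relabeling.
#'
#' @param U,V label vectors of equal length (any coding).
#' @export
ariScore <- function(U, V) {
  if (length(U) != length(V)) stop("label vectors differ in length")
  if (length(U) < 2) stop("need at least 2 observations")
  tab <- table(U, V)
  n <- length(U)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxidx - expected)
}

#' Silhouette coefficient and Davies-Bouldin score
#'
#' Standard definitions on Euclidean distances: the silhouette of a point
#' is (b - a)/max(a, b) with a the mean within-cluster distance and b the
#' smallest mean distance to another cluster (singletons score 0); DB is
#' the mean over clusters of the largest (S_i + S_j) / M_ij with S the
#' mean member-to-centroid distance and M the centroid distance.
#'
#' @param E observations x features matrix (embeddings).
#' @param C cluster labels.
#' @return c(silhouette =, davies_bouldin =).
#' @export
silhouetteDB <- function(E, C) {
  E <- as.matrix(E)
  labs <- unique(C)
  if (length(labs) < 2) stop("need at least 2 clusters")
  Dm <- as.matrix(stats::dist(E))
  sil <- vapply(seq_len(nrow(E)), function(i) {
    own <- C == C[i]
    if (sum(own) == 1) return(0)
    a <- mean(Dm[i, own & seq_len(nrow(E)) != i])
    b <- min(vapply(labs[labs != C[i]],
                    function(l) mean(Dm[i, C == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  cent <- t(vapply(labs, function(l) colMeans(E[C == l, , drop = FALSE]),
                   numeric(ncol(E))))
  S <- vapply(seq_along(labs), function(k) {
    i <- C == labs[k]
    mean(sqrt(rowSums((E[i, , drop = FALSE] -
                         matrix(cent[k, ], sum(i), ncol(E),
                                byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  db <- mean(vapply(seq_along(labs), function(k) {
    r <- (S[k] + S[-k]) / M[k, -k]
    max(r)
  }, numeric(1)))
  c(silhouette = mean(sil), davies_bouldin = db)
}

# domains sharing at least one lattice-adjacent spot pair with `domain`
.neighborDomains <- function(spot_index, platform, C, domain) {
  pairs <- .neighborPairs(spot_index, platform)
  pp <- rbind(pairs$ortho, pairs$diag)
  if (!nrow(pp)) return(integer(0))
  la <- C[pp[, 1]]; lb <- C[pp[, 2]]
  touch <- unique(c(lb[la == domain], la[lb == domain]))
  sort(setdiff(touch, domain))
}

#' Detect spatially variable genes of a spatial domain
#'
#' Per gene, a Wilcoxon rank-sum test of in-domain vs out-domain
#' normalized values with Benjamini-Hochberg adjustment; fold change of
#' back-transformed (expm1) means; in-fraction = share of in-domain spots
#' expressing the gene; and the minimum over neighbouring domains of the
#' in/out fraction ratio. A gene passes with adjusted p < 0.05, fold
#' change > 1.5, in-fraction > 0.8 and every neighbour ratio > 1.
#'
#' @param d a SpotDataset with a `logcounts` assay.
#' @param C 0-based domain labels, one per spot.
#' @param domain the target domain label.
#' @param neighbors integer set of neighbouring domains for the ratio
#'   filter; NULL derives them from lattice adjacency of the labelling.
#' @param p_cut,fc_cut,infrac_cut,ratio_cut the four cutoffs.
#' @return data.frame: domain, gene, adj_p, fold_change, in_fraction,
#'   min_in_out_ratio, passed.
#' @export
detectSVG <- function(d, C, domain, neighbors = NULL,
                      p_cut = 0.05, fc_cut = 1.5, infrac_cut = 0.8,
                      ratio_cut = 1) {
  lc <- as.matrix(assay(d, "logcounts"))
  inside <- which(C == domain)
  if (!length(inside)) stop("domain ", domain, " has no spots")
  outside <- which(C != domain)
  if (is.null(neighbors))
    neighbors <- .neighborDomains(latticeCoords(d), platformOf(d), C, domain)
  pv <- apply(lc, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[inside], x[outside],
                                        alternative = "greater")$p.value))
  adj_p <- stats::p.adjust(pv, method = "BH")
  mean_in <- rowMeans(expm1(lc[, inside, drop = FALSE]))
  mean_out <- rowMeans(expm1(lc[, outside, drop = FALSE]))
  fc <- (mean_in + .EPS) / (mean_out + .EPS)
  in_frac <- rowMeans(lc[, inside, drop = FALSE] > 0)
  if (length(neighbors)) {
    nf <- vapply(neighbors, function(nb)
      rowMeans(lc[, C == nb, drop = FALSE] > 0), numeric(nrow(lc)))
    nf <- matrix(nf, nrow = nrow(lc))
    ratio <- apply(in_frac / pmax(nf, .EPS), 1, min)
  } else {
    ratio <- rep(Inf, nrow(lc))
  }
  data.frame(domain = domain, gene = rownames(lc), adj_p = adj_p,
             fold_change = fc, in_fraction = in_frac,
             min_in_out_ratio = ratio,
             passed = adj_p < p_cut & fc > fc_cut & in_frac > infrac_cut &
               ratio > ratio_cut,
             row.names = NULL)
}
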