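# Synthetic lattice generator: planted spatial domains with marker genes
# and overdispersed UMI counts, for both chip geometries. The generator is
# first-class, seeded and bit-reproducible; every pipeline stage is
# testable against its planted labels without external downloads.

#' Specification of a synthetic lattice fixture
#'
#' @param platform `"visium"` (staggered array; spots occupy positions
#'   whose row+col parity matches) or `"stereo"` (dense grid).
#' @param rows,cols lattice extent. Defaults give ~300 visium spots.
#' @param n_domains number of planted spatial domains.
#' @param layout `"stripes"` (row bands), `"arcs"` (annuli around the
#'   origin corner, emulating cortical layer geometry) or `"blobs"`
#'   (Voronoi cells of random seed points).
#' @param n_genes total genes.
#' @param markers_per_domain genes up-regulated in each domain.
#' @param base_rate baseline negative-binomial mean per gene (default
#'   0.5).
#' @param marker_lift fold lift of a domain's markers inside the domain
#'   (default 8; 1 means no spatial signal).
#' @param dropout probability of zeroing any count (default 0.2).
#' @param dispersion negative-binomial dispersion (default 0.5, i.e.
#'   size = 2), mimicking UMI overdispersion.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @export
fixtureSpec <- function(platform = c("visium", "stereo"), rows = 24L,
                        cols = 25L, n_domains = 3L,
                        layout = c("stripes", "arcs", "blobs"),
                        n_genes = 200L, markers_per_domain = 10L,
                        base_rate = 0.5, marker_lift = 8, dropout = 0.2,
                        dispersion = 0.5, seed = 0L) {
  platform <- match.arg(platform)
  layout <- match.arg(layout)
  stopifnot(n_domains >= 1, dropout >= 0, dropout < 1,
            n_domains * markers_per_domain <= n_genes)
  list(platform = platform, rows = as.integer(rows), cols = as.integer(cols),
       n_domains = as.integer(n_domains), layout = layout,
       n_genes = as.integer(n_genes),
       markers_per_domain = as.integer(markers_per_domain),
       base_rate = base_rate, marker_lift = marker_lift, dropout = dropout,
       dispersion = dispersion, seed = as.integer(seed))
}

#' Build the lattice coordinates of a fixture
#'
#' Visium spots occupy positions with even (row + col); pixel coordinates
#' are an affine map of the lattice with a sqrt(3) row spacing so the six
#' closest neighbours (four diagonal, two transverse) are equidistant, as
#' on a real staggered array. Stereo spots fill the grid with an isotropic
#' 10-unit pitch.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list(lattice_rc, pixel_xy, spot_ids).
#' @export
makeLattice <- function(spec) {
  grid <- expand.grid(row = 0:(spec$rows - 1L), col = 0:(spec$cols - 1L))
  if (spec$platform == "visium")
    grid <- grid[(grid$row + grid$col) %% 2 == 0, ]
  grid <- grid[order(grid$row, grid$col), ]
  if (spec$platform == "visium") {
    px <- grid$col * 50
    py <- grid$row * 50 * sqrt(3)
  } else {
    px <- grid$col * 10
    py <- grid$row * 10
  }
  list(lattice_rc = cbind(row = grid$row, col = grid$col),
       pixel_xy = cbind(x = px, y = py),
       spot_ids = sprintf("spot_%d_%d", grid$row, grid$col))
}

.domainLabels <- function(spec, rc) {
  n <- spec$n_domains
  if (spec$layout == "stripes") {
    pmin(floor(rc[, 1] * n / spec$rows), n - 1L)
  } else if (spec$layout == "arcs") {
    r <- sqrt((rc[, 1] / spec$rows)^2 + (rc[, 2] / spec$cols)^2)
    pmin(floor(r / (sqrt(2) / n)), n - 1L)
  } else {
    seeds <- cbind(stats::runif(n, 0, spec$rows - 1),
                   stats::runif(n, 0, spec$cols - 1))
    d2 <- outer(rc[, 1], seeds[, 1], "-")^2 + outer(rc[, 2], seeds[, 2], "-")^2
    max.col(-d2, ties.method = "first") - 1L
  }
}

#' Simulate a fixture dataset with planted domains
#'
#' Counts are Gamma-Poisson (negative binomial, size = 1/dispersion): a
#' domain's marker genes have mean base_rate * marker_lift inside the
#' domain and base_rate elsewhere; all other genes have mean base_rate
#' everywhere. Bernoulli dropout zeroes entries. True domain labels are
#' stored in `colData(x)$true_domain`.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return a \linkS4class{SpotDataset} with counts and planted labels.
#' @export
simulateFixture <- function(spec) {
  lat <- makeLattice(spec)
  withr::with_seed(spec$seed, {
    labels <- .domainLabels(spec, lat$lattice_rc)
    s <- nrow(lat$lattice_rc)
    g <- spec$n_genes
    marker_of <- rep(NA_integer_, g)  # which domain a gene marks
    marker_of[seq_len(spec$n_domains * spec$markers_per_domain)] <-
      rep(seq_len(spec$n_domains) - 1L, each = spec$markers_per_domain)
    mu <- matrix(spec$base_rate, g, s)
    for (dd in seq_len(spec$n_domains) - 1L) {
      gi <- which(marker_of == dd)
      si <- which(labels == dd)
      mu[gi, si] <- spec$base_rate * spec$marker_lift
    }
    counts <- matrix(stats::rnbinom(g * s, mu = mu,
                                    size = 1 / spec$dispersion), g, s)
    if (spec$dropout > 0)
      counts[matrix(stats::runif(g * s) < spec$dropout, g, s)] <- 0L
    # a spot with zero total breaks normalization; give it one housekeeping
    # count (rare at the default rates, possible at tiny n_genes)
    empty <- which(colSums(counts) == 0)
    if (length(empty)) counts[g, empty] <- 1L
    rownames(counts) <- c(
      sprintf("marker_d%d_%d", marker_of[!is.na(marker_of)],
              seq_len(sum(!is.na(marker_of)))),
      sprintf("noise_%d", seq_len(sum(is.na(marker_of)))))
    SpotDataset(counts, lat$spot_ids, lat$lattice_rc, lat$pixel_xy,
                platform = spec$platform, true_labels = labels)
  })
}

#' Planted ground-truth labels of a fixture
#' @param d a SpotDataset produced by \code{\link{simulateFixture}}.
#' @export
trueDomains <- function(d) {
  td <- colData(d)$true_domain
  if (is.null(td)) stop("no planted labels in this dataset")
  as.integer(td)
}
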