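# Small in-code fixtures shared across test files.

# tiny visium dataset: staggered spots on a rows x cols canvas with
# hand-controllable counts (genes x spots); counts default to a seeded
# Poisson draw
toyVisium <- function(rows = 4, cols = 8, genes = 30, counts = NULL,
                      seed = 42) {
  grid <- expand.grid(row = 0:(rows - 1), col = 0:(cols - 1))
  grid <- grid[(grid$row + grid$col) %% 2 == 0, ]
  grid <- grid[order(grid$row, grid$col), ]
  s <- nrow(grid)
  if (is.null(counts))
    counts <- withr::with_seed(seed,
      matrix(rpois(genes * s, 5), genes, s))
  SpotDataset(counts, sprintf("s%d", seq_len(s)),
              cbind(grid$row, grid$col),
              cbind(grid$col * 50, grid$row * 50 * sqrt(3)),
              platform = "visium")
}

toyStereo <- function(rows = 3, cols = 3, genes = 30, counts = NULL,
                      seed = 42) {
  grid <- expand.grid(row = 0:(rows - 1), col = 0:(cols - 1))
  grid <- grid[order(grid$row, grid$col), ]
  s <- nrow(grid)
  if (is.null(counts))
    counts <- withr::with_seed(seed,
      matrix(rpois(genes * s, 5), genes, s))
  SpotDataset(counts, sprintf("s%d", seq_len(s)),
              cbind(grid$row, grid$col),
              cbind(grid$col * 10, grid$row * 10),
              platform = "stereo")
}

# a normalized toy ready for PCA, deterministic
toyNormalized <- function(...) {
  d <- toyVisium(...)
  selectHVG(normalizeSpots(d), 3000)
}

# a small virtual image with random channel values (for network tests)
toyImage <- function(rows = 6, cols = 12, channels = 5, seed = 7) {
  d <- toyVisium(rows, cols, genes = 40, seed = seed)
  d <- selectHVG(normalizeSpots(d), 3000)
  p <- fitPCA(d, channels, "hvg")
  buildVirtualImage(d, p)
}

expect_all_equal <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)), tol)
}
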