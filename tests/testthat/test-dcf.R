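tap_set <- function(spec) {
  paste(spec$taps$dy, spec$taps$dx, sep = ",")
}

test_that("kernel specs cover exactly the closest lattice neighbours", {
  vs <- makeKernelSpecs("visium")
  union_v <- sort(unique(c(tap_set(vs[[1]]), tap_set(vs[[2]]))))
  want_v <- sort(c("0,0", "0,-2", "0,2", "-2,0", "2,0",
                   "-1,-1", "-1,1", "1,-1", "1,1"))
  expect_equal(union_v, want_v)          # self + 8 closest spot pixels
  expect_equal(vs[[1]]$n_groups, 2)      # {center}, {edge midpoints}
  expect_equal(vs[[2]]$n_groups, 1)      # all 4 diagonal taps tied

  ss <- makeKernelSpecs("stereo")
  union_s <- unique(c(tap_set(ss[[1]]), tap_set(ss[[2]])))
  expect_equal(length(union_s), 13)      # self + 12 closest neighbours
  expect_equal(ss[[1]]$n_groups, 3)      # {center}, {edges}, {corners}
  # dilated stereo kernel masks its center and corners
  expect_true("0,0" %in% paste(ss[[2]]$zero_offsets[, 1],
                               ss[[2]]$zero_offsets[, 2], sep = ","))

  # zero positions never appear among active taps
  for (sp in c(vs, ss)) {
    if (!nrow(sp$zero_offsets)) next
    z <- paste(sp$zero_offsets[, 1], sp$zero_offsets[, 2], sep = ",")
    expect_length(intersect(z, tap_set(sp)), 0)
  }

  # ablations: untied taps, unmasked corners
  nt <- makeKernelSpecs("visium", tie_weights = FALSE)
  expect_equal(nt[[1]]$n_groups, nrow(nt[[1]]$taps))
  cc <- makeKernelSpecs("visium", tie_weights = FALSE, zero_corners = FALSE)
  expect_equal(nrow(cc[[1]]$taps), 9)
  expect_equal(nrow(cc[[1]]$zero_offsets), 0)
})

test_that("constraint enforcement zeroes corners, ties groups, idempotent", {
  spec <- makeKernelSpecs("visium")[[1]]
  set.seed(8)
  K <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  K1 <- enforceConstraints(K, spec)
  expect_true(all(K1[, , c(1, 3), c(1, 3)] == 0))        # corners exactly 0
  for (a in c(1, 3)) {                                   # edge midpoints tied
    expect_identical(K1[, , a, 2], K1[, , 2, 1])
    expect_identical(K1[, , 2, a], K1[, , 2, 1])
  }
  expect_identical(enforceConstraints(K1, spec), K1)     # idempotent

  # the tied parameterization materializes with the same invariants
  W <- array(rnorm(2 * 3 * spec$n_groups), c(2, 3, spec$n_groups))
  KT <- kernelTensor(W, spec)
  expect_true(all(KT[, , c(1, 3), c(1, 3)] == 0))
  expect_identical(KT[, , 1, 2], KT[, , 3, 2])
})

test_that("forward pass honours shapes and the zero-weight degenerate case", {
  img <- toyImage(6, 12, channels = 4)
  params <- dcfInit(4, 3, "visium", hidden = 8, seed = 1)
  fw <- dcfForward(params, img, training = TRUE)
  expect_equal(fw$dims, c(3, 6, 12))
  expect_equal(dim(fw$E), c(nrow(img@spot_index), 3))
  # E rows equal O read at the spot pixels
  Oarr <- array(fw$O, fw$dims)
  expect_all_equal(fw$E, spotPixelValues(img, Oarr), 1e-12)

  # all conv weights zero, biases b: O is constant w1*b1 + w2*b2
  pz <- params
  for (f in 1:2) for (j in 1:4) {
    pz$sub[[f]]$conv[[j]]$W[] <- 0
    pz$sub[[f]]$conv[[j]]$b[] <- 0
  }
  pz$sub[[1]]$conv[[4]]$b <- c(1, 2, 3)
  pz$sub[[2]]$conv[[4]]$b <- c(10, 20, 30)
  fz <- dcfForward(pz, img, training = TRUE)
  want <- 0.7 * c(1, 2, 3) + 0.3 * c(10, 20, 30)
  expect_all_equal(fz$O, matrix(want, 3, ncol(fz$O)), 1e-9)
})

test_that("single constrained conv ignores null pixels on a visium lattice", {
  img <- toyImage(6, 12, channels = 3)
  specs <- makeKernelSpecs("visium")
  set.seed(9)
  for (f in 1:2) {
    spec <- specs[[f]]
    layer <- list(W = array(rnorm(2 * 3 * spec$n_groups),
                            c(2, 3, spec$n_groups)),
                  b = rnorm(2))
    base <- constrainedConv(imageArray(img), layer, spec)$out
    pc <- pixelClass(img)
    nulls <- which(pc == "null", arr.ind = TRUE)
    Xp <- imageArray(img)
    for (k in seq_len(min(5, nrow(nulls)))) {
      Xp[, nulls[k, 1], nulls[k, 2]] <-
        Xp[, nulls[k, 1], nulls[k, 2]] + 100
    }
    pert <- constrainedConv(Xp, layer, spec)$out
    spot_lin <- which(pc == "spot")
    for (ch in 1:2) {
      b_ch <- base[ch, , ]; p_ch <- pert[ch, , ]
      expect_all_equal(b_ch[spot_lin], p_ch[spot_lin], 1e-10)
    }
  }
})

test_that("a spot pixel's single-layer receptive field is <= 9 spot pixels", {
  img <- toyImage(8, 16, channels = 3)
  specs <- makeKernelSpecs("visium")
  pc <- pixelClass(img)
  # an interior spot pixel
  rc <- img@spot_index
  pick <- which(rc[, 1] == 4 & rc[, 2] %% 2 == 0 & rc[, 2] >= 4 &
                  rc[, 2] <= 10)[1]
  at <- c(1, rc[pick, 1] + 1, rc[pick, 2] + 1)
  set.seed(10)
  total <- 0
  for (f in 1:2) {
    spec <- specs[[f]]
    layer <- list(W = array(rnorm(1 * 3 * spec$n_groups),
                            c(1, 3, spec$n_groups)),
                  b = rnorm(1))
    g <- constrainedConv(imageArray(img), layer, spec, grad_at = at)$dX
    total <- total + apply(abs(g), c(2, 3), sum)
  }
  nz <- which(total > 0, arr.ind = TRUE)
  expect_lte(nrow(nz), 9)
  for (k in seq_len(nrow(nz)))
    expect_equal(pc[nz[k, 1], nz[k, 2]], "spot")
})

test_that("a single constrained conv layer is translation equivariant", {
  spec <- makeKernelSpecs("visium")[[2]]
  set.seed(12)
  X <- array(rnorm(2 * 10 * 10), c(2, 10, 10))
  layer <- list(W = array(rnorm(1 * 2 * spec$n_groups),
                          c(1, 2, spec$n_groups)), b = 0)
  out <- constrainedConv(X, layer, spec)$out
  Xs <- X[, c(9:10, 1:8), ]                  # shift rows by 2 (wrap)
  outs <- constrainedConv(Xs, layer, spec)$out
  # shifted input gives shifted output away from the zero-padded border
  expect_all_equal(out[1, 4:7, 3:8], outs[1, 6:9, 3:8], 1e-10)
})

test_that("backprop matches finite differences through conv, bn and relu", {
  img <- toyImage(4, 8, channels = 3)
  params <- dcfInit(3, 2, "visium", hidden = 4, seed = 3)
  set.seed(13)
  R <- matrix(rnorm(2 * prod(dim(img@X)[2:3])), 2)
  lossfun <- function(p) sum(dcfForward(p, img, training = TRUE)$O * R)
  fw <- dcfForward(params, img, training = TRUE)
  bk <- dcfBackward(params, fw$cache, R)
  h <- 1e-5
  for (path in c("sub.1.conv.1.W", "sub.1.conv.2.W", "sub.2.conv.1.W",
                 "sub.1.bn.1.gamma", "sub.2.bn.3.beta", "sub.1.conv.4.W",
                 "sub.2.conv.4.b")) {
    val <- spotDomains:::.getPath(params, path)
    g_an <- spotDomains:::.getPath(bk$grads, path)
    for (idx in sample(length(val), min(3, length(val)))) {
      vp <- val; vp[idx] <- vp[idx] + h
      vm <- val; vm[idx] <- vm[idx] - h
      g_num <- (lossfun(spotDomains:::.setPath(params, path, vp)) -
                  lossfun(spotDomains:::.setPath(params, path, vm))) / (2 * h)
      expect_equal(g_an[idx], g_num, tolerance = 1e-4,
                   label = paste("grad", path, idx))
    }
  }
})

test_that("zero-mask and tie invariants hold bitwise through optimization", {
  img <- toyImage(4, 8, channels = 3)
  params <- dcfInit(3, 2, "visium", hidden = 4, seed = 4)
  opt <- adamInit(params)
  set.seed(14)
  for (step in 1:10) {
    fw <- dcfForward(params, img, training = TRUE)
    params <- fw$params
    R <- matrix(rnorm(length(fw$O)), nrow(fw$O))
    bk <- dcfBackward(params, fw$cache, R)
    st <- adamStep(params, bk$grads, opt, 0.01)
    params <- st$params; opt <- st$opt
  }
  for (f in 1:2) {
    spec <- params$sub[[f]]$spec
    for (j in 1:3) {
      K <- kernelTensor(params$sub[[f]]$conv[[j]]$W, spec)
      expect_identical(K, enforceConstraints(K, spec))
    }
  }
})
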