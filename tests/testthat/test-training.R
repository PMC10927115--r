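# brute-force references for the soft assignment and target distribution
bruteQ <- function(E, mu) {
  s <- nrow(E); n <- nrow(mu)
  Q <- matrix(0, s, n)
  for (i in 1:s) for (j in 1:n)
    Q[i, j] <- 1 / (1 + sum((E[i, ] - mu[j, ])^2))
  Q / rowSums(Q)
}
bruteP <- function(Q) {
  s <- nrow(Q); n <- ncol(Q)
  P <- matrix(0, s, n)
  for (i in 1:s) for (j in 1:n)
    P[i, j] <- Q[i, j]^2 / sum(Q[, j])
  P / rowSums(P)
}

test_that("soft assignment follows the student-t kernel", {
  mu <- rbind(c(0, 0), c(3, 0))
  # spot at a centroid, the other centroid at distance 3
  Q <- softAssign(rbind(c(0, 0)), mu)
  expect_equal(Q[1, 1], 10 / 11, tolerance = 1e-12)
  # equidistant from all centroids: uniform
  Qe <- softAssign(rbind(c(1.5, 5)), mu)
  expect_all_equal(Qe, matrix(0.5, 1, 2), 1e-12)

  set.seed(41)
  E <- matrix(rnorm(100), 20, 5)
  mu5 <- matrix(rnorm(25), 5, 5)
  Q <- softAssign(E, mu5)
  expect_all_equal(Q, bruteQ(E, mu5), 1e-12)
  expect_all_equal(rowSums(Q), rep(1, 20), 1e-12)
})

test_that("target distribution sharpens Q per the stated formula", {
  Qu <- matrix(1 / 3, 4, 3)
  expect_all_equal(targetDistribution(Qu), Qu, 1e-12)
  Qh <- diag(3)[c(1, 2, 3, 1), ]
  expect_all_equal(targetDistribution(Qh), Qh, 1e-12)
  set.seed(42)
  Q <- matrix(runif(6), 3, 2)
  Q <- Q / rowSums(Q)
  expect_all_equal(targetDistribution(Q), bruteP(Q), 1e-12)
  expect_error(targetDistribution(cbind(rep(1, 3), rep(0, 3))), "zero")
})

test_that("KL and high-confidence cross-entropy evaluate the closed forms", {
  P <- rbind(c(1, 0)); Q <- rbind(c(0.5, 0.5))
  expect_equal(klLoss(P, Q), log(2), tolerance = 1e-6)
  expect_equal(klLoss(Q, Q), 0, tolerance = 1e-10)
  set.seed(43)
  for (i in 1:20) {
    A <- matrix(runif(8), 2); A <- A / rowSums(A)
    B <- matrix(runif(8), 2); B <- B / rowSums(B)
    expect_gte(klLoss(A, B), -1e-10)
  }

  expect_equal(highConfCE(rbind(c(0.6, 0.4)), 0.5), -log(0.6),
               tolerance = 1e-9)
  expect_equal(highConfCE(rbind(c(1, 0), c(0, 1)), 0.9), 0,
               tolerance = 1e-9)
  # q_cut = 0 includes every spot
  Q <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  expect_equal(highConfCE(Q, 0), mean(-log(c(0.6, 0.7))), tolerance = 1e-9)
  expect_equal(highConfCE(rbind(c(0.5, 0.5)), 0.6), 0)  # empty set
})

test_that("continuity loss pairs the right lattice neighbours", {
  # constant embeddings: zero loss
  si <- rbind(c(0, 0), c(1, 1), c(0, 2))
  E <- matrix(1, 3, 2)
  expect_equal(continuityLoss(E, si, "visium"), 0)

  # one diagonal visium pair at embedding distance 2: 0.58 * 2
  si2 <- rbind(c(0, 0), c(1, 1))
  E2 <- rbind(c(0, 0), c(2, 0))
  expect_equal(continuityLoss(E2, si2, "visium",
                              c(ortho = 0.62, diag = 0.58)), 0.58 * 2)
  # same geometry under stereo weights: diagonal weight is 0, and (1,1)
  # is not a stereo orthogonal offset
  expect_equal(continuityLoss(E2, si2, "stereo",
                              c(ortho = 0.62, diag = 0)), 0)
  # an orthogonal visium pair at offset (0,2)
  si3 <- rbind(c(0, 0), c(0, 2))
  expect_equal(continuityLoss(E2, si3, "visium",
                              c(ortho = 0.62, diag = 0.58)), 0.62 * 2)
})

test_that("total loss applies the stated weights", {
  expect_equal(totalLoss(1, 1, 1), 2.49)
  expect_equal(totalLoss(0, 0, 0), 0)
  expect_equal(totalLoss(2, 1, 3, c(kl = 0.5, ce = 0.25, cont = 1)), 4.25)
})

test_that("stop conditions fire on label collapse and convergence", {
  expect_true(stopCheck(rep(0:5, 10), NULL, 7)$stop)       # 6 < n = 7
  C <- c(rep(3L, 9), rep(0:2, length.out = 991))  # smallest share 9/1000
  expect_true(stopCheck(C, NULL, 4, min_frac = 0.01)$stop)
  Ca <- rep(0:3, 250)
  expect_false(stopCheck(Ca, NULL, 4)$stop)
  # change ratio below 0.001 stops only on a P-update iteration
  Cb <- Ca; Cb[1] <- (Cb[1] + 1) %% 4                      # ratio 0.001
  Cb2 <- Ca
  expect_false(stopCheck(Ca, Cb, 4, p_updated = TRUE)$stop)  # exactly 0.001
  Cb2[1] <- Ca[1]                                          # ratio 0.0000
  expect_true(stopCheck(Ca, Cb2, 4, p_updated = TRUE)$stop)
  expect_false(stopCheck(Ca, Cb2, 4, p_updated = FALSE)$stop)
})

test_that("loss gradients through Q and the continuity term are exact", {
  set.seed(44)
  E <- matrix(rnorm(12), 6, 2)
  mu <- matrix(rnorm(4), 2, 2)
  Q <- softAssign(E, mu)
  P <- targetDistribution(Q)
  qcut <- 0.4
  loss <- function(E, mu) {
    Q <- softAssign(E, mu)
    0.78 * klLoss(P, Q) + 0.71 * highConfCE(Q, qcut)
  }
  gQ <- -0.78 * P / (Q + 1e-12)
  qmax <- apply(Q, 1, max)
  keep <- which(qmax > qcut)
  jmax <- max.col(Q, ties.method = "first")[keep]
  gQ[cbind(keep, jmax)] <- gQ[cbind(keep, jmax)] -
    0.71 / (length(keep) * (qmax[keep] + 1e-12))
  sb <- spotDomains:::.softAssignBackward(E, mu, gQ)
  h <- 1e-6
  for (idx in sample(length(E), 4)) {
    Ep <- E; Ep[idx] <- Ep[idx] + h
    Em <- E; Em[idx] <- Em[idx] - h
    expect_equal(sb$dE[idx], (loss(Ep, mu) - loss(Em, mu)) / (2 * h),
                 tolerance = 1e-4)
  }
  for (idx in seq_along(mu)) {
    mp <- mu; mp[idx] <- mp[idx] + h
    mm <- mu; mm[idx] <- mm[idx] - h
    expect_equal(sb$dmu[idx], (loss(E, mp) - loss(E, mm)) / (2 * h),
                 tolerance = 1e-4)
  }

  si <- rbind(c(0, 0), c(1, 1), c(0, 2), c(2, 0), c(1, 3))
  E5 <- matrix(rnorm(10), 5, 2)
  cw <- c(ortho = 0.62, diag = 0.58)
  cres <- continuityLoss(E5, si, "visium", cw, grad = TRUE)
  for (idx in sample(length(E5), 5)) {
    Ep <- E5; Ep[idx] <- Ep[idx] + h
    Em <- E5; Em[idx] <- Em[idx] - h
    num <- (continuityLoss(Ep, si, "visium", cw) -
              continuityLoss(Em, si, "visium", cw)) / (2 * h)
    expect_equal(cres$dE[idx], num, tolerance = 1e-4)
  }
})

test_that("with P fixed, the KL term is minimized where Q matches P", {
  mu <- rbind(c(0, 0), c(4, 0))
  Ptarget <- rbind(c(0.7, 0.3))
  f <- function(e) klLoss(Ptarget, softAssign(matrix(e, 1), mu))
  opt <- optim(c(1, 1), f)
  Qstar <- softAssign(matrix(opt$par, 1), mu)
  expect_all_equal(Qstar, Ptarget, 1e-2)
})

test_that("pre-training reproduces the pseudo-labels and respects max_iter", {
  d <- simulateFixture(fixtureSpec(rows = 10, cols = 11, n_genes = 80,
                                   markers_per_domain = 8))
  d <- selectHVG(normalizeSpots(filterSpots(d)), 3000)
  p <- fitPCA(d, 10, "hvg")
  g <- buildSpotGraph(d)
  pre <- runAGC(pcaScores(p), laplacian(g), 3, seed = 0)
  img <- buildVirtualImage(d, p)
  cfg <- trainConfig("visium", 3)
  cfg$hidden <- 20L
  cfg$stop_in_pretrain <- FALSE   # measure pure fitting capacity
  params <- dcfInit(10, 3, "visium", hidden = 20L, seed = 0)

  pt0 <- pretrainDcf(params, img, preLabels(pre),
                     modifyList(cfg, list(max_pre = 0L)))
  expect_identical(pt0$params$sub[[1]]$conv[[1]]$W,
                   params$sub[[1]]$conv[[1]]$W)

  pt <- pretrainDcf(params, img, preLabels(pre), cfg)
  fw <- dcfForward(pt$params, img, training = TRUE)
  agree <- mean(max.col(spotDomains:::.softmaxRows(fw$E)) - 1L ==
                  preLabels(pre))
  expect_gte(agree, 0.95)
  expect_error(pretrainDcf(params, img, preLabels(pre)[-1], cfg), "spots")
})

test_that("training with zero loss weights freezes the labels, and Q and P
           stay row-stochastic", {
  d <- simulateFixture(fixtureSpec(rows = 10, cols = 11, n_genes = 80,
                                   markers_per_domain = 8))
  d <- selectHVG(normalizeSpots(filterSpots(d)), 3000)
  p <- fitPCA(d, 10, "hvg")
  g <- buildSpotGraph(d)
  pre <- runAGC(pcaScores(p), laplacian(g), 3, seed = 0)
  img <- buildVirtualImage(d, p)
  cfg <- trainConfig("visium", 3)
  cfg$hidden <- 20L
  cfg$stop_in_pretrain <- FALSE
  params <- dcfInit(10, 3, "visium", hidden = 20L, seed = 0)
  pt <- pretrainDcf(params, img, preLabels(pre), cfg)

  cfg0 <- cfg
  cfg0$loss_weights <- c(kl = 0, ce = 0, cont = 0)
  cfg0$max_train <- 5L
  cfg0$change_tol <- 0                       # disable the convergence stop
  tr0 <- trainDcf(pt$params, img, preLabels(pre), cfg0)
  fw <- dcfForward(pt$params, img, training = TRUE)
  frozen <- max.col(softAssign(fw$E, tr0$mu)) - 1L
  expect_identical(tr0$labels, frozen)

  tr <- trainDcf(pt$params, img, preLabels(pre), cfg)
  expect_all_equal(rowSums(tr$Q), rep(1, ncol(d)), 1e-9)
  expect_all_equal(rowSums(targetDistribution(tr$Q)), rep(1, ncol(d)), 1e-9)
  expect_true(all(is.finite(tr$traces$Lt)))
})
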