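test_that("Bray-Curtis matches its defining formula", {
  X <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0),
             s4 = c(2, 0, 0), s5 = c(0, 0, 3))
  colnames(X) <- c("a", "b", "c")
  D <- brayCurtis(X)
  expect_equal(D["s1", "s3"], 0)            # identical rows
  expect_equal(D["s4", "s5"], 1)            # disjoint support
  expect_equal(D["s1", "s2"], 0.5)          # 2/4 by hand
  # independent formula on random pairs
  set.seed(4)
  Y <- matrix(stats::rexp(30), 5, 6, dimnames = list(paste0("r", 1:5), NULL))
  DY <- brayCurtis(Y)
  for (pair in list(c(1, 2), c(3, 5))) {
    i <- pair[1]; j <- pair[2]
    expect_equal(DY[i, j],
                 sum(abs(Y[i, ] - Y[j, ])) / sum(Y[i, ] + Y[j, ]))
  }
  expect_error(brayCurtis(matrix(c(-1, 1), 1)), "negative")
})

test_that("all-zero samples get the boundary distance conventions", {
  X <- rbind(z1 = c(0, 0), z2 = c(0, 0), s = c(1, 2))
  D <- brayCurtis(X)
  expect_equal(D["z1", "z2"], 0)
  expect_equal(D["z1", "s"], 1)
})

test_that("similarity conversion follows the kernel definitions", {
  n <- 6L
  set.seed(7)
  P <- matrix(stats::runif(n * 4), n)
  D <- as.matrix(dist(P)); D <- D / max(D)
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))

  expect_equal(distanceToSimilarity(D, method = "complement"), 1 - D)
  z <- matrix(0, 3, 3)
  expect_true(all(distanceToSimilarity(z, method = "complement") == 1))
  expect_true(all(distanceToSimilarity(z, K = 2, method = "snf_kernel") == 1))

  # recompute the scaled-exponential kernel independently
  K <- 3L; mu <- 0.5
  W <- distanceToSimilarity(D, K = K, mu = mu)
  nnMean <- sapply(seq_len(n), function(i) mean(sort(D[i, -i])[1:K]))
  i <- 2L; j <- 5L
  eps <- (nnMean[i] + nnMean[j] + D[i, j]) / 3
  expect_equal(W[i, j], exp(-D[i, j]^2 / (mu * eps)))

  # monotone: with a shared bandwidth, larger distance -> smaller similarity
  expect_true(all(diff(exp(-c(0.1, 0.2, 0.3)^2 / (mu * eps))) < 0))
  expect_lt(.Machine$double.eps, min(W))
})

test_that("kingdom weights honor the scheme and sum to one", {
  counts <- c(bacteria = 5057, archaea = 166, fungi = 54, virus = 22)
  wp <- kingdomWeights(counts, "proportional")
  expect_equal(unname(wp["bacteria"]), 5057 / 5299, tolerance = 1e-12)
  expect_equal(sum(wp), 1)
  we <- kingdomWeights(counts, "equal")
  expect_equal(unname(we), rep(0.25, 4))
  wl <- kingdomWeights(counts, "log")
  expect_equal(sum(wl), 1)
  expect_true(all(diff(unname(wl)) < 0))       # preserves ordering
  expect_gt(min(wl), 0.1)                      # small kingdoms stay relevant
  expect_equal(unname(kingdomWeights(c(virus = 10))), 1)
  expect_error(kingdomWeights(c(a = 0, b = 0)), "positive")
})

test_that("fusion preserves symmetry, positivity and row normalization", {
  set.seed(2)
  mats <- lapply(1:3, function(i) {
    X <- matrix(stats::runif(25 * 8), 25)
    rownames(X) <- paste0("s", 1:25)
    distanceToSimilarity(brayCurtis(X), K = 8)
  })
  names(mats) <- c("bacteria", "fungi", "virus")
  w <- kingdomWeights(c(bacteria = 100, fungi = 20, virus = 5))
  fz <- fuse(mats, w, fusionConfig(K = 8, T = 15))
  F <- fz$fused
  expect_lt(max(abs(F - t(F))), 1e-9)
  expect_gte(min(F), 0)
  expect_lt(max(abs(rowSums(F) - 1)), 1e-9)
  for (P in fz$kernels) {
    expect_lt(max(abs(P - t(P))), 1e-9)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
})

test_that("degenerate fusion cases reduce to the single-view kernel", {
  set.seed(3)
  X <- matrix(stats::runif(20 * 6), 20)
  rownames(X) <- paste0("s", 1:20)
  W <- distanceToSimilarity(brayCurtis(X), K = 6)
  sims <- list(bacteria = W, archaea = W, fungi = W, virus = W)

  single <- fuse(sims["bacteria"], c(bacteria = 1), fusionConfig(K = 6, T = 10))
  expect_equal(single$iterations, 0L)

  degen <- fuse(sims, c(bacteria = 1, archaea = 0, fungi = 0, virus = 0),
                fusionConfig(K = 6, T = 10))
  expect_lt(max(abs(degen$fused - single$fused)), 1e-6)

  # T = 0 returns the weighted average of the initial normalized kernels
  w <- c(bacteria = 0.4, archaea = 0.3, fungi = 0.2, virus = 0.1)
  fz0 <- fuse(sims, w, fusionConfig(K = 6, T = 0))
  P0 <- kingdomFuse:::.normalizeKernel(W)
  expect_lt(max(abs(fz0$fused - P0)), 1e-9)  # all views equal here
})

test_that("identical views with block structure keep their eigen-structure", {
  set.seed(5)
  X <- rbind(matrix(stats::rnorm(15 * 8, 0), 15),
             matrix(stats::rnorm(15 * 8, 2), 15))
  rownames(X) <- sprintf("s%02d", 1:30)
  D <- as.matrix(dist(X)); D <- D / max(D)
  W <- distanceToSimilarity(D, K = 8)
  sims <- list(bacteria = W, archaea = W, fungi = W, virus = W)
  fz <- fuse(sims, kingdomWeights(c(bacteria = 1, archaea = 1,
                                    fungi = 1, virus = 1), "equal"),
             fusionConfig(K = 8, T = 10))
  e1 <- eigen(fz$fused, symmetric = TRUE)$vectors[, 2]
  e2 <- eigen(kingdomFuse:::.normalizeKernel(W), symmetric = TRUE)$vectors[, 2]
  expect_gt(abs(cor(e1, e2)), 0.95)
})

test_that("block-diagonal similarity stays block-diagonal through fusion", {
  W <- blockSimilarity(10, 10)
  fz <- fuse(list(bacteria = W, fungi = W), c(bacteria = 0.8, fungi = 0.2),
             fusionConfig(K = 5, T = 10))
  expect_equal(max(fz$fused[1:10, 11:20]), 0)
})

test_that("spectral clustering recovers exact blocks and respects k", {
  W <- blockSimilarity(12, 8)
  lab <- spectralCluster(W, 2, seed = 1L)
  expect_equal(ariScore(lab, rep(c("A", "B"), c(12, 8))), 1)
  # larger block is C1
  expect_equal(unname(table(lab)[["C1"]]), 12L)

  set.seed(6)
  pts <- matrix(stats::rnorm(8 * 2), 8)
  rownames(pts) <- paste0("s", 1:8)
  Wp <- distanceToSimilarity(as.matrix(dist(pts)) / 3, K = 4)
  lab7 <- spectralCluster(Wp, 7, seed = 1L)
  expect_equal(nlevels(droplevels(lab7)), 7L)

  expect_identical(spectralCluster(W, 2, seed = 3L),
                   spectralCluster(W, 2, seed = 3L))
})

test_that("silhouette scan picks the planted k and handles degeneracy", {
  W <- blockSimilarity(10, 10, within = 1, between = 0.05)
  scan <- silhouetteScan(W, kRange = 2:4, seed = 1L)
  expect_equal(scan$chosenK, 2L)
  expect_true(all(scan$scores$score >= -1 & scan$scores$score <= 1))

  flat <- matrix(1, 12, 12, dimnames = list(paste0("s", 1:12),
                                            paste0("s", 1:12)))
  scanFlat <- silhouetteScan(flat, kRange = 2:4, seed = 1L)
  expect_true(all(abs(scanFlat$scores$score) < 1e-9))
  expect_equal(scanFlat$chosenK, 2L)  # tie -> smallest k
})

test_that("mean silhouette agrees with the cluster package", {
  set.seed(8)
  X <- rbind(matrix(stats::rnorm(20, 0), 10), matrix(stats::rnorm(20, 3), 10))
  D <- as.matrix(dist(X))
  lab <- rep(1:2, each = 10)
  ours <- kingdomFuse:::.meanSilhouette(D, lab)
  ref <- mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the full WSNF run is deterministic and permutation-equivariant", {
  cfg <- quickConfig(seed = 21L)
  sim <- simulateCounts(cfg)
  fcfg <- fusionConfig(K = 10, kRange = 2:4, seed = 2L)
  f1 <- runWSNF(sim$table, fcfg)
  f2 <- runWSNF(sim$table, fcfg)
  expect_identical(subtypeLabels(f1), subtypeLabels(f2))
  expect_s4_class(f1, "FusionResult")
  expect_output(show(f1), "chosen k")

  set.seed(9)
  perm <- sample(sampleIDs(sim$table))
  tbP <- MultiKingdomTable(lapply(sim$table@assays,
                                  function(m) m[perm, , drop = FALSE]))
  fP <- runWSNF(tbP, fcfg)
  expect_equal(ariScore(subtypeLabels(f1), sim$truth$subtype),
               ariScore(subtypeLabels(fP), sim$truth$subtype[perm]))
})
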