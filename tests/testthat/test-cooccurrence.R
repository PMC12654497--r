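test_that("the basis-variance solver is exact on hand-built systems", {
  # construct t from known basis variances under the sparse truth (rho = 0)
  om <- c(1.0, 0.5, 2.0, 1.5)
  tMat <- outer(om, om, "+"); diag(tMat) <- 0
  solved <- kingdomFuse:::.solveBasis(tMat, matrix(FALSE, 4, 4))
  expect_lt(max(abs(solved - om)), 1e-8)

  # independent route: closed-form inverse of A = (m-2) I + J for m = 4
  m <- 4
  A <- matrix(1, m, m); diag(A) <- m - 1
  Ainv <- diag(m) / (m - 2) - matrix(1, m, m) / ((m - 2) * 2 * (m - 1))
  expect_lt(max(abs(Ainv %*% rowSums(tMat) - solved)), 1e-10)

  # known correlation structure round-trips through rho reconstruction
  rho <- diag(4); rho[1, 2] <- rho[2, 1] <- 0.6
  sig <- sqrt(outer(om, om))
  t2 <- outer(om, om, "+") - 2 * sig * rho; diag(t2) <- 0
  back <- kingdomFuse:::.rhoFromBasis(t2, om)
  expect_lt(max(abs(back - rho)), 1e-12)
})

test_that("SparCC recovers a planted correlation and stays null under independence", {
  pc <- data.frame(taxonA = "bacteria|b1", taxonB = "bacteria|b2", rho = 0.7)
  cfg <- simulationConfig(nSamplesPerSubtype = c(250L, 250L),
                          taxaPerKingdom = c(bacteria = 20L),
                          nSignalTaxa = c(bacteria = 0L),
                          zeroInflation = 0, plantedCorrelations = pc,
                          seed = 61L)
  fit <- sparcc(kingdomMatrix(simulateCounts(cfg)$table, "bacteria"))
  expect_lt(abs(sparccRho(fit)["b1", "b2"] - 0.7), 0.15)

  cfg0 <- simulationConfig(nSamplesPerSubtype = c(1000L, 1000L),
                           taxaPerKingdom = c(bacteria = 4L),
                           nSignalTaxa = c(bacteria = 0L),
                           zeroInflation = 0, seed = 62L)
  f0 <- sparcc(kingdomMatrix(simulateCounts(cfg0)$table, "bacteria"))
  r0 <- sparccRho(f0); diag(r0) <- 0
  expect_lt(max(abs(r0)), 0.15)
  expect_lt(max(abs(sparccRho(f0) - t(sparccRho(f0)))), 1e-12)
})

test_that("rho is invariant to per-sample rescaling (compositionality)", {
  cfg <- simulationConfig(nSamplesPerSubtype = c(60L, 60L),
                          taxaPerKingdom = c(bacteria = 10L),
                          nSignalTaxa = c(bacteria = 0L),
                          zeroInflation = 0, sequencingDepth = 1e6,
                          seed = 63L)
  counts <- kingdomMatrix(simulateCounts(cfg)$table, "bacteria")
  set.seed(1)
  scale <- sample(2:5, nrow(counts), replace = TRUE)
  r1 <- sparccRho(sparcc(counts))
  r2 <- sparccRho(sparcc(counts * scale))
  expect_lt(max(abs(r1 - r2)), 1e-3)   # residual difference is pseudo-count only
})

test_that("bootstrap p-values respect their bounds and flag planted pairs", {
  pairs <- data.frame(
    taxonA = paste0("bacteria|b", c(1, 3, 5, 7, 9)),
    taxonB = paste0("bacteria|b", c(2, 4, 6, 8, 10)),
    rho = 0.85)
  cfg <- simulationConfig(nSamplesPerSubtype = c(100L, 100L),
                          taxaPerKingdom = c(bacteria = 12L),
                          nSignalTaxa = c(bacteria = 0L),
                          zeroInflation = 0, plantedCorrelations = pairs,
                          seed = 64L)
  counts <- kingdomMatrix(simulateCounts(cfg)$table, "bacteria")
  fit <- sparccBootstrap(counts, sparcc(counts), nBoot = 399L, seed = 2L)
  p <- fit@p
  expect_true(all(p[upper.tri(p)] >= 1 / 400))
  expect_true(all(adjustedP(fit)[upper.tri(p)] >= p[upper.tri(p)] - 1e-12))
  for (i in seq_len(nrow(pairs))) {
    a <- sub("bacteria\\|", "", pairs$taxonA[i])
    b <- sub("bacteria\\|", "", pairs$taxonB[i])
    expect_lt(adjustedP(fit)[a, b], 0.05)
  }
  # a near-zero observed correlation cannot look extreme under the null
  r <- sparccRho(fit); diag(r) <- NA
  weak <- which(abs(r) == min(abs(r), na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_gt(p[weak[1], weak[2]], 0.2)
})

test_that("strong-edge summaries count kingdom-pair combinations", {
  m <- 13
  kingdoms <- c(rep("bacteria", 10), rep("fungi", 3))
  rho <- diag(m)
  rho[1:10, 1:10] <- 0.9
  diag(rho) <- 1
  taxa <- paste0("t", 1:m)
  dimnames(rho) <- list(taxa, taxa)
  names(kingdoms) <- taxa
  s <- strongEdgeSummary(rho, kingdoms, threshold = 0.5)
  bb <- s[s$pair == "bacteria-bacteria", ]
  expect_equal(bb$nStrong, 45)          # C(10, 2)
  expect_equal(bb$fraction, 1)
  expect_equal(s$nPairs[s$pair == "bacteria-fungi"], 30)
  expect_equal(s$nPairs[s$pair == "fungi-fungi"], 3)
  expect_equal(sum(s$nPairs), choose(m, 2))
  expect_equal(s$nStrong[s$pair != "bacteria-bacteria"], c(0, 0))

  weak <- diag(m); dimnames(weak) <- dimnames(rho)
  sw <- strongEdgeSummary(weak, kingdoms)
  expect_true(all(sw$nStrong == 0))
})

test_that("network construction thresholds edges and finds hubs", {
  m <- 8
  taxa <- paste0("t", 1:m)
  rho <- diag(m); dimnames(rho) <- list(taxa, taxa)
  padj <- matrix(1, m, m, dimnames = dimnames(rho))
  # star: t1 correlated with t2..t6
  for (j in 2:6) {
    rho["t1", taxa[j]] <- rho[taxa[j], "t1"] <- 0.8
    padj["t1", taxa[j]] <- padj[taxa[j], "t1"] <- 0.001
  }
  kingdoms <- stats::setNames(rep(c("bacteria", "fungi"), each = 4), taxa)
  fit <- new("SparccResult", rho = rho, omega = rep(1, m), p = padj,
             padj = padj, nBootstrap = 100L, seed = 1L)
  net <- buildNetwork(fit, kingdoms, alpha = 0.05)
  expect_equal(nrow(net@edges), 5L)
  expect_equal(sum(net@nodes$degree), 2L * nrow(net@edges))  # handshake
  core <- coreTaxa(net)
  expect_equal(core$taxon[core$kingdom == "bacteria"], "t1")

  empty <- new("SparccResult", rho = diag(4), omega = rep(1, 4),
               p = matrix(1, 4, 4), padj = matrix(1, 4, 4),
               nBootstrap = 10L, seed = 1L)
  rownames(empty@rho) <- colnames(empty@rho) <- paste0("x", 1:4)
  dimnames(empty@p) <- dimnames(empty@padj) <- dimnames(empty@rho)
  expect_warning(net0 <- buildNetwork(empty, stats::setNames(rep("virus", 4),
                                                             paste0("x", 1:4))),
                 "no significant")
  expect_equal(nrow(net0@edges), 0L)
  expect_true(all(net0@nodes$degree == 0L))
})

test_that("network exports are well-formed text files", {
  taxa <- paste0("g", 1:5)
  rho <- diag(5); dimnames(rho) <- list(taxa, taxa)
  rho[1, 2] <- rho[2, 1] <- -0.6
  padj <- matrix(1, 5, 5, dimnames = dimnames(rho))
  padj[1, 2] <- padj[2, 1] <- 0.01
  fit <- new("SparccResult", rho = rho, omega = rep(1, 5), p = padj,
             padj = padj, nBootstrap = 50L, seed = 1L)
  net <- buildNetwork(fit, stats::setNames(rep("bacteria", 5), taxa))
  g <- asIgraph(net)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$sign, "negative")
  dir <- withr::local_tempdir()
  paths <- writeNetworkFiles(net, dir)
  expect_true(all(file.exists(paths)))
  gexf <- readLines(paths[["gexf"]])
  expect_true(any(grepl("<gexf", gexf)))
  expect_true(any(grepl('source="g1" target="g2"', gexf)))
})
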