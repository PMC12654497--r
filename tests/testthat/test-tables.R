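test_that("write/read round trip preserves values and intersects samples", {
  dir <- withr::local_tempdir()
  tb <- tinyTable()
  md <- data.frame(sample_id = c(paste0("s", 1:4), "s9"),
                   response = c("R", "NR", "R", "NR", "R"))
  paths <- writeTables(tb, dir, metadata = md)
  expect_warning(
    rt <- readTables(paths[c("bacteria", "virus")], paths[["metadata"]]),
    "s9")
  expect_identical(rt$table@assays, tb@assays)
  expect_equal(rt$metadata$sample_id, paste0("s", 1:4))
})

test_that("malformed and negative cells are rejected with their location", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c("taxon_id\tkingdom\ts1\ts2",
               "b1\tbacteria\t3\t4",
               "b2\tbacteria\t-1\t2"), p)
  pm <- file.path(dir, "md.tsv")
  writeLines(c("sample_id\tresponse", "s1\tR", "s2\tNR"), pm)
  expect_error(readTables(c(bacteria = p), pm), "b2.*s1")

  writeLines(c("taxon_id\tkingdom\ts1\ts2",
               "b1\tbacteria\t3\toops"), p)
  expect_error(readTables(c(bacteria = p), pm), "malformed.*b1.*s2")
})

test_that("prevalence filter uses a ceiling-based presence count", {
  counts <- matrix(0L, 20, 3,
                   dimnames = list(sprintf("s%02d", 1:20), c("t1", "t2", "t3")))
  counts[1, "t1"] <- 5L            # present in 1/20: below ceil(0.1*20) = 2
  counts[1:2, "t2"] <- 1L          # present in exactly 2: retained
  counts[, "t3"] <- 7L             # everywhere
  tb <- MultiKingdomTable(list(bacteria = counts))
  out <- filterTaxaByPrevalence(tb, 0.10)
  expect_equal(colnames(kingdomMatrix(out, "bacteria")), c("t2", "t3"))
  out1 <- filterTaxaByPrevalence(tb, 1)
  expect_equal(colnames(kingdomMatrix(out1, "bacteria")), "t3")
})

test_that("richness filter is strict and pools kingdoms", {
  b <- matrix(0L, 2, 300, dimnames = list(c("keep", "drop"),
                                          sprintf("b%03d", 1:300)))
  b["keep", ] <- 1L
  b["drop", ] <- 1L
  v <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("keep", "drop"), "v1"))
  tb <- MultiKingdomTable(list(bacteria = b, virus = v))
  # keep has 301 nonzero taxa (> 300), drop has exactly 300 (not >)
  out <- filterSamplesByRichness(tb, 300L)
  expect_equal(sampleIDs(out), "keep")
  expect_error(filterSamplesByRichness(out, 301L), "every sample")
  expect_equal(nSamples(filterSamplesByRichness(tb, 0L)), 2L)
})

test_that("rarefaction conserves depth, drops shallow samples, matches expectation", {
  b <- matrix(c(400L, 150L, 50L,
                50L,  30L,  20L,
                900L, 60L,  40L), 3, 3, byrow = TRUE,
              dimnames = list(c("sA", "sB", "sC"), c("t1", "t2", "t3")))
  tb <- MultiKingdomTable(list(bacteria = b))
  expect_message(out <- rarefy(tb, depth = 500L, seed = 1L), "sB")
  m <- kingdomMatrix(out, "bacteria")
  expect_equal(sort(rownames(m)), c("sA", "sC"))
  expect_true(all(rowSums(m) == 500L))

  # depth equal to a sample's total returns it unchanged
  same <- rarefy(MultiKingdomTable(list(bacteria = b["sA", , drop = FALSE])),
                 depth = 600L, seed = 2L)
  expect_equal(kingdomMatrix(same, "bacteria")["sA", ], b["sA", ])

  # hypergeometric expectation on replicated rows of a 3-taxon toy
  reps <- 4000L
  toy <- matrix(rep(c(5L, 3L, 2L), each = reps), reps, 3,
                dimnames = list(sprintf("r%04d", 1:reps), c("a", "b", "c")))
  rr <- rarefy(MultiKingdomTable(list(bacteria = toy)), depth = 5L, seed = 3L)
  em <- colMeans(kingdomMatrix(rr, "bacteria"))
  expect_true(all(abs(em - c(2.5, 1.5, 1.0)) < 0.1))

  # determinism
  r1 <- rarefy(tb, 500L, seed = 9L); r2 <- rarefy(tb, 500L, seed = 9L)
  expect_identical(r1@assays, r2@assays)
})

test_that("relative abundance normalizes within the requested scope", {
  tb <- tinyTable()
  rel <- toRelativeAbundance(tb, scope = "per_kingdom")
  bm <- kingdomMatrix(rel, "bacteria")
  expect_equal(unname(bm["s4", ]), c(1, 1, 1) / 3)
  expect_equal(unname(rowSums(bm)), rep(1, 4))
  vm <- kingdomMatrix(rel, "virus")
  expect_equal(unname(vm["s4", ]), c(0, 0))   # all-zero stays zero, no NaN

  relG <- toRelativeAbundance(tb, scope = "global")
  tot <- rowSums(kingdomMatrix(relG, "bacteria")) +
         rowSums(kingdomMatrix(relG, "virus"))
  expect_equal(unname(tot), rep(1, 4))

  m <- matrix(c(2, 2, 6), 1, dimnames = list("s1", c("a", "b", "c")))
  one <- toRelativeAbundance(MultiKingdomTable(list(bacteria = m)))
  expect_equal(unname(kingdomMatrix(one, "bacteria")[1, ]), c(0.2, 0.2, 0.6))
})

test_that("hellinger square-roots proportions and preserves unit mass", {
  m <- matrix(c(0.25, 0.75, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  h <- hellinger(m)
  expect_equal(h["s1", ], c(a = 0.5, b = sqrt(0.75)))
  expect_equal(h["s2", ], c(a = 1, b = 0))
  expect_equal(rowSums(h^2), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  expect_error(hellinger(matrix(-0.1)), "negative")

  # Euclidean distance on transformed rows equals the Hellinger distance
  set.seed(1)
  P <- matrix(stats::runif(20), 4, 5); P <- P / rowSums(P)
  H <- hellinger(P)
  d12 <- sqrt(sum((H[1, ] - H[2, ])^2))
  expect_equal(d12, sqrt(sum((sqrt(P[1, ]) - sqrt(P[2, ]))^2)))
})

test_that("filters are invariant to sample order", {
  cfg <- quickConfig(seed = 11L)
  tb <- simulateCounts(cfg)$table
  perm <- sample(sampleIDs(tb))
  assays <- lapply(tb@assays, function(m) m[perm, , drop = FALSE])
  tbPerm <- MultiKingdomTable(assays)
  f1 <- filterTaxaByPrevalence(tb, 0.2)
  f2 <- filterTaxaByPrevalence(tbPerm, 0.2)
  expect_equal(taxaPerKingdom(f1), taxaPerKingdom(f2))
  expect_equal(lapply(f1@assays, colnames), lapply(f2@assays, colnames))
})
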