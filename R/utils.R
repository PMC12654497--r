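# Internal helpers: seed substreams, pooled views, small numerics.

# One user-facing seed drives a fixed substream per stage so stages can be
# re-run independently without coupling their RNG draws.
.substream <- function(seed, stage) {
  offsets <- c(counts = 1L, metadata = 2L, rarefy = 3L, fusion = 4L,
               permanova = 5L, split = 6L, models = 7L, bootstrap = 8L,
               network = 9L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) %% 2147480000 + 7919 * off) %% 2147483647)
}

# Evaluate expr under a local RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Pool kingdom matrices column-wise with kingdom-prefixed taxon ids,
# remembering the split so the pooled matrix can be mapped back.
.poolAssays <- function(x) {
  mats <- lapply(kingdomNames(x), function(k) {
    m <- kingdomMatrix(x, k)
    colnames(m) <- paste(k, colnames(m), sep = "|")
    m
  })
  pooled <- do.call(cbind, mats)
  split <- rep(kingdomNames(x), times = taxaPerKingdom(x))
  list(pooled = pooled, split = split)
}

.unpoolAssays <- function(pooled, split, template) {
  assays <- lapply(kingdomNames(template), function(k) {
    m <- pooled[, split == k, drop = FALSE]
    colnames(m) <- sub("^[^|]*\\|", "", colnames(m))
    m
  })
  names(assays) <- kingdomNames(template)
  assays
}

.checkSquare <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  invisible(D)
}

# Max absolute asymmetry, used in invariant checks.
.asym <- function(M) max(abs(M - t(M)))
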