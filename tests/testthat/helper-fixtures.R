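# Shared fixtures: tiny hand-built tables and small simulation configs.

tinyTable <- function() {
  b <- matrix(c(10, 0, 5,
                2, 8, 0,
                0, 1, 9,
                4, 4, 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("b", 1:3)))
  v <- matrix(c(1, 0,
                0, 2,
                3, 3,
                0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("v", 1:2)))
  MultiKingdomTable(list(bacteria = b, virus = v))
}

quickConfig <- function(seed = 1L, ...) {
  simulationConfig(nSamplesPerSubtype = c(20L, 20L),
                   taxaPerKingdom = c(bacteria = 40L, archaea = 10L,
                                      fungi = 8L, virus = 6L),
                   nSignalTaxa = c(bacteria = 16L, archaea = 4L,
                                   fungi = 3L, virus = 2L),
                   sequencingDepth = 2e4, seed = seed, ...)
}

# two-block similarity matrix with exact block structure
blockSimilarity <- function(n1 = 10L, n2 = 10L, within = 1, between = 0) {
  n <- n1 + n2
  W <- matrix(between, n, n)
  W[seq_len(n1), seq_len(n1)] <- within
  W[(n1 + 1):n, (n1 + 1):n] <- within
  dimnames(W) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  W
}

ariScore <- function(a, b) mclust::adjustedRandIndex(a, b)
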