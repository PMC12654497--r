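# SparCC compositional correlation with iterative strong-pair exclusion
# and permutation-bootstrap p-values.

# Log-ratio variance matrix t_ij = Var(log x_i - log x_j) from fractions.
.logRatioVariances <- function(frac) {
  L <- log(frac)
  C <- stats::cov(L)
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

# Solve the basis-variance system under the sparsity assumption, honoring
# an exclusion mask (TRUE = pair excluded from the aggregation).
.solveBasis <- function(tMat, excluded) {
  m <- nrow(tMat)
  inc <- !excluded
  diag(inc) <- FALSE
  # row i: sum_{j included} t_ij = (m - 1 - x_i) * w_i + sum_{j included} w_j
  # where x_i = number of excluded partners of i.
  A <- matrix(0, m, m)
  A[inc] <- 1
  xi <- (m - 1) - rowSums(inc)
  diag(A) <- m - 1 - xi
  b <- rowSums(tMat * inc)
  omega <- solve(A, b)
  if (any(omega <= 0)) {
    warning("SparCC: non-positive basis variance floored (degenerate system)")
    omega[omega <= 0] <- .Machine$double.eps
  }
  omega
}

.rhoFromBasis <- function(tMat, omega) {
  denom <- 2 * sqrt(outer(omega, omega))
  rho <- (outer(omega, omega, "+") - tMat) / denom
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  (rho + t(rho)) / 2
}

# Core SparCC pass on a count matrix; returns rho and omega.
.sparccCore <- function(counts, nExclusionIter, exclusionThreshold,
                        pseudoCount) {
  frac <- (counts + pseudoCount) / rowSums(counts + pseudoCount)
  tMat <- .logRatioVariances(frac)
  m <- ncol(counts)
  excluded <- matrix(FALSE, m, m)
  omega <- .solveBasis(tMat, excluded)
  rho <- .rhoFromBasis(tMat, omega)
  for (it in seq_len(nExclusionIter)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    # a taxon must keep at least 3 included partners or the system degrades
    starved <- rowSums(!excluded) - 1 <= 3
    cand[starved, ] <- 0
    cand[, starved] <- 0
    mx <- max(cand)
    if (mx < exclusionThreshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1L, ]
    excluded[idx[1L], idx[2L]] <- TRUE
    excluded[idx[2L], idx[1L]] <- TRUE
    omegaNew <- tryCatch(.solveBasis(tMat, excluded), error = function(e) NULL)
    if (is.null(omegaNew)) break   # singular system: keep last solution
    omega <- omegaNew
    rho <- .rhoFromBasis(tMat, omega)
  }
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  names(omega) <- colnames(counts)
  list(rho = rho, omega = omega)
}

#' SparCC compositionally corrected correlations
#'
#' Counts plus a pseudo-count are normalized to fractions per sample;
#' pairwise log-ratio variances t_ij = Var(ln x_i / x_j) are aggregated
#' per taxon and, under the sparse-correlation assumption, solved for
#' basis variances omega, giving
#' rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j)),
#' clipped to [-1, 1]. The strongest correlated pair is then iteratively
#' excluded from the aggregation and the system re-solved, up to
#' \code{nExclusionIter} times or until max |rho| falls below
#' \code{exclusionThreshold}.
#'
#' @param counts samples x taxa count matrix (>= 3 samples, >= 4 taxa).
#' @param nExclusionIter maximum strong-pair exclusions (default 10).
#' @param exclusionThreshold |rho| below which exclusion stops (default 0.1).
#' @param pseudoCount added to every count before forming fractions.
#' @return A \linkS4class{SparccResult} (rho and omega; p-values empty
#'   until \code{\link{sparccBootstrap}}).
#' @export
sparcc <- function(counts, nExclusionIter = 10L, exclusionThreshold = 0.1,
                   pseudoCount = 0.5) {
  stopifnot(ncol(counts) >= 4L, nrow(counts) >= 3L)
  fit <- .sparccCore(counts, nExclusionIter, exclusionThreshold, pseudoCount)
  new("SparccResult", rho = fit$rho, omega = fit$omega,
      p = matrix(numeric(0), 0, 0), padj = matrix(numeric(0), 0, 0),
      nBootstrap = 0L, seed = NA_integer_)
}

#' Bootstrap p-values for SparCC correlations
#'
#' Null datasets are formed by independently permuting each taxon's
#' counts across samples (breaking all associations while preserving
#' marginals); each is run through the same SparCC estimator and
#' p_ij = (1 + #{|rho_null| >= |rho_obs|}) / (nBoot + 1). The upper
#' triangle is BH-adjusted and mirrored.
#'
#' @param counts the observed count matrix.
#' @param result the observed \linkS4class{SparccResult}.
#' @param nBoot bootstrap iterations (default 500).
#' @param seed RNG seed.
#' @param nExclusionIter,exclusionThreshold,pseudoCount passed through to
#'   the estimator (match the observed run).
#' @return The result with p and padj matrices filled in.
#' @export
sparccBootstrap <- function(counts, result, nBoot = 500L, seed = 1L,
                            nExclusionIter = 10L, exclusionThreshold = 0.1,
                            pseudoCount = 0.5) {
  stopifnot(nBoot >= 1L)
  rhoObs <- abs(result@rho)
  m <- ncol(counts)
  exceed <- matrix(0L, m, m)
  .withSeed(.substream(seed, "bootstrap"), {
    for (b in seq_len(nBoot)) {
      perm <- apply(counts, 2L, sample)
      rownames(perm) <- rownames(counts)
      # permuted-null fits routinely hit the negative-basis-variance
      # degeneracy; the floor is applied silently here
      rhoNull <- suppressWarnings(
        .sparccCore(perm, nExclusionIter, exclusionThreshold,
                    pseudoCount)$rho)
      exceed <- exceed + (abs(rhoNull) >= rhoObs)
    }
  })
  p <- (1 + exceed) / (nBoot + 1)
  diag(p) <- NA_real_
  padj <- p
  up <- upper.tri(p)
  padj[up] <- stats::p.adjust(p[up], "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  dimnames(p) <- dimnames(padj) <- dimnames(result@rho)
  new("SparccResult", rho = result@rho, omega = result@omega, p = p,
      padj = padj, nBootstrap = as.integer(nBoot), seed = as.integer(seed))
}

#' Strong-edge summary by kingdom pair
#'
#' Counts, per unordered kingdom pair, the unordered taxon pairs whose
#' |rho| exceeds the threshold, plus the fraction of all pairs in that
#' combination.
#'
#' @param rho correlation matrix.
#' @param kingdoms character vector: kingdom of each taxon (rho order),
#'   or named by taxon.
#' @param threshold |rho| cutoff (default 0.5).
#' @return data.frame pair, nStrong, nPairs, fraction.
#' @export
strongEdgeSummary <- function(rho, kingdoms, threshold = 0.5) {
  .checkSquare(rho)
  if (!is.null(names(kingdoms)) && !is.null(rownames(rho)))
    kingdoms <- kingdoms[rownames(rho)]
  stopifnot(length(kingdoms) == nrow(rho))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  pair <- paste(pmin(kingdoms[idx[, 1L]], kingdoms[idx[, 2L]]),
                pmax(kingdoms[idx[, 1L]], kingdoms[idx[, 2L]]), sep = "-")
  strong <- abs(rho[upper.tri(rho)]) > threshold
  agg <- tapply(strong, pair, function(v) c(sum(v), length(v)))
  out <- data.frame(pair = names(agg),
                    nStrong = vapply(agg, `[`, numeric(1L), 1L),
                    nPairs = vapply(agg, `[`, numeric(1L), 2L),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$fraction <- out$nStrong / out$nPairs
  out
}
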