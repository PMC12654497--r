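# Weighted similarity network fusion: per-kingdom Bray-Curtis distances,
# similarity kernels, count-based kingdom weights, iterative cross-view
# diffusion that maintains symmetry and row-normalization, silhouette-based
# choice of cluster number, spectral clustering.

#' Fusion configuration
#'
#' @param K neighborhood size for the local kernel (capped at n/3 at run
#'   time).
#' @param mu kernel bandwidth scale in (0, 1] typically; default 0.5.
#' @param T maximum diffusion iterations.
#' @param kRange candidate cluster numbers for the silhouette scan.
#' @param tol early-stopping tolerance on the max absolute change of any
#'   view kernel between iterations.
#' @param seed RNG seed (k-means restarts).
#' @param weightScheme kingdom-weight scheme: "log" (default),
#'   "proportional" or "equal"; see \code{\link{kingdomWeights}}.
#' @param kernel similarity conversion: "snf_kernel" or "complement".
#' @param scope relative-abundance scope fed to the per-kingdom distances.
#' @return list of class FusionConfig.
#' @export
fusionConfig <- function(K = 20L, mu = 0.5, T = 20L, kRange = 2:8,
                         tol = 1e-6, seed = 1L,
                         weightScheme = c("log", "proportional", "equal"),
                         kernel = c("snf_kernel", "complement"),
                         scope = c("per_kingdom", "global")) {
  stopifnot(K >= 1, mu > 0, T >= 0, tol > 0, all(kRange >= 2))
  structure(list(K = as.integer(K), mu = mu, T = as.integer(T),
                 kRange = as.integer(kRange), tol = tol,
                 seed = as.integer(seed),
                 weightScheme = match.arg(weightScheme),
                 kernel = match.arg(kernel),
                 scope = match.arg(scope)),
            class = "FusionConfig")
}

#' Bray-Curtis distance matrix between samples
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j); a pair of all-zero samples
#' has distance 0 by convention.
#'
#' @param X non-negative samples x taxa matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
brayCurtis <- function(X) {
  if (any(X < 0)) stop("brayCurtis: negative entries")
  D <- as.matrix(suppressWarnings(vegan::vegdist(X, method = "bray")))
  empty <- rowSums(X) == 0
  if (any(empty)) {
    D[empty, ] <- 1; D[, empty] <- 1
    D[empty, empty] <- 0   # all-zero vs all-zero
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Convert a distance matrix to a similarity matrix
#'
#' The default is the scaled-exponential SNF kernel
#' W(i,j) = exp(-d^2(i,j) / (mu * eps_ij)) with
#' eps_ij = (mean_{l in N_K(i)} d(i,l) + mean_{l in N_K(j)} d(j,l) + d(i,j)) / 3;
#' "complement" returns 1 - D.
#'
#' @param D distance matrix.
#' @param K neighborhood size for the bandwidth (snf_kernel only).
#' @param mu bandwidth scale.
#' @param method "snf_kernel" or "complement".
#' @return Symmetric similarity matrix.
#' @export
distanceToSimilarity <- function(D, K = 20L, mu = 0.5,
                                 method = c("snf_kernel", "complement")) {
  method <- match.arg(method)
  .checkSquare(D)
  n <- nrow(D)
  if (method == "complement") {
    W <- 1 - D
  } else {
    K <- min(K, n - 1L)
    nnMean <- vapply(seq_len(n), function(i) {
      mean(sort(D[i, -i])[seq_len(K)])
    }, numeric(1L))
    eps <- (outer(nnMean, nnMean, "+") + D) / 3
    eps <- pmax(eps, 1e-12)
    W <- exp(-D^2 / (mu * eps))
  }
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(D)
  W
}

#' Kingdom weights from taxa counts
#'
#' "proportional" uses w_k = m_k / sum(m); "log" (default) uses
#' w_k = log10(1 + m_k) / sum log10(1 + m), which keeps the small kingdoms
#' numerically relevant despite order-of-magnitude count differences;
#' "equal" gives 1/#kingdoms.
#'
#' @param taxaCounts named non-negative integer vector.
#' @param scheme weighting scheme.
#' @return Named weights summing to 1.
#' @export
kingdomWeights <- function(taxaCounts,
                           scheme = c("log", "proportional", "equal")) {
  scheme <- match.arg(scheme)
  if (any(taxaCounts < 0) || all(taxaCounts == 0))
    stop("taxaCounts must be non-negative with at least one positive entry")
  w <- switch(scheme,
              proportional = taxaCounts / sum(taxaCounts),
              log = log10(1 + taxaCounts) / sum(log10(1 + taxaCounts)),
              equal = rep(1 / length(taxaCounts), length(taxaCounts)))
  names(w) <- names(taxaCounts)
  w
}

# Symmetric Sinkhorn scaling: drives row sums to 1 while preserving
# symmetry exactly (M <- M / sqrt(d_i d_j)).
.sinkhornSym <- function(M, tol = 1e-12, maxit = 500L) {
  for (it in seq_len(maxit)) {
    d <- rowSums(M)
    if (max(abs(d - 1)) < tol) break
    s <- sqrt(pmax(d, 1e-300))
    M <- M / outer(s, s)
  }
  (M + t(M)) / 2
}

# Full kernel: half-mass diagonal row normalization, then symmetric
# doubly-stochastic scaling.
.normalizeKernel <- function(W) {
  diag(W) <- 0
  rs <- rowSums(W)
  P <- W / (2 * pmax(rs, 1e-300))
  diag(P) <- 0.5
  if (any(rs == 0)) {
    z <- which(rs == 0)
    P[z, ] <- 0
    P[cbind(z, z)] <- 1
  }
  .sinkhornSym((P + t(P)) / 2)
}

# Sparse local kernel: each row normalized over its K nearest neighbors.
.localKernel <- function(W, K) {
  n <- nrow(W)
  K <- min(K, n - 1L)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    ord <- order(W[i, -i], decreasing = TRUE)
    nb <- setdiff(seq_len(n), i)[ord][seq_len(K)]
    wi <- W[i, nb]
    if (sum(wi) == 0) wi <- rep(1, K)
    S[i, nb] <- wi / sum(wi)
  }
  S
}

#' Fuse per-kingdom similarity networks
#'
#' Iterative weighted cross-diffusion: each view's kernel is updated
#' through its local neighborhood graph against the weighted average of
#' the other views' kernels, then symmetrized and rescaled to a symmetric
#' doubly-stochastic matrix, so every iteration preserves non-negativity,
#' symmetry and unit row sums. Views with zero weight are dropped; a
#' single view is returned as its own normalized kernel.
#'
#' @param similarities named list of similarity matrices over one sample set.
#' @param weights named non-negative weights (matched by name; normalized
#'   to sum 1 over the views used).
#' @param config a \code{\link{fusionConfig}}.
#' @return list(fused = matrix, iterations = integer, kernels = list of
#'   final per-view kernels).
#' @export
fuse <- function(similarities, weights, config = fusionConfig()) {
  stopifnot(length(similarities) >= 1L, !is.null(names(similarities)))
  weights <- weights[names(similarities)]
  if (anyNA(weights)) stop("weights must cover every view")
  keep <- weights > 0
  similarities <- similarities[keep]
  weights <- weights[keep] / sum(weights[keep])
  if (length(similarities) == 0L) stop("all weights are zero")
  n <- nrow(similarities[[1L]])
  P <- lapply(similarities, .normalizeKernel)
  if (length(P) == 1L)
    return(list(fused = P[[1L]], iterations = 0L, kernels = P))
  K <- min(config$K, n - 1L)
  S <- lapply(similarities, .localKernel, K = K)
  iters <- 0L
  if (config$T > 0L) {
    for (t in seq_len(config$T)) {
      Pnew <- P
      for (k in seq_along(P)) {
        others <- setdiff(seq_along(P), k)
        wo <- weights[others] / sum(weights[others])
        avg <- Reduce(`+`, Map(function(w, M) w * M, wo, P[others]))
        M <- S[[k]] %*% avg %*% t(S[[k]])
        M <- .sinkhornSym((M + t(M)) / 2)
        # invariants maintained by construction; assert cheaply
        stopifnot(min(M) >= 0, .asym(M) < 1e-9,
                  max(abs(rowSums(M) - 1)) < 1e-9)
        Pnew[[k]] <- M
      }
      delta <- max(vapply(seq_along(P),
                          function(k) max(abs(Pnew[[k]] - P[[k]])), numeric(1L)))
      P <- Pnew
      iters <- t
      if (delta < config$tol) break
    }
  }
  fused <- Reduce(`+`, Map(function(w, M) w * M, weights, P))
  fused <- .sinkhornSym((fused + t(fused)) / 2)
  list(fused = fused, iterations = iters, kernels = P)
}

#' Spectral clustering of a fused similarity network
#'
#' Normalized spectral clustering: take the top-k eigenvectors of
#' D^{-1/2} W D^{-1/2} (equivalently the bottom-k of the symmetric
#' normalized Laplacian), unit-normalize the rows and run k-means with
#' multiple restarts. Clusters are renamed C1, C2, ... by decreasing size
#' (ties broken by the lexicographically smallest member sample id).
#'
#' @param W symmetric non-negative similarity matrix.
#' @param k number of clusters (2 <= k < n).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts (>= 10).
#' @return Factor of labels named by sample id.
#' @export
spectralCluster <- function(W, k, seed = 1L, nstart = 25L) {
  .checkSquare(W)
  n <- nrow(W)
  stopifnot(k >= 2, k < n)
  d <- rowSums(W)
  s <- 1 / sqrt(pmax(d, 1e-300))
  Wn <- W * outer(s, s)
  eig <- eigen((Wn + t(Wn)) / 2, symmetric = TRUE)
  if (sum(eig$values > 1 - 1e-10) > k)
    warning("similarity graph has more than k near-disconnected components")
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- .withSeed(.substream(seed, "fusion"),
                  stats::kmeans(U, centers = k, nstart = max(10L, nstart),
                                iter.max = 100L))
  raw <- km$cluster
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  firstID <- vapply(seq_len(k), function(g) min(ids[raw == g]), character(1L))
  ord <- order(-tabulate(raw, k), firstID)
  lab <- factor(paste0("C", match(raw, ord)),
                levels = paste0("C", seq_len(k)))
  names(lab) <- ids
  lab
}

# Mean silhouette from a distance matrix; singleton clusters score 0.
.meanSilhouette <- function(D, labels) {
  labels <- as.factor(labels)
  n <- nrow(D)
  s <- numeric(n)
  lev <- levels(labels)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(lev[lev != labels[i]], function(g) {
      mean(D[i, labels == g])
    }, numeric(1L)))
    mx <- max(a, b)
    s[i] <- if (mx == 0) 0 else (b - a) / mx
  }
  mean(s)
}

#' Silhouette scan over candidate cluster numbers
#'
#' The silhouette distance is 1 - Wtilde where Wtilde is the fused
#' similarity rescaled to [0, 1] over off-diagonal entries with a zero
#' diagonal. The chosen k maximizes the mean silhouette (ties go to the
#' smallest k).
#'
#' @param W fused similarity matrix.
#' @param kRange candidate cluster counts.
#' @param seed RNG seed.
#' @return list(scores = data.frame(k, score), chosenK = integer).
#' @export
silhouetteScan <- function(W, kRange = 2:8, seed = 1L) {
  .checkSquare(W)
  n <- nrow(W)
  kRange <- as.integer(kRange[kRange >= 2 & kRange <= n - 1L])
  stopifnot(length(kRange) >= 1L)
  Wt <- W; diag(Wt) <- NA
  rng <- range(Wt, na.rm = TRUE)
  Ws <- if (diff(rng) > 0) (Wt - rng[1L]) / diff(rng) else Wt * 0
  D <- 1 - Ws
  diag(D) <- 0
  scores <- vapply(kRange, function(k) {
    .meanSilhouette(D, spectralCluster(W, k, seed = seed))
  }, numeric(1L))
  list(scores = data.frame(k = kRange, score = scores),
       chosenK = kRange[which.max(scores)])
}

#' Run the full WSNF subtype analysis
#'
#' Composes relative abundance -> Hellinger -> per-kingdom Bray-Curtis ->
#' similarity kernel -> kingdom weights -> fusion -> silhouette scan ->
#' spectral clustering, recording every intermediate.
#'
#' @param table a preprocessed MultiKingdomTable of counts.
#' @param config a \code{\link{fusionConfig}}.
#' @return A \linkS4class{FusionResult}.
#' @export
runWSNF <- function(table, config = fusionConfig()) {
  stopifnot(is(table, "MultiKingdomTable"))
  n <- nSamples(table)
  K <- min(config$K, max(2L, floor(n / 3)))
  rel <- toRelativeAbundance(table, scope = config$scope)
  h <- hellinger(rel)
  sims <- lapply(kingdomNames(h), function(k) {
    D <- brayCurtis(kingdomMatrix(h, k))
    distanceToSimilarity(D, K = K, mu = config$mu, method = config$kernel)
  })
  names(sims) <- kingdomNames(h)
  w <- kingdomWeights(taxaPerKingdom(table), scheme = config$weightScheme)
  fz <- fuse(sims, w, fusionConfig(K = K, mu = config$mu, T = config$T,
                                   kRange = config$kRange, tol = config$tol,
                                   seed = config$seed,
                                   weightScheme = config$weightScheme,
                                   kernel = config$kernel,
                                   scope = config$scope))
  scan <- silhouetteScan(fz$fused, kRange = config$kRange, seed = config$seed)
  labels <- spectralCluster(fz$fused, scan$chosenK, seed = config$seed)
  new("FusionResult", similarities = sims, weights = w, fused = fz$fused,
      silhouette = scan$scores, chosenK = as.integer(scan$chosenK),
      labels = labels, iterations = as.integer(fz$iterations))
}
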