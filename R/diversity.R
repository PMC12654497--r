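# Alpha/beta diversity and a permutation PERMANOVA.

#' Alpha diversity per sample
#'
#' Observed taxa (nonzero entries) and the natural-log Shannon index
#' -sum p_i ln p_i over nonzero proportions. With scope "total" the
#' kingdoms are pooled per sample; with "per_kingdom" each kingdom is
#' summarized separately.
#'
#' @param table a MultiKingdomTable (counts or relative values).
#' @param scope "total" or "per_kingdom".
#' @return data.frame with columns sample_id, kingdom ("total" or the
#'   kingdom), observed, shannon.
#' @export
alphaDiversity <- function(table, scope = c("total", "per_kingdom")) {
  scope <- match.arg(scope)
  one <- function(m, label) {
    obs <- rowSums(m > 0)
    sh <- apply(m, 1L, function(x) {
      tot <- sum(x)
      if (tot == 0) return(0)
      p <- x[x > 0] / tot
      -sum(p * log(p))
    })
    data.frame(sample_id = rownames(m), kingdom = label,
               observed = as.integer(obs), shannon = sh,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (scope == "total") {
    one(.poolAssays(table)$pooled, "total")
  } else {
    do.call(rbind, lapply(kingdomNames(table), function(k)
      one(kingdomMatrix(table, k), k)))
  }
}

#' Compare alpha diversity between subtypes
#'
#' Welch (unequal-variance) two-sample t-tests per metric.
#'
#' @param alpha output of \code{\link{alphaDiversity}}.
#' @param labels factor of subtype labels named by sample id.
#' @return data.frame kingdom, metric, t, p.
#' @export
compareAlphaDiversity <- function(alpha, labels) {
  stopifnot(!is.null(names(labels)))
  do.call(rbind, lapply(split(alpha, alpha$kingdom), function(df) {
    g <- droplevels(as.factor(labels[df$sample_id]))
    do.call(rbind, lapply(c("observed", "shannon"), function(metric) {
      tt <- stats::t.test(df[[metric]] ~ g)
      data.frame(kingdom = df$kingdom[1L], metric = metric,
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis on abundances or Jaccard on presence/absence
#' (1 - |intersection| / |union|). Kingdoms are pooled ("total") or taken
#' singly.
#'
#' @param table a MultiKingdomTable.
#' @param metric "bray_curtis" or "jaccard".
#' @param scope "total" or a kingdom name.
#' @return Symmetric distance matrix.
#' @export
betaDistance <- function(table, metric = c("bray_curtis", "jaccard"),
                         scope = "total") {
  metric <- match.arg(metric)
  X <- if (identical(scope, "total")) .poolAssays(table)$pooled
       else kingdomMatrix(table, scope)
  if (any(X < 0)) stop("betaDistance: negative entries")
  if (metric == "bray_curtis") return(brayCurtis(X))
  B <- (X > 0) * 1
  D <- as.matrix(suppressWarnings(vegan::vegdist(B, method = "jaccard",
                                                 binary = TRUE)))
  empty <- rowSums(B) == 0
  if (any(empty)) {
    D[empty, ] <- 1; D[, empty] <- 1
    D[empty, empty] <- 0
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

# Pseudo-F from squared distances for a grouping.
.permanovaF <- function(D2, groups) {
  n <- nrow(D2)
  lev <- levels(groups)
  a <- length(lev)
  ssTotal <- sum(D2[upper.tri(D2)]) / n
  ssWithin <- sum(vapply(lev, function(g) {
    idx <- which(groups == g)
    sum(D2[idx, idx][upper.tri(D2[idx, idx, drop = FALSE])]) / length(idx)
  }, numeric(1L)))
  ssBetween <- ssTotal - ssWithin
  (ssBetween / (a - 1)) / (ssWithin / (n - a))
}

#' PERMANOVA permutation test on a distance matrix
#'
#' Pseudo-F from total and within-group sums of squared distances;
#' the p-value is (1 + #permuted F >= observed F) / (nPerm + 1) under
#' random label permutations.
#'
#' @param D distance matrix.
#' @param labels grouping factor (>= 2 groups, each of size >= 2).
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list(pseudoF, p, nPerm, seed).
#' @export
permanova <- function(D, labels, nPerm = 999L, seed = 1L) {
  .checkSquare(D)
  groups <- droplevels(as.factor(labels))
  if (nlevels(groups) < 2L) stop("permanova needs >= 2 groups")
  if (any(table(groups) < 2L)) stop("permanova: every group needs >= 2 samples")
  D2 <- D^2
  fObs <- .permanovaF(D2, groups)
  exceed <- .withSeed(.substream(seed, "permanova"), {
    sum(vapply(seq_len(nPerm), function(b) {
      .permanovaF(D2, sample(groups)) >= fObs
    }, logical(1L)))
  })
  list(pseudoF = fObs, p = (1 + exceed) / (nPerm + 1),
       nPerm = as.integer(nPerm), seed = as.integer(seed))
}
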