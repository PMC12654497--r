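# Differential abundance: stratified split, median-of-ratios size factors,
# negative-binomial Wald tests with method-of-moments dispersion, BH
# correction with per-kingdom fold-change thresholds, panel selection.

#' Stratified train/test split of samples
#'
#' Within each subtype, round(fraction * n) samples are drawn without
#' replacement for the training set (always leaving at least one sample
#' in test).
#'
#' @param labels factor of subtype labels named by sample id.
#' @param fraction training fraction in (0, 1); default 0.70.
#' @param seed RNG seed.
#' @return list(train, test) of sample ids.
#' @export
stratifiedSplit <- function(labels, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  labels <- as.factor(labels)
  stopifnot(!is.null(names(labels)), all(table(labels) >= 2L))
  train <- .withSeed(.substream(seed, "split"), {
    unlist(lapply(levels(labels), function(g) {
      ids <- names(labels)[labels == g]
      nTrain <- min(round(fraction * length(ids)), length(ids) - 1L)
      sample(ids, nTrain)
    }), use.names = FALSE)
  })
  list(train = sort(train), test = sort(setdiff(names(labels), train)))
}

#' Median-of-ratios size factors
#'
#' f_s = median over taxa of count_st / geometric-mean_t, computed over
#' taxa with all-positive counts; if no taxon is everywhere positive the
#' factors fall back to library-size ratios (total / geometric mean of
#' totals).
#'
#' @param counts samples x taxa count matrix.
#' @return Named per-sample factors (geometric mean 1 under the fallback).
#' @export
sizeFactors <- function(counts) {
  pos <- colSums(counts > 0) == nrow(counts)
  if (any(pos)) {
    sub <- counts[, pos, drop = FALSE]
    logGeo <- colMeans(log(sub))
    f <- apply(sub, 1L, function(r) stats::median(exp(log(r) - logGeo)))
  } else {
    tot <- rowSums(counts)
    f <- tot / exp(mean(log(pmax(tot, 1))))
  }
  names(f) <- rownames(counts)
  f
}

#' Negative-binomial Wald test per taxon
#'
#' Counts are normalized by the size factors; per group the normalized
#' mean is estimated and a common dispersion alpha is estimated by the
#' method of moments from the within-group variance of the normalized
#' counts (Var(y) = mu / f + alpha mu^2), floored at 1e-8. The log2 fold
#' change is log2((mu_C2 + pc) / (mu_C1 + pc)) with pseudo-count
#' pc = 0.5 / median(size factors), and the Wald statistic is the fold
#' change over its delta-method standard error, referred to a two-sided
#' normal.
#'
#' @param counts samples x taxa count matrix (train samples).
#' @param labels two-level subtype factor named by sample id (C1 is the
#'   reference; fold changes are C2 vs C1).
#' @param sf size factors; computed from \code{counts} when NULL.
#' @param kingdoms optional named character giving each taxon's kingdom
#'   (carried into the result for downstream thresholds).
#' @return A \linkS4class{DifferentialResult} (thresholds not yet applied).
#' @export
nbWald <- function(counts, labels, sf = NULL, kingdoms = NULL) {
  labels <- droplevels(as.factor(labels[rownames(counts)]))
  if (nlevels(labels) != 2L) stop("nbWald needs exactly two groups")
  if (is.null(sf)) sf <- sizeFactors(counts)
  sf <- sf[rownames(counts)]
  y <- counts / sf
  g1 <- labels == levels(labels)[1L]
  g2 <- !g1
  pc <- 0.5 / stats::median(sf)
  n1 <- sum(g1); n2 <- sum(g2)
  invf1 <- mean(1 / sf[g1]); invf2 <- mean(1 / sf[g2])

  res <- lapply(seq_len(ncol(counts)), function(j) {
    yj <- y[, j]
    if (all(yj == 0)) return(NULL)
    m1 <- mean(yj[g1]); m2 <- mean(yj[g2])
    v1 <- stats::var(yj[g1]); v2 <- stats::var(yj[g2])
    # pooled MoM dispersion: (v - mu * mean(1/f)) / mu^2, weighted by df
    num <- (n1 - 1) * (v1 - m1 * invf1) + (n2 - 1) * (v2 - m2 * invf2)
    den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
    alphaHat <- max(if (den > 0) num / den else 0, 1e-8)
    lfc <- log2((m2 + pc) / (m1 + pc))
    varM1 <- (m1 * invf1 + alphaHat * m1^2) / n1
    varM2 <- (m2 * invf2 + alphaHat * m2^2) / n2
    se <- sqrt(varM1 / (m1 + pc)^2 + varM2 / (m2 + pc)^2) / log(2)
    z <- if (se > 0) lfc / se else 0
    data.frame(taxon = colnames(counts)[j],
               baseMean = mean(yj), log2fc = lfc, waldStat = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1L)))
  if (dropped) message("nbWald: excluded ", dropped, " all-zero taxa")
  tb <- do.call(rbind, res)
  tb$kingdom <- if (!is.null(kingdoms)) unname(kingdoms[tb$taxon]) else NA_character_
  tb <- tb[, c("taxon", "kingdom", "baseMean", "log2fc", "waldStat", "p")]
  new("DifferentialResult", table = tb, alpha = NA_real_,
      lfcThresholds = numeric(0))
}

#' Default per-kingdom |log2FC| thresholds
#'
#' 1 for bacteria, 0.5 for fungi and archaea, 0.25 for viruses.
#' @export
defaultLfcThresholds <- function() {
  c(bacteria = 1, archaea = 0.5, fungi = 0.5, virus = 0.25)
}

#' Apply BH correction and per-kingdom fold-change thresholds
#'
#' BH is applied jointly over all tested taxa (per-kingdom adjustment is
#' available via \code{perKingdom = TRUE}); a taxon is called significant
#' iff padj < alpha and |log2fc| >= the kingdom's threshold.
#'
#' @param result a \linkS4class{DifferentialResult} from \code{\link{nbWald}}.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param thresholds named |log2FC| cutoffs per kingdom.
#' @param perKingdom adjust p-values within each kingdom separately.
#' @return The result with padj and significant columns filled in.
#' @export
applyThresholds <- function(result, alpha = 0.05,
                            thresholds = defaultLfcThresholds(),
                            perKingdom = FALSE) {
  tb <- result@table
  if (perKingdom) {
    tb$padj <- stats::ave(tb$p, tb$kingdom,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  } else {
    tb$padj <- stats::p.adjust(tb$p, "BH")
  }
  thr <- thresholds[tb$kingdom]
  thr[is.na(thr)] <- 0
  tb$significant <- tb$padj < alpha & abs(tb$log2fc) >= thr
  new("DifferentialResult", table = tb, alpha = alpha,
      lfcThresholds = thresholds)
}

#' Select the multi-kingdom marker panel
#'
#' Within each kingdom, significant taxa are ranked by |log2fc|
#' descending (ties by smaller padj, then lexicographic id) and the
#' requested number is taken; if fewer are available, all are taken with
#' a warning. The defaults reproduce a 32-taxon panel
#' (12 bacteria, 7 archaea, 7 fungi, 6 viruses).
#'
#' @param result a thresholded \linkS4class{DifferentialResult}.
#' @param sizes named panel sizes per kingdom.
#' @return data.frame taxon, kingdom, log2fc, padj (panel order).
#' @export
selectPanel <- function(result,
                        sizes = c(archaea = 7L, bacteria = 12L,
                                  fungi = 7L, virus = 6L)) {
  tb <- result@table
  if (!"significant" %in% names(tb))
    stop("apply thresholds before selecting a panel")
  sig <- tb[tb$significant, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant taxa to select from")
  panel <- do.call(rbind, lapply(names(sizes), function(k) {
    sk <- sig[sig$kingdom == k, , drop = FALSE]
    sk <- sk[order(-abs(sk$log2fc), sk$padj, sk$taxon), , drop = FALSE]
    want <- sizes[[k]]
    if (nrow(sk) < want)
      warning(sprintf("only %d significant %s taxa available (wanted %d)",
                      nrow(sk), k, want))
    utils::head(sk, want)
  }))
  rownames(panel) <- NULL
  panel[, c("taxon", "kingdom", "log2fc", "padj")]
}

#' One-call differential stage
#'
#' Splits samples 70/30 stratified by subtype, runs the NB Wald test on
#' the training samples, applies thresholds and selects the panel.
#'
#' @param table MultiKingdomTable of counts.
#' @param labels subtype factor named by sample id.
#' @param fraction training fraction.
#' @param alpha adjusted-p cutoff.
#' @param thresholds per-kingdom |log2FC| cutoffs.
#' @param sizes panel sizes per kingdom.
#' @param seed RNG seed for the split.
#' @return list(split, result, panel).
#' @export
runDifferential <- function(table, labels, fraction = 0.7, alpha = 0.05,
                            thresholds = defaultLfcThresholds(),
                            sizes = c(archaea = 7L, bacteria = 12L,
                                      fungi = 7L, virus = 6L),
                            seed = 1L) {
  split <- stratifiedSplit(labels, fraction, seed)
  pl <- .poolAssays(table)
  counts <- pl$pooled[split$train, , drop = FALSE]
  kingdoms <- structure(pl$split, names = colnames(pl$pooled))
  res <- nbWald(counts, labels[split$train], kingdoms = kingdoms)
  res <- applyThresholds(res, alpha = alpha, thresholds = thresholds)
  sizes <- sizes[names(sizes) %in% kingdomNames(table)]
  panel <- selectPanel(res, sizes = sizes)
  list(split = split, result = res, panel = panel)
}
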