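#' @import methods
NULL

KINGDOMS <- c("bacteria", "archaea", "fungi", "virus")

#' MultiKingdomTable: aligned per-kingdom abundance matrices
#'
#' Container for per-kingdom abundance matrices (samples in rows, taxa in
#' columns) over one shared, identically ordered sample set. The same class
#' carries raw counts, relative abundances and Hellinger-transformed values;
#' the \code{type} slot records which, and validity enforces integer counts
#' only for \code{type = "counts"}.
#'
#' @slot assays named list of numeric matrices, one per kingdom
#'   (subset of bacteria/archaea/fungi/virus), each samples x taxa with
#'   rownames = sample ids and colnames = taxon ids.
#' @slot type one of "counts", "relative", "hellinger".
#' @slot rank taxonomic rank tag ("species" or "genus").
#' @export
setClass("MultiKingdomTable",
  representation(assays = "list", type = "character", rank = "character"),
  prototype(assays = list(), type = "counts", rank = "species")
)

setValidity("MultiKingdomTable", function(object) {
  msgs <- character()
  a <- object@assays
  if (length(a) == 0L) return("at least one kingdom assay is required")
  if (is.null(names(a)) || any(!names(a) %in% KINGDOMS))
    msgs <- c(msgs, sprintf("assay names must be in {%s}",
                            paste(KINGDOMS, collapse = ", ")))
  if (anyDuplicated(names(a)))
    msgs <- c(msgs, "duplicate kingdom assays")
  if (!object@type %in% c("counts", "relative", "hellinger"))
    msgs <- c(msgs, "type must be counts, relative or hellinger")
  ref <- rownames(a[[1L]])
  for (k in names(a)) {
    m <- a[[k]]
    if (!is.matrix(m) || !is.numeric(m)) {
      msgs <- c(msgs, sprintf("%s: assay must be a numeric matrix", k)); next
    }
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msgs <- c(msgs, sprintf("%s: dimnames required", k))
    if (!identical(rownames(m), ref))
      msgs <- c(msgs, sprintf("%s: sample ordering differs from %s",
                              k, names(a)[1L]))
    if (anyDuplicated(colnames(m)))
      msgs <- c(msgs, sprintf("%s: duplicate taxon ids", k))
    if (anyNA(m) || any(m < 0))
      msgs <- c(msgs, sprintf("%s: values must be non-negative and non-missing", k))
    if (object@type == "counts" && any(abs(m - round(m)) > 1e-8))
      msgs <- c(msgs, sprintf("%s: counts must be integers", k))
  }
  if (anyDuplicated(ref)) msgs <- c(msgs, "duplicate sample ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultiKingdomTable
#'
#' @param assays named list of samples x taxa matrices (names are kingdoms).
#' @param type value type stored in the matrices.
#' @param rank taxonomic rank of the columns.
#' @return A \linkS4class{MultiKingdomTable}.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("b", 1:4)))
#' MultiKingdomTable(list(bacteria = m))
#' @export
MultiKingdomTable <- function(assays, type = "counts", rank = "species") {
  assays <- assays[order(match(names(assays), KINGDOMS))]
  new("MultiKingdomTable", assays = assays, type = type, rank = rank)
}

setMethod("show", "MultiKingdomTable", function(object) {
  cat(sprintf("MultiKingdomTable (%s, %s level)\n", object@type, object@rank))
  cat(sprintf("  %d samples; taxa: %s\n", nSamples(object),
              paste(sprintf("%s=%d", names(object@assays),
                            vapply(object@assays, ncol, 0L)), collapse = ", ")))
})

#' FusionResult: everything produced by one WSNF run
#'
#' @slot similarities named list of per-kingdom similarity matrices.
#' @slot weights named numeric kingdom weights (sum 1).
#' @slot fused fused similarity matrix (symmetric, rows sum to 1).
#' @slot silhouette data.frame with columns k, score.
#' @slot chosenK selected number of clusters.
#' @slot labels factor of subtype labels (C1, C2, ...) named by sample.
#' @slot iterations diffusion iterations actually run.
#' @export
setClass("FusionResult",
  representation(similarities = "list", weights = "numeric", fused = "matrix",
                 silhouette = "data.frame", chosenK = "integer",
                 labels = "factor", iterations = "integer"))

setValidity("FusionResult", function(object) {
  msgs <- character()
  if (length(object@labels) &&
      nlevels(droplevels(object@labels)) != object@chosenK)
    msgs <- c(msgs, "labels must take exactly chosenK distinct values")
  if (nrow(object@silhouette) &&
      any(object@silhouette$score < -1 - 1e-9 | object@silhouette$score > 1 + 1e-9))
    msgs <- c(msgs, "silhouette scores must lie in [-1, 1]")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-9)
    msgs <- c(msgs, "weights must sum to 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult: %d samples fused from %d kingdom(s) (%d iterations)\n",
              nrow(object@fused), length(object@similarities), object@iterations))
  cat(sprintf("  weights: %s\n",
              paste(sprintf("%s=%.3f", names(object@weights), object@weights),
                    collapse = ", ")))
  cat(sprintf("  chosen k = %d; subtype sizes: %s\n", object@chosenK,
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", ")))
})

#' DifferentialResult: per-taxon NB Wald tests with per-kingdom calls
#'
#' @slot table data.frame with columns taxon, kingdom, baseMean, log2fc,
#'   waldStat, p, padj, significant.
#' @slot alpha adjusted-p cutoff used for the significance call.
#' @slot lfcThresholds named numeric |log2FC| cutoff per kingdom.
#' @export
setClass("DifferentialResult",
  representation(table = "data.frame", alpha = "numeric",
                 lfcThresholds = "numeric"))

setValidity("DifferentialResult", function(object) {
  tb <- object@table
  need <- c("taxon", "kingdom", "log2fc", "p")
  if (!all(need %in% names(tb)))
    return(sprintf("table must contain columns %s", paste(need, collapse = ", ")))
  if ("padj" %in% names(tb) && any(tb$padj < tb$p - 1e-12, na.rm = TRUE))
    return("padj must be >= p")
  TRUE
})

setMethod("show", "DifferentialResult", function(object) {
  tb <- object@table
  cat(sprintf("DifferentialResult: %d taxa tested", nrow(tb)))
  if ("significant" %in% names(tb))
    cat(sprintf("; %d significant (padj < %.3g + per-kingdom |log2FC|)",
                sum(tb$significant), object@alpha))
  cat("\n")
  if ("significant" %in% names(tb) && any(tb$significant)) {
    s <- table(tb$kingdom[tb$significant])
    cat("  per kingdom:", paste(sprintf("%s=%d", names(s), s), collapse = ", "), "\n")
  }
})

#' SparccResult: compositionally corrected correlations
#'
#' @slot rho symmetric correlation matrix in [-1, 1], unit diagonal.
#' @slot omega inferred basis variances per taxon.
#' @slot p bootstrap p-value matrix (NA diagonal) or empty matrix.
#' @slot padj BH-adjusted p (upper triangle adjusted, mirrored).
#' @slot nBootstrap number of bootstrap null iterations used.
#' @slot seed RNG seed used for the bootstrap.
#' @export
setClass("SparccResult",
  representation(rho = "matrix", omega = "numeric", p = "matrix",
                 padj = "matrix", nBootstrap = "integer", seed = "integer"))

setValidity("SparccResult", function(object) {
  msgs <- character()
  r <- object@rho
  if (max(abs(r - t(r))) > 1e-9) msgs <- c(msgs, "rho must be symmetric")
  if (any(abs(r) > 1 + 1e-9)) msgs <- c(msgs, "|rho| must be <= 1")
  if (length(object@p) && length(object@padj) &&
      any(object@padj < object@p - 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "padj must be >= p")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SparccResult", function(object) {
  cat(sprintf("SparccResult: %d taxa", nrow(object@rho)))
  if (length(object@p))
    cat(sprintf("; bootstrap p-values from %d iterations", object@nBootstrap))
  cat("\n")
})

#' CooccurrenceNetwork: significant SparCC edges
#'
#' @slot nodes data.frame taxon, kingdom, degree.
#' @slot edges data.frame from, to, rho, sign.
#' @slot alpha adjusted-p threshold that defined the edges.
#' @export
setClass("CooccurrenceNetwork",
  representation(nodes = "data.frame", edges = "data.frame", alpha = "numeric"))

setValidity("CooccurrenceNetwork", function(object) {
  e <- object@edges
  if (nrow(e) && any(e$from == e$to)) return("self edges are not allowed")
  deg <- tabulate(factor(c(e$from, e$to), levels = object@nodes$taxon),
                  nbins = nrow(object@nodes))
  if (nrow(object@nodes) && !all(deg == object@nodes$degree))
    return("node degrees inconsistent with edge list")
  TRUE
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf("CooccurrenceNetwork: %d nodes, %d edges (padj < %.3g)\n",
              nrow(object@nodes), nrow(object@edges), object@alpha))
})
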