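# Co-occurrence network construction and graph export.

#' Build the significant co-occurrence network
#'
#' An edge joins two taxa iff the BH-adjusted bootstrap p-value of their
#' SparCC correlation is below alpha; the correlation is carried as the
#' edge weight with its sign.
#'
#' @param result a \linkS4class{SparccResult} with bootstrap p-values.
#' @param kingdoms kingdom per taxon (named by taxon or in rho order).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return A \linkS4class{CooccurrenceNetwork}.
#' @export
buildNetwork <- function(result, kingdoms, alpha = 0.05) {
  rho <- result@rho
  padj <- result@padj
  if (!length(padj)) stop("run sparccBootstrap before building the network")
  if (!is.null(names(kingdoms)) && !is.null(rownames(rho)))
    kingdoms <- kingdoms[rownames(rho)]
  taxa <- rownames(rho)
  idx <- which(upper.tri(rho) & padj < alpha, arr.ind = TRUE)
  edges <- data.frame(from = taxa[idx[, 1L]], to = taxa[idx[, 2L]],
                      rho = rho[idx],
                      sign = ifelse(rho[idx] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) warning("no significant co-occurrence edges")
  deg <- tabulate(factor(c(edges$from, edges$to), levels = taxa),
                  nbins = length(taxa))
  nodes <- data.frame(taxon = taxa, kingdom = unname(kingdoms),
                      degree = deg, stringsAsFactors = FALSE)
  new("CooccurrenceNetwork", nodes = nodes, edges = edges, alpha = alpha)
}

#' Per-kingdom core taxa (maximum degree)
#'
#' @param network a \linkS4class{CooccurrenceNetwork}.
#' @return data.frame kingdom, taxon, degree; one row per kingdom with
#'   at least one node (lexicographic tie-break).
#' @export
coreTaxa <- function(network) {
  nd <- network@nodes
  do.call(rbind, lapply(split(nd, nd$kingdom), function(df) {
    df <- df[order(-df$degree, df$taxon), , drop = FALSE]
    data.frame(kingdom = df$kingdom[1L], taxon = df$taxon[1L],
               degree = df$degree[1L], row.names = NULL)
  }))
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param network a \linkS4class{CooccurrenceNetwork}.
#' @return An undirected igraph with kingdom/degree vertex attributes and
#'   rho/sign edge attributes.
#' @export
asIgraph <- function(network) {
  igraph::graph_from_data_frame(network@edges, directed = FALSE,
                                vertices = network@nodes)
}

#' Write network exports (GraphML and GEXF)
#'
#' @param network a \linkS4class{CooccurrenceNetwork}.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeNetworkFiles <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gml <- file.path(dir, "network.graphml")
  igraph::write_graph(asIgraph(network), gml, format = "graphml")
  gexf <- file.path(dir, "network.gexf")
  .writeGexf(network, gexf)
  edges <- file.path(dir, "edges.tsv")
  utils::write.table(network@edges, edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml = gml, gexf = gexf, edges = edges))
}

# Minimal GEXF 1.2 writer (node kingdom attribute, edge weight = |rho|).
.writeGexf <- function(network, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  nd <- network@nodes; ed <- network@edges
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('<graph defaultedgetype="undirected">')
  w('<attributes class="node"><attribute id="0" title="kingdom" type="string"/></attributes>')
  w('<nodes>')
  for (i in seq_len(nrow(nd)))
    w('<node id="%s" label="%s"><attvalues><attvalue for="0" value="%s"/></attvalues></node>',
      esc(nd$taxon[i]), esc(nd$taxon[i]), esc(nd$kingdom[i]))
  w('</nodes>')
  w('<edges>')
  for (i in seq_len(nrow(ed)))
    w('<edge id="%d" source="%s" target="%s" weight="%.6f"/>',
      i, esc(ed$from[i]), esc(ed$to[i]), abs(ed$rho[i]))
  w('</edges>')
  w('</graph>')
  w('</gexf>')
  invisible(path)
}
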