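# Table IO and preprocessing: prevalence/richness filters, rarefaction,
# relative abundance, Hellinger.

#' Validate and normalize a sample metadata table
#'
#' @param df data.frame with at least a sample_id column; recognized
#'   columns: cohort, response (R/NR/unknown), pfs_gt6, os_months,
#'   death_event, plus arbitrary covariates.
#' @return The validated data.frame.
#' @export
sampleMetadata <- function(df) {
  stopifnot(is.data.frame(df), "sample_id" %in% names(df))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if ("response" %in% names(df)) {
    bad <- setdiff(unique(df$response), c("R", "NR", "unknown", NA))
    if (length(bad)) stop("response must be R, NR or unknown; got: ",
                          paste(bad, collapse = ", "))
  }
  if ("os_months" %in% names(df) && any(df$os_months < 0, na.rm = TRUE))
    stop("os_months must be non-negative")
  if ("death_event" %in% names(df)) {
    if (!all(df$death_event %in% c(0L, 1L, NA)))
      stop("death_event must be 0/1 or missing")
    if ("os_months" %in% names(df) &&
        any(!is.na(df$death_event) & is.na(df$os_months)))
      stop("os_months must be present whenever death_event is present")
  }
  df
}

.readKingdomTSV <- function(path, kingdom) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop(path, ": expected taxon id column plus samples")
  taxa <- as.character(raw[[1L]])
  raw <- raw[, -1L, drop = FALSE]
  if (names(raw)[1L] == "kingdom") raw <- raw[, -1L, drop = FALSE]
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stop(sprintf("%s: malformed numeric cell at taxon '%s', sample '%s'",
                   path, taxa[bad[1L]], names(raw)[j]))
    neg <- which(num < 0)
    if (length(neg))
      stop(sprintf("%s: negative count at taxon '%s', sample '%s'",
                   path, taxa[neg[1L]], names(raw)[j]))
    raw[[j]] <- num
  }
  m <- t(as.matrix(raw))           # file is taxa x samples; we store samples x taxa
  colnames(m) <- taxa
  m
}

#' Read per-kingdom abundance TSVs plus metadata
#'
#' Files are taxa-by-sample TSVs: first column taxon id, optional second
#' column kingdom, remaining columns samples. Sample sets are intersected
#' across all kingdoms and the metadata; dropped ids are reported in a
#' warning.
#'
#' @param paths named character vector of file paths (names are kingdoms).
#' @param metadataPath path to the metadata TSV keyed by sample_id.
#' @param rank taxonomic rank tag to attach.
#' @return list(table = MultiKingdomTable, metadata = data.frame).
#' @export
readTables <- function(paths, metadataPath, rank = "species") {
  stopifnot(length(paths) >= 1L, !is.null(names(paths)))
  mats <- Map(.readKingdomTSV, paths, names(paths))
  md <- sampleMetadata(utils::read.delim(metadataPath, check.names = FALSE,
                                         stringsAsFactors = FALSE))
  sets <- c(lapply(mats, rownames), list(md$sample_id))
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0L) stop("no samples shared across tables and metadata")
  dropped <- setdiff(unique(unlist(sets)), shared)
  if (length(dropped))
    warning("dropped samples absent from some input: ",
            paste(sort(dropped), collapse = ", "))
  assays <- lapply(mats, function(m) m[shared, , drop = FALSE])
  list(table = MultiKingdomTable(assays, type = "counts", rank = rank),
       metadata = md[match(shared, md$sample_id), , drop = FALSE])
}

#' Write a MultiKingdomTable (and optional metadata) to TSV files
#'
#' @param table a MultiKingdomTable.
#' @param dir output directory (created if needed).
#' @param metadata optional metadata data.frame.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeTables <- function(table, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(kingdomNames(table), function(k) {
    m <- kingdomMatrix(table, k)
    df <- data.frame(taxon_id = colnames(m), kingdom = k,
                     t(m), check.names = FALSE)
    p <- file.path(dir, paste0(k, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1L))
  if (!is.null(metadata)) {
    p <- file.path(dir, "metadata.tsv")
    utils::write.table(metadata, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, metadata = p)
  }
  invisible(paths)
}

#' Keep taxa present in at least a fraction of samples
#'
#' A taxon is retained iff it has a nonzero value in at least
#' \code{ceiling(minPrevalence * nSamples)} samples; applied within each
#' kingdom independently.
#'
#' @param table a MultiKingdomTable.
#' @param minPrevalence fraction in (0, 1]; default 0.10.
#' @return Filtered MultiKingdomTable.
#' @export
filterTaxaByPrevalence <- function(table, minPrevalence = 0.10) {
  stopifnot(minPrevalence > 0, minPrevalence <= 1)
  need <- ceiling(minPrevalence * nSamples(table))
  assays <- lapply(kingdomNames(table), function(k) {
    m <- kingdomMatrix(table, k)
    keep <- colSums(m > 0) >= need
    if (!any(keep))
      message("prevalence filter removed every ", k, " taxon")
    m[, keep, drop = FALSE]
  })
  names(assays) <- kingdomNames(table)
  MultiKingdomTable(assays, type = table@type, rank = table@rank)
}

#' Keep samples whose richness exceeds a cutoff
#'
#' Richness is the number of nonzero taxa summed over all kingdoms; a
#' sample is retained iff richness is strictly greater than
#' \code{minSpecies}.
#'
#' @param table a MultiKingdomTable.
#' @param minSpecies integer cutoff (default 300, the cohort-scale screen).
#' @return Filtered MultiKingdomTable.
#' @export
filterSamplesByRichness <- function(table, minSpecies = 300L) {
  stopifnot(minSpecies >= 0)
  pooled <- .poolAssays(table)$pooled
  rich <- rowSums(pooled > 0)
  keep <- rich > minSpecies
  if (!any(keep)) stop("richness filter removed every sample")
  assays <- lapply(kingdomNames(table), function(k)
    kingdomMatrix(table, k)[keep, , drop = FALSE])
  names(assays) <- kingdomNames(table)
  MultiKingdomTable(assays, type = table@type, rank = table@rank)
}

#' Rarefy samples to a common sequencing depth
#'
#' All kingdoms are pooled per sample and a subsample of exactly
#' \code{depth} reads is drawn without replacement (vegan's rrarefy);
#' counts are then split back into their kingdoms. Samples whose pooled
#' total is below the depth are dropped with a message.
#'
#' @param table a MultiKingdomTable of counts.
#' @param depth target reads per sample.
#' @param seed RNG seed.
#' @return Rarefied MultiKingdomTable with per-sample totals == depth.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(table@type == "counts", depth >= 1)
  pl <- .poolAssays(table)
  totals <- rowSums(pl$pooled)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  if (any(!keep))
    message("rarefy: dropped ", sum(!keep), " sample(s) below depth ", depth,
            ": ", paste(rownames(pl$pooled)[!keep], collapse = ", "))
  sub <- pl$pooled[keep, , drop = FALSE]
  rare <- .withSeed(.substream(seed, "rarefy"), withCallingHandlers(
    vegan::rrarefy(sub, sample = depth),
    warning = function(w) {
      # vegan's "should be used for observed counts" heuristic is benign here
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  assays <- .unpoolAssays(rare, pl$split, table)
  assays <- lapply(kingdomNames(table), function(k) assays[[k]])
  names(assays) <- kingdomNames(table)
  MultiKingdomTable(assays, type = "counts", rank = table@rank)
}

#' Convert counts to relative abundances
#'
#' @param table a MultiKingdomTable.
#' @param scope "per_kingdom" (each kingdom's sample vector sums to 1;
#'   the default used for fusion inputs) or "global" (one normalization
#'   across all kingdoms per sample).
#' @return MultiKingdomTable with type "relative".
#' @export
toRelativeAbundance <- function(table, scope = c("per_kingdom", "global")) {
  scope <- match.arg(scope)
  if (scope == "per_kingdom") {
    assays <- lapply(kingdomNames(table), function(k) {
      m <- kingdomMatrix(table, k)
      tot <- rowSums(m)
      tot[tot == 0] <- 1  # all-zero samples stay all-zero
      m / tot
    })
  } else {
    pl <- .poolAssays(table)
    tot <- rowSums(pl$pooled)
    tot[tot == 0] <- 1
    rel <- pl$pooled / tot
    assays <- .unpoolAssays(rel, pl$split, table)
  }
  names(assays) <- kingdomNames(table)
  MultiKingdomTable(assays, type = "relative", rank = table@rank)
}

#' Hellinger transformation
#'
#' Elementwise square root of relative abundances; Euclidean distance on
#' the result equals the Hellinger distance between samples.
#'
#' @param rel a MultiKingdomTable of relative abundances, or a plain
#'   non-negative matrix.
#' @return Object of the same shape with square-rooted values.
#' @export
hellinger <- function(rel) {
  tr <- function(m) {
    if (any(m < 0)) stop("hellinger: negative input")
    sqrt(m)
  }
  if (is(rel, "MultiKingdomTable")) {
    assays <- lapply(kingdomNames(rel), function(k) tr(kingdomMatrix(rel, k)))
    names(assays) <- kingdomNames(rel)
    MultiKingdomTable(assays, type = "hellinger", rank = rel@rank)
  } else tr(rel)
}
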