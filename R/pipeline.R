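# End-to-end orchestration: simulate -> preprocess -> cluster -> diversity
# -> outcomes -> differential -> predict -> network, with one seed policy,
# TSV outputs per stage and a hashed run manifest.

PIPELINE_STAGES <- c("simulate", "preprocess", "cluster", "diversity",
                     "outcomes", "differential", "predict", "network")

#' Pipeline configuration
#'
#' Every stage parameter in one place; each has a sensible desk-scale
#' default matched to the synthetic generator. All randomness derives
#' from \code{seed} through fixed per-stage substreams.
#'
#' @param outDir output directory.
#' @param seed global seed.
#' @param stages named logical vector of stage toggles.
#' @param simulation a \code{\link{simulationConfig}}.
#' @param depth rarefaction depth (reads/sample).
#' @param minPrevalence taxon prevalence filter fraction.
#' @param minSpecies sample richness cutoff (strictly greater than).
#' @param fusion a \code{\link{fusionConfig}}.
#' @param nPerm PERMANOVA permutations.
#' @param fraction training fraction of the differential split.
#' @param alpha adjusted-p cutoff (differential and network).
#' @param thresholds per-kingdom |log2FC| cutoffs.
#' @param panelSizes per-kingdom panel sizes.
#' @param families classifier families.
#' @param nFolds cross-validation folds.
#' @param nBoot SparCC bootstrap iterations.
#' @param strongThreshold |rho| cutoff of the strong-edge summary.
#' @param networkMaxTaxa cap on taxa entering SparCC (top |log2fc|).
#' @return list of class PipelineConfig.
#' @export
pipelineConfig <- function(outDir = tempfile("kingdomfuse_"),
                           seed = 1L,
                           stages = stats::setNames(rep(TRUE, 8L),
                                                    PIPELINE_STAGES),
                           simulation = simulationConfig(seed = seed),
                           depth = 5e4,
                           minPrevalence = 0.10,
                           minSpecies = 50L,
                           fusion = fusionConfig(seed = seed),
                           nPerm = 999L,
                           fraction = 0.7,
                           alpha = 0.05,
                           thresholds = defaultLfcThresholds(),
                           panelSizes = c(archaea = 7L, bacteria = 12L,
                                          fungi = 7L, virus = 6L),
                           families = c("rf", "svm"),
                           nFolds = 10L,
                           nBoot = 500L,
                           strongThreshold = 0.5,
                           networkMaxTaxa = 40L) {
  toggles <- stats::setNames(rep(TRUE, length(PIPELINE_STAGES)),
                             PIPELINE_STAGES)
  toggles[names(stages)] <- stages
  structure(list(outDir = outDir, seed = as.integer(seed), stages = toggles,
                 simulation = simulation, depth = depth,
                 minPrevalence = minPrevalence, minSpecies = minSpecies,
                 fusion = fusion, nPerm = nPerm, fraction = fraction,
                 alpha = alpha, thresholds = thresholds,
                 panelSizes = panelSizes, families = families,
                 nFolds = nFolds, nBoot = nBoot,
                 strongThreshold = strongThreshold,
                 networkMaxTaxa = networkMaxTaxa),
            class = "PipelineConfig")
}

#' Read a plain-text key=value pipeline configuration
#'
#' Recognized keys are the scalar arguments of
#' \code{\link{pipelineConfig}} (outDir, seed, depth, minPrevalence,
#' minSpecies, nPerm, fraction, alpha, nFolds, nBoot, strongThreshold,
#' networkMaxTaxa) plus \code{stages} as a comma-separated list of the
#' stages to enable. Lines starting with '#' are ignored.
#'
#' @param path config file path.
#' @return A PipelineConfig.
#' @export
readPipelineConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  args <- list()
  numKeys <- c("seed", "depth", "minPrevalence", "minSpecies", "nPerm",
               "fraction", "alpha", "nFolds", "nBoot", "strongThreshold",
               "networkMaxTaxa")
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k == "outDir") args$outDir <- vals[i]
    else if (k == "stages") {
      on <- trimws(strsplit(vals[i], ",")[[1L]])
      args$stages <- stats::setNames(PIPELINE_STAGES %in% on, PIPELINE_STAGES)
    } else if (k %in% numKeys) args[[k]] <- as.numeric(vals[i])
    else warning("ignoring unknown config key: ", k)
  }
  do.call(pipelineConfig, args)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeMatrixTSV <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  .writeTSV(df, path)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs as
#' TSV under the configured directory, and returns (and writes) a run
#' manifest recording parameters, seeds and output file hashes. A stage
#' failure aborts with the failing stage named; earlier outputs are
#' retained.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the manifest data.frame and the key
#'   in-memory results (table, metadata, truth, fusion, differential,
#'   models, networks).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(config$outDir, "run.log"), "w")
  on.exit(close(logCon))
  logMsg <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    writeLines(msg, logCon)
    message(msg)
  }
  manifest <- list()
  state <- new.env(parent = emptyenv())
  record <- function(stage, outputs, params = "") {
    hashes <- if (length(outputs)) unname(tools::md5sum(outputs)) else character(0)
    manifest[[stage]] <<- data.frame(
      stage = stage, seed = config$seed, params = params,
      outputs = paste(basename(outputs), collapse = ";"),
      md5 = paste(hashes, collapse = ";"), stringsAsFactors = FALSE)
  }
  runStage <- function(stage, fn) {
    if (!config$stages[[stage]]) return(invisible(NULL))
    logMsg("stage ", stage, " started")
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) {
                     stop("pipeline stage '", stage, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    logMsg("stage ", stage, " done")
  }

  runStage("simulate", function() {
    sim <- simulateCounts(config$simulation)
    md <- simulateMetadata(sim$truth$subtype, config$simulation)
    state$table <- sim$table
    state$truth <- sim$truth
    state$metadata <- md
    paths <- writeTables(sim$table, config$outDir, metadata = md)
    truthPath <- .writeTSV(
      data.frame(sample_id = names(sim$truth$subtype),
                 subtype = as.character(sim$truth$subtype)),
      file.path(config$outDir, "truth_labels.tsv"))
    sigPath <- if (!is.null(sim$truth$signalTaxa))
      .writeTSV(sim$truth$signalTaxa,
                file.path(config$outDir, "truth_signal_taxa.tsv"))
    record("simulate", c(unname(paths), truthPath, sigPath),
           sprintf("depth=%g", config$simulation$sequencingDepth))
  })

  runStage("preprocess", function() {
    tb <- rarefy(state$table, depth = config$depth, seed = config$seed)
    tb <- filterSamplesByRichness(tb, minSpecies = config$minSpecies)
    tb <- filterTaxaByPrevalence(tb, minPrevalence = config$minPrevalence)
    state$table <- tb
    keep <- sampleIDs(tb)
    state$metadata <- state$metadata[state$metadata$sample_id %in% keep, ]
    state$truth$subtype <- state$truth$subtype[keep]
    dir <- file.path(config$outDir, "preprocessed")
    paths <- writeTables(tb, dir)
    record("preprocess", unname(paths),
           sprintf("depth=%g;minPrevalence=%g;minSpecies=%d",
                   config$depth, config$minPrevalence, config$minSpecies))
  })

  runStage("cluster", function() {
    fr <- runWSNF(state$table, config$fusion)
    state$fusion <- fr
    labPath <- .writeTSV(data.frame(sample_id = names(subtypeLabels(fr)),
                                    subtype = as.character(subtypeLabels(fr))),
                         file.path(config$outDir, "subtype_labels.tsv"))
    silPath <- .writeTSV(silhouetteTrace(fr),
                         file.path(config$outDir, "silhouette.tsv"))
    fusedPath <- .writeMatrixTSV(fusedMatrix(fr),
                                 file.path(config$outDir, "fused_matrix.tsv"))
    record("cluster", c(labPath, silPath, fusedPath),
           sprintf("chosenK=%d", fr@chosenK))
  })

  runStage("diversity", function() {
    labels <- subtypeLabels(state$fusion)
    alpha <- alphaDiversity(state$table, scope = "total")
    alphaTests <- compareAlphaDiversity(alpha, labels)
    perm <- lapply(c("bray_curtis", "jaccard"), function(met) {
      D <- betaDistance(state$table, metric = met)
      pr <- permanova(D, labels, nPerm = config$nPerm, seed = config$seed)
      data.frame(metric = met, pseudoF = pr$pseudoF, p = pr$p,
                 nPerm = pr$nPerm)
    })
    paths <- c(.writeTSV(alpha, file.path(config$outDir, "alpha_diversity.tsv")),
               .writeTSV(alphaTests, file.path(config$outDir, "alpha_tests.tsv")),
               .writeTSV(do.call(rbind, perm),
                         file.path(config$outDir, "permanova.tsv")))
    record("diversity", paths, sprintf("nPerm=%d", config$nPerm))
  })

  runStage("outcomes", function() {
    labels <- subtypeLabels(state$fusion)
    md <- state$metadata
    ct <- lapply(c("response", "pfs_gt6"), function(o) {
      r <- contingencyTest(md, o, labels)
      data.frame(outcome = o, chi2 = r$chi2, p = r$p)
    })
    g <- labels[md$sample_id]
    km <- kmEstimate(md$os_months, md$death_event, g)
    kmDf <- do.call(rbind, Map(function(curve, nm)
      if (nrow(curve)) cbind(group = nm, curve) else NULL, km, names(km)))
    lr <- logrankTest(md$os_months, md$death_event, g)
    paths <- c(.writeTSV(do.call(rbind, ct),
                         file.path(config$outDir, "contingency_tests.tsv")),
               .writeTSV(kmDf, file.path(config$outDir, "km_curves.tsv")),
               .writeTSV(data.frame(chi2 = lr$chi2, p = lr$p),
                         file.path(config$outDir, "logrank.tsv")))
    record("outcomes", paths)
  })

  runStage("differential", function() {
    labels <- subtypeLabels(state$fusion)
    diff <- runDifferential(state$table, labels, fraction = config$fraction,
                            alpha = config$alpha,
                            thresholds = config$thresholds,
                            sizes = config$panelSizes, seed = config$seed)
    state$differential <- diff
    paths <- c(.writeTSV(resultTable(diff$result),
                         file.path(config$outDir, "differential.tsv")),
               .writeTSV(diff$panel, file.path(config$outDir, "panel.tsv")),
               .writeTSV(data.frame(set = c(rep("train", length(diff$split$train)),
                                            rep("test", length(diff$split$test))),
                                    sample_id = c(diff$split$train,
                                                  diff$split$test)),
                         file.path(config$outDir, "split.tsv")))
    record("differential", paths,
           sprintf("fraction=%g;alpha=%g", config$fraction, config$alpha))
  })

  runStage("predict", function() {
    labels <- subtypeLabels(state$fusion)
    diff <- state$differential
    cmp <- comparePanels(state$table, diff$panel, labels, diff$split,
                         families = config$families, nFolds = config$nFolds,
                         seed = config$seed)
    state$models <- cmp
    rocDf <- do.call(rbind, Map(function(df, nm) cbind(model = nm, df),
                                cmp$roc, names(cmp$roc)))
    paths <- c(.writeTSV(cmp$reports, file.path(config$outDir, "model_auc.tsv")),
               .writeTSV(rocDf, file.path(config$outDir, "roc_points.tsv")),
               .writeTSV(cmp$summary, file.path(config$outDir,
                                                "panel_comparison.tsv")))
    record("predict", paths, sprintf("nFolds=%d", config$nFolds))
  })

  runStage("network", function() {
    labels <- subtypeLabels(state$fusion)
    tb <- resultTable(state$differential$result)
    sig <- tb[tb$significant, , drop = FALSE]
    sig <- sig[order(-abs(sig$log2fc)), , drop = FALSE]
    taxa <- utils::head(sig$taxon, config$networkMaxTaxa)
    if (length(taxa) < 4L) stop("fewer than 4 significant taxa for SparCC")
    pooled <- .poolAssays(state$table)$pooled[, taxa, drop = FALSE]
    kingdoms <- structure(sig$kingdom[match(taxa, sig$taxon)], names = taxa)
    paths <- character(0)
    state$networks <- list()
    for (g in levels(labels)) {
      counts <- pooled[names(labels)[labels == g], , drop = FALSE]
      fit <- sparcc(counts)
      fit <- sparccBootstrap(counts, fit, nBoot = config$nBoot,
                             seed = config$seed)
      net <- suppressWarnings(buildNetwork(fit, kingdoms,
                                           alpha = config$alpha))
      sub <- file.path(config$outDir, paste0("network_", g))
      paths <- c(paths,
                 unname(writeNetworkFiles(net, sub)),
                 .writeMatrixTSV(sparccRho(fit),
                                 file.path(sub, "rho.tsv")),
                 .writeMatrixTSV(adjustedP(fit),
                                 file.path(sub, "padj.tsv")),
                 .writeTSV(strongEdgeSummary(sparccRho(fit), kingdoms,
                                             config$strongThreshold),
                           file.path(sub, "strong_edges.tsv")))
      state$networks[[g]] <- net
    }
    record("network", paths,
           sprintf("nBoot=%d;strong=%g", config$nBoot, config$strongThreshold))
  })

  manifestDf <- do.call(rbind, manifest[PIPELINE_STAGES[
    PIPELINE_STAGES %in% names(manifest)]])
  rownames(manifestDf) <- NULL
  .writeTSV(manifestDf, file.path(config$outDir, "manifest.tsv"))
  logMsg("pipeline complete: ", nrow(manifestDf), " stage(s)")
  invisible(list(manifest = manifestDf,
                 table = state$table,
                 metadata = state$metadata,
                 truth = state$truth,
                 fusion = state$fusion,
                 differential = state$differential,
                 models = state$models,
                 networks = state$networks))
}
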