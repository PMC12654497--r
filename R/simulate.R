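#' Simulation configuration for synthetic multi-kingdom cohorts
#'
#' Bundles every knob of the synthetic-data generator. The defaults are a
#' desk-scale cohort that preserves the kingdom-size ordering seen in real
#' gut metagenomes (hundreds of bacteria down to tens of viruses), two
#' latent subtypes with per-kingdom abundance shifts, response and PFS
#' probabilities that differ by subtype, and exponential survival with a
#' subtype hazard ratio of 2 under light censoring.
#'
#' @param nSamplesPerSubtype integer pair: samples in subtype C1 and C2.
#' @param taxaPerKingdom named integer vector of taxa per kingdom.
#' @param nSignalTaxa named integer vector: differentially abundant taxa
#'   planted per kingdom (each <= the kingdom's taxon count).
#' @param signalLog2FC named positive vector: planted |log2 fold change| of
#'   the signal taxa (subtype C2 relative to C1; sign drawn per taxon).
#' @param sequencingDepth reads drawn per sample (single multinomial over
#'   all kingdoms).
#' @param zeroInflation probability that a taxon is structurally absent
#'   from a sample before counting.
#' @param baseAbundanceSD natural-log standard deviation of the latent
#'   per-sample abundance noise.
#' @param responseProb named vector (C1, C2): P(responder).
#' @param hazardRate named vector (C1, C2): exponential death hazard per
#'   month; mean OS = 1/rate.
#' @param censorRate exponential censoring hazard per month.
#' @param plantedCorrelations data.frame with columns taxonA, taxonB, rho
#'   (|rho| < 1) naming kingdom-prefixed taxa (e.g. "bacteria|b1"), or NULL.
#' @param seed integer seed; all stages derive fixed substreams from it.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nSamplesPerSubtype = c(60L, 60L),
                             taxaPerKingdom = c(bacteria = 200L, archaea = 40L,
                                                fungi = 30L, virus = 20L),
                             nSignalTaxa = c(bacteria = 80L, archaea = 16L,
                                             fungi = 12L, virus = 8L),
                             signalLog2FC = c(bacteria = 2.5, archaea = 2.5,
                                              fungi = 2.5, virus = 2.5),
                             sequencingDepth = 1e5,
                             zeroInflation = 0.3,
                             baseAbundanceSD = 1,
                             responseProb = c(C1 = 0.25, C2 = 0.55),
                             hazardRate = c(C1 = 0.05, C2 = 0.025),
                             censorRate = 1 / 60,
                             plantedCorrelations = NULL,
                             seed = 1L) {
  stopifnot(length(nSamplesPerSubtype) == 2L, all(nSamplesPerSubtype >= 2L),
            all(taxaPerKingdom >= 1L), sequencingDepth >= 1,
            zeroInflation >= 0, zeroInflation <= 1, baseAbundanceSD > 0,
            all(responseProb >= 0), all(responseProb <= 1),
            all(hazardRate > 0), censorRate >= 0)
  kk <- names(taxaPerKingdom)
  if (is.null(kk) || any(!kk %in% KINGDOMS))
    stop("taxaPerKingdom must be named with kingdoms")
  nSignalTaxa <- nSignalTaxa[kk]
  nSignalTaxa[is.na(nSignalTaxa)] <- 0L
  names(nSignalTaxa) <- kk
  if (any(nSignalTaxa > taxaPerKingdom))
    stop("nSignalTaxa must not exceed taxaPerKingdom")
  if (!is.null(plantedCorrelations)) {
    stopifnot(is.data.frame(plantedCorrelations),
              all(c("taxonA", "taxonB", "rho") %in% names(plantedCorrelations)))
    if (any(abs(plantedCorrelations$rho) >= 1))
      stop("planted correlation targets must satisfy |rho| < 1")
    if (anyDuplicated(c(plantedCorrelations$taxonA, plantedCorrelations$taxonB)))
      stop("planted correlation pairs must be disjoint")
  }
  structure(list(nSamplesPerSubtype = as.integer(nSamplesPerSubtype),
                 taxaPerKingdom = taxaPerKingdom,
                 nSignalTaxa = nSignalTaxa,
                 signalLog2FC = signalLog2FC,
                 sequencingDepth = sequencingDepth,
                 zeroInflation = zeroInflation,
                 baseAbundanceSD = baseAbundanceSD,
                 responseProb = responseProb,
                 hazardRate = hazardRate,
                 censorRate = censorRate,
                 plantedCorrelations = plantedCorrelations,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Taxon ids: b1..bN etc., kingdom-prefixed when pooled.
.taxonIDs <- function(taxaPerKingdom) {
  lapply(seq_along(taxaPerKingdom), function(i) {
    k <- names(taxaPerKingdom)[i]
    paste0(substr(k, 1, 1), seq_len(taxaPerKingdom[i]))
  })
}

#' Simulate multi-kingdom count tables with planted subtype structure
#'
#' Each sample draws latent log-normal basis abundances per taxon. Signal
#' taxa have their latent mean shifted by \code{signalLog2FC * log(2)} in
#' subtype C2 (sign drawn per taxon and recorded in the ground truth).
#' Planted taxon pairs share a latent standard-normal factor whose loadings
#' are solved in closed form so the latent log-abundance correlation equals
#' the target rho. Zero inflation removes taxa from samples at the given
#' probability, and counts are drawn from one multinomial per sample at the
#' configured depth over all kingdoms jointly, so per-sample totals are
#' conserved exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list with elements \code{table} (a
#'   \linkS4class{MultiKingdomTable} of counts), and \code{truth}: subtype
#'   labels, the planted signal taxa with signed log2FC, the planted
#'   correlations, and the latent log-abundance matrix (pre-multinomial).
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n1 <- config$nSamplesPerSubtype[1L]; n2 <- config$nSamplesPerSubtype[2L]
  n <- n1 + n2
  tk <- config$taxaPerKingdom
  ids <- .taxonIDs(tk)
  pooledIDs <- unlist(Map(function(k, v) paste(k, v, sep = "|"), names(tk), ids))
  m <- length(pooledIDs)
  sampleIDs <- sprintf("s%03d", seq_len(n))
  subtype <- factor(rep(c("C1", "C2"), c(n1, n2)), levels = c("C1", "C2"))
  names(subtype) <- sampleIDs

  .withSeed(.substream(config$seed, "counts"), {
    # Basis log-means: spread over taxa to give a realistic rank-abundance
    # curve (sd 2 natural log units).
    basis <- rnorm(m, mean = 0, sd = 2)
    names(basis) <- pooledIDs

    # Signal taxa: sampled per kingdom, random sign, shift applied to C2.
    sigTab <- do.call(rbind, lapply(names(tk), function(k) {
      ns <- config$nSignalTaxa[[k]]
      if (ns == 0L) return(NULL)
      kIDs <- paste(k, ids[[which(names(tk) == k)]], sep = "|")
      chosen <- sample(kIDs, ns)
      data.frame(taxon = chosen, kingdom = k,
                 direction = sample(c(-1, 1), ns, replace = TRUE),
                 log2fc = config$signalLog2FC[[k]],
                 stringsAsFactors = FALSE)
    }))
    shift <- numeric(m); names(shift) <- pooledIDs
    if (!is.null(sigTab))
      shift[sigTab$taxon] <- sigTab$direction * sigTab$log2fc * log(2)

    # Latent noise with shared factors for planted pairs:
    # z = sd * (lambda * f + sqrt(1 - lambda^2) * eps), lambda_a * lambda_b = rho.
    sd0 <- config$baseAbundanceSD
    eps <- matrix(rnorm(n * m, sd = 1), n, m,
                  dimnames = list(sampleIDs, pooledIDs))
    noise <- eps
    pc <- config$plantedCorrelations
    if (!is.null(pc) && nrow(pc)) {
      bad <- setdiff(c(pc$taxonA, pc$taxonB), pooledIDs)
      if (length(bad))
        stop("planted correlation names unknown taxa: ",
             paste(bad, collapse = ", "))
      for (i in seq_len(nrow(pc))) {
        f <- rnorm(n)
        la <- sqrt(abs(pc$rho[i]))
        lb <- sign(pc$rho[i]) * la
        noise[, pc$taxonA[i]] <- la * f + sqrt(1 - la^2) * eps[, pc$taxonA[i]]
        noise[, pc$taxonB[i]] <- lb * f + sqrt(1 - lb^2) * eps[, pc$taxonB[i]]
      }
    }
    latent <- sweep(sd0 * noise, 2L, basis, "+")
    latent <- latent + outer(as.integer(subtype == "C2"), shift)

    # Zero inflation, then one multinomial per sample over all taxa.
    keep <- matrix(runif(n * m) >= config$zeroInflation, n, m)
    w <- exp(latent) * keep
    counts <- t(vapply(seq_len(n), function(i) {
      wi <- w[i, ]
      if (sum(wi) == 0) wi <- rep(1, m)  # degenerate all-zero guard
      as.numeric(rmultinom(1L, size = config$sequencingDepth, prob = wi))
    }, numeric(m)))
    dimnames(counts) <- list(sampleIDs, pooledIDs)

    split <- rep(names(tk), times = tk)
    assays <- lapply(names(tk), function(k) {
      mk <- counts[, split == k, drop = FALSE]
      colnames(mk) <- sub("^[^|]*\\|", "", colnames(mk))
      mk
    })
    names(assays) <- names(tk)

    list(table = MultiKingdomTable(assays, type = "counts"),
         truth = list(subtype = subtype,
                      signalTaxa = sigTab,
                      plantedCorrelations = pc,
                      latent = latent))
  })
}

#' Simulate per-sample outcome metadata for planted subtypes
#'
#' Response is Bernoulli with the subtype's response probability; overall
#' survival is exponential with the subtype's hazard, censored by an
#' independent exponential clock; the PFS>6-months flag is Bernoulli with
#' p = 0.75 for responders and 0.25 for non-responders (a monotone link —
#' any would do for testing).
#'
#' @param labels factor of subtype labels (C1/C2) named by sample id.
#' @param config a \code{\link{simulationConfig}}.
#' @return A metadata data.frame as accepted by \code{\link{readTables}}:
#'   sample_id, cohort, response, pfs_gt6, os_months, death_event.
#' @export
simulateMetadata <- function(labels, config) {
  stopifnot(inherits(config, "SimulationConfig"), length(labels) > 0)
  labels <- as.factor(labels)
  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  .withSeed(.substream(config$seed, "metadata"), {
    pResp <- config$responseProb[as.character(labels)]
    response <- ifelse(runif(n) < pResp, "R", "NR")
    pPFS <- ifelse(response == "R", 0.75, 0.25)
    pfs <- runif(n) < pPFS
    haz <- config$hazardRate[as.character(labels)]
    tDeath <- rexp(n, rate = haz)
    tCens <- if (config$censorRate > 0) rexp(n, rate = config$censorRate)
             else rep(Inf, n)
    os <- pmin(tDeath, tCens)
    death <- as.integer(tDeath <= tCens)
    data.frame(sample_id = ids, cohort = "synthetic",
               response = response, pfs_gt6 = pfs,
               os_months = os, death_event = death,
               stringsAsFactors = FALSE)
  })
}
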