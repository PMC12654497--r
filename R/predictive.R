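# Subtype classifiers: panel features, RF/SVM with stratified 10-fold CV,
# rank-statistic AUC with explicit ROC points, multi- vs single-kingdom
# comparison.

#' Build a panel feature matrix of relative abundances
#'
#' Features are per-kingdom relative abundances of the panel taxa
#' (kingdom-prefixed ids, as produced by \code{\link{runDifferential}});
#' a taxon missing from the table contributes a zero column.
#'
#' @param table MultiKingdomTable of counts.
#' @param panel data.frame with columns taxon, kingdom.
#' @param samples sample ids to keep (default all).
#' @return samples x panel numeric matrix.
#' @export
buildFeatures <- function(table, panel, samples = sampleIDs(table)) {
  if (nrow(panel) == 0L) stop("empty panel")
  rel <- toRelativeAbundance(table, scope = "per_kingdom")
  pooled <- .poolAssays(rel)$pooled
  X <- matrix(0, length(samples), nrow(panel),
              dimnames = list(samples, panel$taxon))
  hit <- panel$taxon %in% colnames(pooled)
  X[, panel$taxon[hit]] <- pooled[samples, panel$taxon[hit], drop = FALSE]
  X
}

# Rank-statistic (Mann-Whitney) AUC of scores for the positive class.
.rankAUC <- function(scores, truth) {
  pos <- truth
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# ROC points (FPR, TPR) sweeping thresholds from high to low scores.
.rocPoints <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  nPos <- sum(truth); nNeg <- sum(!truth)
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(diff(s) != 0, TRUE)   # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / nNeg), tpr = c(0, tp[keep] / nPos))
}

.stratifiedFolds <- function(y, nFolds, seed) {
  .withSeed(seed, {
    fold <- integer(length(y))
    for (g in levels(y)) {
      idx <- sample(which(y == g))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
  })
}

.fitScore <- function(family, Xtr, ytr, Xte, seed) {
  .withSeed(seed, {
    if (family == "rf") {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 500L)
      stats::predict(fit, Xte, type = "prob")[, levels(ytr)[2L]]
    } else {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE)
      pr <- attr(stats::predict(fit, Xte, probability = TRUE), "probabilities")
      pr[, levels(ytr)[2L]]
    }
  })
}

#' Train and evaluate subtype classifiers
#'
#' For each model family, stratified 10-fold cross-validation on the
#' training samples yields a CV AUC (mean and sd over folds); the model
#' is then refit on the full training set and scored on the held-out
#' test set with rank-statistic AUC and explicit ROC points. The second
#' factor level is treated as the positive class.
#'
#' @param Xtrain,ytrain training features and labels.
#' @param Xtest,ytest test features and labels.
#' @param families subset of c("rf", "svm").
#' @param featureSet label recorded in the report (e.g. "multi").
#' @param nFolds CV folds (default 10).
#' @param seed RNG seed.
#' @return list(report = data.frame(family, featureSet, cvAUC, cvSD,
#'   testAUC), roc = named list of ROC point data.frames).
#' @export
evaluateModels <- function(Xtrain, ytrain, Xtest, ytest,
                           families = c("rf", "svm"),
                           featureSet = "multi", nFolds = 10L, seed = 1L) {
  ytrain <- droplevels(as.factor(ytrain))
  ytest <- factor(ytest, levels = levels(ytrain))
  stopifnot(nlevels(ytrain) == 2L, all(table(ytrain) >= 2L),
            all(table(ytest) >= 1L))
  baseSeed <- .substream(seed, "models")
  fold <- .stratifiedFolds(ytrain, nFolds, baseSeed)
  # guard: every fold's training part must keep both classes
  for (f in sort(unique(fold))) {
    if (nlevels(droplevels(ytrain[fold != f])) < 2L) {
      warning("re-stratifying folds to keep both classes")
      fold <- .stratifiedFolds(ytrain, max(2L, nFolds - 1L), baseSeed + 1L)
      break
    }
  }
  pos <- levels(ytrain)[2L]
  rocs <- list()
  report <- do.call(rbind, lapply(families, function(fam) {
    cv <- vapply(sort(unique(fold)), function(f) {
      tr <- fold != f
      if (nlevels(droplevels(ytrain[!tr])) < 2L) return(NA_real_)
      sc <- .fitScore(fam, Xtrain[tr, , drop = FALSE], ytrain[tr],
                      Xtrain[!tr, , drop = FALSE], baseSeed + f)
      .rankAUC(sc, ytrain[!tr] == pos)
    }, numeric(1L))
    scTest <- .fitScore(fam, Xtrain, ytrain, Xtest, baseSeed)
    truth <- ytest == pos
    rocs[[paste(fam, featureSet, sep = ".")]] <<- .rocPoints(scTest, truth)
    data.frame(family = fam, featureSet = featureSet,
               cvAUC = mean(cv, na.rm = TRUE),
               cvSD = stats::sd(cv, na.rm = TRUE),
               testAUC = .rankAUC(scTest, truth),
               stringsAsFactors = FALSE)
  }))
  list(report = report, roc = rocs)
}

#' Compare the multi-kingdom panel against single-kingdom panels
#'
#' Runs \code{\link{evaluateModels}} on the full panel and on each
#' kingdom's sub-panel, and summarizes test AUCs. The comparison is
#' descriptive (no hypothesis test).
#'
#' @param table MultiKingdomTable of counts.
#' @param panel panel data.frame (taxon, kingdom).
#' @param labels subtype factor named by sample id.
#' @param split list(train, test) of sample ids.
#' @param families model families.
#' @param nFolds CV folds.
#' @param seed RNG seed.
#' @return list(reports = combined report data.frame, roc = ROC lists,
#'   summary = per-featureSet mean test AUC with the multi-vs-best-single
#'   difference as attribute "deltaBestSingle").
#' @export
comparePanels <- function(table, panel, labels, split,
                          families = c("rf", "svm"), nFolds = 10L,
                          seed = 1L) {
  sets <- c(list(multi = panel),
            lapply(stats::setNames(nm = unique(panel$kingdom)),
                   function(k) panel[panel$kingdom == k, , drop = FALSE]))
  ytr <- labels[split$train]; yte <- labels[split$test]
  out <- lapply(names(sets), function(nm) {
    X <- buildFeatures(table, sets[[nm]])
    evaluateModels(X[split$train, , drop = FALSE], ytr,
                   X[split$test, , drop = FALSE], yte,
                   families = families, featureSet = nm,
                   nFolds = nFolds, seed = seed)
  })
  reports <- do.call(rbind, lapply(out, `[[`, "report"))
  rocs <- do.call(c, lapply(out, `[[`, "roc"))
  meanAUC <- tapply(reports$testAUC, reports$featureSet, mean)
  singles <- meanAUC[names(meanAUC) != "multi"]
  summary <- data.frame(featureSet = names(meanAUC),
                        meanTestAUC = as.numeric(meanAUC),
                        row.names = NULL)
  attr(summary, "deltaBestSingle") <-
    unname(meanAUC["multi"] - max(singles))
  list(reports = reports, roc = rocs, summary = summary)
}
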