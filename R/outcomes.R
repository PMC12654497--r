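# Subtype-versus-outcome statistics: contingency tests, Kaplan-Meier
# curves and the log-rank test (product-limit and O-E forms written out).

#' Chi-square contingency test of an outcome against subtype labels
#'
#' Pearson chi-square without continuity correction on the observed
#' cross-table; samples with unknown outcome are dropped.
#'
#' @param metadata metadata data.frame (see \code{\link{sampleMetadata}}).
#' @param outcome "response" or "pfs_gt6".
#' @param labels factor of subtype labels named by sample id.
#' @return list(chi2, p, table).
#' @export
contingencyTest <- function(metadata, outcome = c("response", "pfs_gt6"),
                            labels) {
  outcome <- match.arg(outcome)
  v <- metadata[[outcome]]
  g <- labels[metadata$sample_id]
  known <- !is.na(v) & v != "unknown" & !is.na(g)
  tab <- table(subtype = droplevels(as.factor(g[known])),
               outcome = droplevels(as.factor(as.character(v[known]))))
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingencyTest needs >= 2 observed levels on both margins")
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp < 1)) warning("expected cell count below 1")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i / n_i); tied
#' deaths are handled simultaneously and censored times only shrink the
#' risk set.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @param labels group per observation (a single group is fine).
#' @return Named list of data.frames (time, nRisk, nEvent, surv), one per
#'   group, rows at distinct event times.
#' @export
kmEstimate <- function(time, event, labels = rep("all", length(time))) {
  if (any(time < 0)) stop("kmEstimate: negative time")
  stopifnot(all(event %in% c(0, 1)), length(event) == length(time))
  groups <- as.factor(labels)
  out <- lapply(levels(groups), function(g) {
    tt <- time[groups == g]; ee <- event[groups == g]
    ts <- sort(unique(tt[ee == 1]))
    surv <- 1
    rows <- lapply(ts, function(t0) {
      nRisk <- sum(tt >= t0)
      d <- sum(tt == t0 & ee == 1)
      surv <<- surv * (1 - d / nRisk)
      data.frame(time = t0, nRisk = nRisk, nEvent = d, surv = surv)
    })
    if (length(rows)) do.call(rbind, rows)
    else data.frame(time = numeric(0), nRisk = integer(0),
                    nEvent = integer(0), surv = numeric(0))
  })
  names(out) <- levels(groups)
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve one element of \code{\link{kmEstimate}}'s result.
#' @param at times to evaluate.
#' @return Survival probabilities (1 before the first event).
#' @export
kmSurvival <- function(curve, at) {
  vapply(at, function(t0) {
    i <- which(curve$time <= t0)
    if (length(i)) curve$surv[max(i)] else 1
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' Standard O-E statistic over distinct event times with the
#' hypergeometric variance, compared to chi-square with 1 df.
#'
#' @param time follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param labels two-level grouping.
#' @return list(chi2, p).
#' @export
logrankTest <- function(time, event, labels) {
  groups <- droplevels(as.factor(labels))
  if (nlevels(groups) != 2L) stop("logrankTest needs exactly 2 groups")
  if (any(tapply(event, groups, sum) == 0))
    warning("a group has zero events")
  g1 <- groups == levels(groups)[1L]
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t0 in ts) {
    atRisk <- time >= t0
    n <- sum(atRisk); n1 <- sum(atRisk & g1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) oe^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}
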