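#' Split samples into equal-size low- and high-risk groups
#'
#' Samples are sorted ascending by risk score (stable: ties keep their input
#' order); the first ceiling(n/2) form the low-risk group and the rest the
#' high-risk group, so at odd n the low group receives the extra sample.
#'
#' @param risks Numeric risk scores, named by sample id (names optional).
#' @return A \linkS4class{RiskPartition}.
#' @examples
#' splitGroups(c(a = 0.1, b = 0.4, c = 0.2))
#' @export
splitGroups <- function(risks) {
  n <- length(risks)
  ids <- names(risks)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(risks)                  # radix: stable for ties
  nl <- ceiling(n / 2)
  group <- character(n)
  group[ord[seq_len(nl)]] <- "low"
  if (nl < n) group[ord[seq.int(nl + 1L, n)]] <- "high"
  new("RiskPartition", sample_ids = ids, risk = unname(risks),
      group = factor(group, levels = c("low", "high")))
}

#' Log-rank test and hazard ratio between risk groups
#'
#' Standard two-group log-rank chi-square (1 df) comparing the survival of
#' the low- and high-risk groups, plus the hazard ratio of high vs low from
#' a one-covariate Cox fit on the group indicator with a 95% Wald interval.
#'
#' @param part A \linkS4class{RiskPartition}.
#' @param clin data.frame with \code{sample_id}, \code{time}, \code{event};
#'   must cover the partition's samples.
#' @return List with \code{statistic}, \code{p_value}, \code{hazard_ratio},
#'   \code{ci_low}, \code{ci_high}.
#' @export
logrankTest <- function(part, clin) {
  g <- riskGroups(part)
  idx <- match(names(g), clin$sample_id)
  if (anyNA(idx))
    stop("clinical data missing for samples: ",
         paste(names(g)[is.na(idx)], collapse = ", "))
  time <- clin$time[idx]; event <- clin$event[idx]
  if (!all(c("low", "high") %in% g)) stop("both risk groups must be nonempty")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- sd$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ I(g == "high"))
  beta <- unname(stats::coef(cx))
  se <- sqrt(unname(stats::vcov(cx)[1, 1]))
  list(statistic = stat, p_value = p,
       hazard_ratio = exp(beta),
       ci_low = exp(beta - stats::qnorm(0.975) * se),
       ci_high = exp(beta + stats::qnorm(0.975) * se))
}

#' Discrimination score across datasets
#'
#' \deqn{Dscore = \sum_i -\log_{10} \max(p_i, floor)} over the per-dataset
#' log-rank p-values. Each dataset contributes at most
#' \eqn{-\log_{10}} of the floor (17 at the default 1e-17); larger Dscore
#' means better, more consistent risk discrimination across cohorts.
#'
#' @param pValues Numeric vector of p-values in (0, 1].
#' @param params A \code{\link{dscoreParams}} object.
#' @return The Dscore (non-negative scalar).
#' @examples
#' dscore(c(0.032, 0.00556, 0.0096, 0.054, 0.013, 0.0029))
#' @export
dscore <- function(pValues, params = dscoreParams()) {
  stopifnot(all(pValues > 0), all(pValues <= 1))
  sum(-log10(pmax(pValues, params$pFloor)))
}

#' Fisher's combined probability test
#'
#' \eqn{X = -2 \sum \ln \max(p_i, floor)} referred to a chi-square
#' distribution with 2n degrees of freedom. Note the identity
#' \eqn{X = 2 \ln(10) \cdot Dscore} with the same floor.
#'
#' @inheritParams dscore
#' @return Combined p-value.
#' @export
fisherCombined <- function(pValues, params = dscoreParams()) {
  stopifnot(all(pValues > 0), all(pValues <= 1))
  x <- -2 * sum(log(pmax(pValues, params$pFloor)))
  stats::pchisq(x, df = 2 * length(pValues), lower.tail = FALSE)
}

#' Evaluate a signature on one or more datasets
#'
#' For each dataset the samples are scored with the signature, split into
#' equal-size risk groups, and compared by log-rank test; the per-dataset
#' p-values are summarised by the Dscore.
#'
#' @param sig A \linkS4class{GeneSignature}.
#' @param datasets Named list; each element a list with \code{expr}
#'   (genes x samples matrix) and \code{clin} (clinical data.frame).
#' @param params A \code{\link{dscoreParams}} object.
#' @return List with \code{table} (data.frame: dataset, hazard_ratio,
#'   ci_low, ci_high, logrank_p) and \code{dscore}.
#' @export
evaluateSignature <- function(sig, datasets, params = dscoreParams()) {
  rows <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    common <- intersect(colnames(d$expr), d$clin$sample_id)
    risks <- riskScoreMatrix(sig, d$expr[, common, drop = FALSE])
    lr <- logrankTest(splitGroups(risks), d$clin)
    data.frame(dataset = nm, hazard_ratio = lr$hazard_ratio,
               ci_low = lr$ci_low, ci_high = lr$ci_high,
               logrank_p = lr$p_value)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, dscore = dscore(tab$logrank_p, params))
}

#' Null distribution of Dscores from random signatures
#'
#' Draws \code{nReps} random signatures of size \code{k} from a gene pool,
#' estimates each drawn gene's coefficient sign by univariate Cox regression
#' on a designated training dataset, scores and splits every evaluation
#' dataset, and records the resulting Dscore. Two pools mirror the usual
#' controls: the whole measured gene set, or a pre-selected candidate pool.
#'
#' @param datasets Named list of evaluation datasets (as in
#'   \code{\link{evaluateSignature}}).
#' @param training A list with \code{expr} and \code{clin}: the dataset used
#'   to estimate coefficient signs for each random draw.
#' @param pool Character vector of gene ids to draw from; must have at least
#'   \code{k} members and be present in all expression matrices.
#' @param k Signature size per draw.
#' @param nReps Number of random signatures.
#' @param seed Integer seed.
#' @param params A \code{\link{dscoreParams}} object.
#' @return Numeric vector of \code{nReps} Dscores.
#' @export
randomSignatureNull <- function(datasets, training, pool, k, nReps,
                                seed = 1L, params = dscoreParams()) {
  pool <- unique(pool)
  if (k > length(pool)) stop("k exceeds the pool size")
  if (nReps == 0) return(numeric())
  common <- intersect(colnames(training$expr), training$clin$sample_id)
  trExpr <- training$expr[, common, drop = FALSE]
  trClin <- training$clin[match(common, training$clin$sample_id), ]
  set.seed(seed)
  vapply(seq_len(nReps), function(rep) {
    draw <- sample(pool, k)
    betas <- vapply(draw, function(g) {
      fit <- tryCatch(coxUnivariate(trExpr[g, ], trClin$time, trClin$event),
                      error = function(e) NULL)
      if (is.null(fit)) 0 else fit$beta
    }, 0)
    sig <- newSignature(data.frame(gene_id = draw, cox_beta = betas,
                                   cox_p = NA_real_, stability = NA_real_))
    ev <- evaluateSignature(sig, datasets, params)
    ev$dscore
  }, 0)
}

#' Empirical p-value of an observed Dscore against a null sample
#'
#' Plain exceedance fraction \code{#\{null >= observed\} / length(null)}
#' (no add-one correction), matching the usual reporting of
#' random-signature comparisons.
#'
#' @param observed Observed Dscore.
#' @param null Numeric vector of null Dscores.
#' @return Proportion in [0, 1].
#' @examples
#' empiricalPvalue(18.9, c(2, 3, 19, 20))  # 0.5
#' @export
empiricalPvalue <- function(observed, null) {
  if (length(null) == 0) stop("empty null sample")
  mean(null >= observed)
}
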