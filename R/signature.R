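#' Construct a GeneSignature from a gene table
#'
#' @param genes data.frame with columns \code{gene_id}, \code{cox_beta},
#'   \code{cox_p}, \code{stability}.
#' @return A \linkS4class{GeneSignature}.
#' @export
newSignature <- function(genes) {
  rownames(genes) <- NULL
  new("GeneSignature", genes = genes)
}

#' Univariate Cox proportional-hazards fit for one gene
#'
#' Partial-likelihood estimate of the log hazard ratio per unit expression,
#' with Efron handling of tied event times, and its Wald p-value.
#'
#' @param geneValues Continuous expression vector.
#' @param time Follow-up times (years), aligned.
#' @param event Binary event indicator, aligned.
#' @return List with \code{beta}, \code{p_value}, \code{se}.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' t <- rexp(100, rate = 0.2 * exp(0.8 * x))
#' coxUnivariate(x, t, rep(1, 100))
#' @export
coxUnivariate <- function(geneValues, time, event) {
  if (sum(event) < 2) stop("need at least 2 events for a Cox fit")
  if (all(geneValues == geneValues[1]))
    stop("constant covariate: Cox coefficient not estimable")
  fit <- survival::coxph(survival::Surv(time, event) ~ geneValues,
                         ties = "efron")
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)),
       p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
       se = unname(s$coefficients[1, "se(coef)"]))
}

#' Resampled univariate Cox candidate selection
#'
#' Repeatedly subsamples the cohort (without replacement), fits a univariate
#' Cox model per gene on each subsample, and keeps the genes whose Wald
#' p-value falls below \code{perRunAlpha} in at least
#' \code{stabilityThreshold} of the runs. Reported beta and p are averages
#' over the runs in which the fit succeeded; a run where the fit fails (e.g.
#' constant gene in the subsample) counts as not significant.
#'
#' @param expr Continuous genes x samples matrix; colnames are sample ids.
#' @param clin data.frame with \code{sample_id}, \code{time}, \code{event};
#'   must overlap \code{colnames(expr)} in at least 10 samples.
#' @param params A \code{\link{resamplingParams}} object.
#' @return data.frame with columns \code{gene_id}, \code{cox_beta},
#'   \code{cox_p}, \code{stability}, one row per selected gene (possibly
#'   zero rows).
#' @export
resampledCandidateSelection <- function(expr, clin,
                                        params = resamplingParams()) {
  common <- intersect(colnames(expr), clin$sample_id)
  if (length(common) < 10)
    stop("need at least 10 samples shared by expression and clinical data")
  expr <- expr[, common, drop = FALSE]
  clin <- clin[match(common, clin$sample_id), ]
  n <- length(common)
  k <- round(params$subsampleFraction * n)
  genes <- rownames(expr)
  sig_count <- integer(length(genes))
  beta_sum <- numeric(length(genes))
  p_sum <- numeric(length(genes))
  fit_count <- integer(length(genes))
  for (r in seq_len(params$nRuns)) {
    # per-run stream derived from (seed, run) so partial reruns reproduce
    set.seed((params$seed + 1000003L * r) %% .Machine$integer.max)
    idx <- sample.int(n, k)
    ti <- clin$time[idx]; ev <- clin$event[idx]
    if (sum(ev) < 2) next
    for (g in seq_along(genes)) {
      fit <- tryCatch(coxUnivariate(expr[g, idx], ti, ev),
                      error = function(e) NULL)
      if (is.null(fit)) next
      fit_count[g] <- fit_count[g] + 1L
      beta_sum[g] <- beta_sum[g] + fit$beta
      p_sum[g] <- p_sum[g] + fit$p_value
      if (fit$p_value < params$perRunAlpha) sig_count[g] <- sig_count[g] + 1L
    }
  }
  stability <- sig_count / params$nRuns
  keep <- stability >= params$stabilityThreshold & fit_count > 0
  data.frame(gene_id = genes[keep],
             cox_beta = beta_sum[keep] / fit_count[keep],
             cox_p = p_sum[keep] / fit_count[keep],
             stability = stability[keep])
}

#' Intersect Cox candidates with network hubs
#'
#' The hub-based signature keeps the candidate genes that are also hubs of
#' the dependency network, preserving their candidate statistics.
#'
#' @param candidates data.frame from
#'   \code{\link{resampledCandidateSelection}} (or a parsed signature table).
#' @param hubs Character vector of hub gene ids.
#' @return A \linkS4class{GeneSignature} (possibly empty).
#' @export
hubSignature <- function(candidates, hubs) {
  keep <- candidates$gene_id %in% hubs
  newSignature(candidates[keep, c("gene_id", "cox_beta", "cox_p",
                                  "stability"), drop = FALSE])
}

#' GGI-style risk score of one sample
#'
#' Unweighted sum of expression over positively associated signature genes
#' minus the sum over negatively associated ones:
#' \deqn{RS = \sum_{i: \beta_i > 0} x_i - \sum_{j: \beta_j < 0} x_j.}
#'
#' @param sig A \linkS4class{GeneSignature}; must be non-empty.
#' @param sampleExpression Named numeric vector of expression values indexed
#'   by gene id; all signature genes must be present.
#' @return Numeric risk score.
#' @examples
#' sig <- newSignature(data.frame(gene_id = c("g1", "g2"),
#'                                cox_beta = c(0.5, -0.5),
#'                                cox_p = c(0.01, 0.01), stability = 1))
#' riskScore(sig, c(g1 = 3, g2 = 1))  # 2
#' @export
riskScore <- function(sig, sampleExpression) {
  if (length(sig) == 0) stop("empty signature")
  pos <- positiveGenes(sig); neg <- negativeGenes(sig)
  missing <- setdiff(c(pos, neg), names(sampleExpression))
  if (length(missing) > 0)
    stop("signature genes absent from sample expression: ",
         paste(missing, collapse = ", "))
  sum(sampleExpression[pos]) - sum(sampleExpression[neg])
}

#' Risk scores for every sample of an expression matrix
#'
#' @param sig A \linkS4class{GeneSignature}.
#' @param expr Continuous genes x samples matrix.
#' @return Numeric vector of risk scores named by sample id.
#' @export
riskScoreMatrix <- function(sig, expr) {
  if (length(sig) == 0) stop("empty signature")
  pos <- positiveGenes(sig); neg <- negativeGenes(sig)
  missing <- setdiff(c(pos, neg), rownames(expr))
  if (length(missing) > 0)
    stop("signature genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  up <- if (length(pos)) colSums(expr[pos, , drop = FALSE]) else 0
  dn <- if (length(neg)) colSums(expr[neg, , drop = FALSE]) else 0
  up - dn
}
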