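#' Mutual information of two binary vectors (bits)
#'
#' Plug-in estimate of the mutual information of the empirical 2x2 joint
#' distribution, with base-2 logarithm; cells with zero probability
#' contribute zero. Bounded by min(H(x), H(y)) <= 1 bit.
#'
#' @param x,y Binary vectors (values in \{0, 1\}) of equal length >= 2.
#' @return Mutual information in bits.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' mutualInformation(c(0, 1, 0, 1), c(0, 0, 1, 1))  # 0 bits
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  stopifnot(all(x %in% c(0, 1)), all(y %in% c(0, 1)))
  .mi2x2(.jointCounts(x, y))
}

# 2x2 joint counts as a length-4 vector: (00, 01, 10, 11)
.jointCounts <- function(x, y) {
  idx <- 2L * x + y + 1L
  tabulate(idx, nbins = 4L)
}

# MI in bits from a length-4 count vector (00, 01, 10, 11)
.mi2x2 <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  p <- cnt / n
  px <- c(p[1] + p[2], p[3] + p[4])   # x = 0, 1
  py <- c(p[1] + p[3], p[2] + p[4])   # y = 0, 1
  ex <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ex[nz]))
}

# Indices of the bottom/top floor(fraction * n) samples by modulator value.
# Ties in b broken by stable input order (ascending radix sort).
.stratumIndices <- function(bValues, fraction) {
  n <- length(bValues)
  k <- floor(fraction * n)
  if (k < 2) stop("stratum size ", k, " < 2; increase n or the fraction")
  ord <- order(bValues)   # radix sort: stable in input order for ties
  list(low = ord[seq_len(k)], high = ord[seq.int(n - k + 1L, n)], size = k)
}

#' Mutual information of gene and phenotype within one modulator stratum
#'
#' Sorts the (target, phenotype, modulator) sample triplets ascending by the
#' modulator's continuous expression (ties broken by input order), restricts
#' to the bottom or top \code{floor(stratumFraction * n)} samples, and
#' returns the MI of the globally binarized target with the phenotype there.
#' Binarization is global: it is never redone within the stratum.
#'
#' @param aBinary Binarized target-gene vector (0/1).
#' @param phen Binary phenotype vector (0/1), aligned with \code{aBinary}.
#' @param bValues Continuous modulator expression, aligned.
#' @param params A \code{\link{cmiParams}} object.
#' @param side \code{"low"} (bottom stratum) or \code{"high"} (top stratum).
#' @return MI in bits within the stratum.
#' @export
stratifiedMI <- function(aBinary, phen, bValues, params = cmiParams(),
                         side = c("low", "high")) {
  side <- match.arg(side)
  stopifnot(length(aBinary) == length(phen),
            length(aBinary) == length(bValues))
  idx <- .stratumIndices(bValues, params$stratumFraction)[[side]]
  .mi2x2(.jointCounts(aBinary[idx], phen[idx]))
}

#' Modulator-dependence score (CMI) of a gene-phenotype association
#'
#' The dependency score of target A on modulator B is the absolute change in
#' the A-phenotype mutual information between the bottom and top strata of
#' B's expression: \code{cmi = |I_high - I_low|}. A large score means B's
#' level gates how strongly A tracks the phenotype.
#'
#' @inheritParams stratifiedMI
#' @return List with \code{mi_low}, \code{mi_high}, \code{cmi} (all in bits)
#'   and \code{n_stratum} (samples per stratum).
#' @examples
#' set.seed(1)
#' b <- rnorm(40)
#' a <- rbinom(40, 1, 0.5); p <- rbinom(40, 1, 0.5)
#' cmiScore(a, p, b, cmiParams())
#' @export
cmiScore <- function(aBinary, phen, bValues, params = cmiParams()) {
  stopifnot(length(aBinary) == length(phen),
            length(aBinary) == length(bValues))
  st <- .stratumIndices(bValues, params$stratumFraction)
  lo <- .mi2x2(.jointCounts(aBinary[st$low], phen[st$low]))
  hi <- .mi2x2(.jointCounts(aBinary[st$high], phen[st$high]))
  list(mi_low = lo, mi_high = hi, cmi = abs(hi - lo), n_stratum = st$size)
}

#' Permutation p-value for a modulator-dependence score
#'
#' The observed CMI is compared with a null distribution obtained by jointly
#' shuffling the (target, phenotype) sample pairs across samples relative to
#' the modulator: the marginal target-phenotype association is preserved
#' while the link to the modulator's ordering is broken. The p-value uses the
#' add-one rank convention, \code{p = min(1, (1 + #\{null >= observed\}) / N)},
#' so an observed score above every null value scores 1/N and p is never 0.
#'
#' @inheritParams stratifiedMI
#' @return List with \code{cmi} (observed score) and \code{p_value}.
#' @export
permutationPvalue <- function(aBinary, phen, bValues, params = cmiParams()) {
  st <- .stratumIndices(bValues, params$stratumFraction)
  obs <- abs(.mi2x2(.jointCounts(aBinary[st$high], phen[st$high])) -
             .mi2x2(.jointCounts(aBinary[st$low], phen[st$low])))
  n <- length(aBinary)
  ge <- 0L
  for (i in seq_len(params$nPermutations)) {
    perm <- sample.int(n)
    ap <- aBinary[perm]; pp <- phen[perm]
    nullCmi <- abs(.mi2x2(.jointCounts(ap[st$high], pp[st$high])) -
                   .mi2x2(.jointCounts(ap[st$low], pp[st$low])))
    if (nullCmi >= obs) ge <- ge + 1L
  }
  list(cmi = obs, p_value = min(1, (1 + ge) / params$nPermutations))
}

#' Screen candidate gene pairs for modulator-dependent associations
#'
#' For each unordered candidate pair \{A, B\} both directions are tested: B
#' modulating the A-phenotype association and A modulating the B-phenotype
#' association. A direction is kept when its permutation p-value is at most
#' \code{params$alpha}. Genes absent from the expression matrix are skipped
#' (with a message giving the count), as are directions whose target gene
#' binarizes to a constant vector.
#'
#' @param expr Continuous genes x samples expression matrix (rownames =
#'   gene ids) over the retained samples.
#' @param phenStatus Binary phenotype vector aligned with \code{colnames(expr)}.
#' @param candidates data.frame of unordered pairs with columns
#'   \code{gene_a}, \code{gene_b} (as from \code{\link{readEdgeList}}).
#' @param params A \code{\link{cmiParams}} object; \code{params$seed} makes
#'   the screen deterministic.
#' @return data.frame with columns \code{modulator}, \code{target},
#'   \code{cmi}, \code{p_value}; one row per significant directed pair.
#' @export
screenPairs <- function(expr, phenStatus, candidates, params = cmiParams()) {
  stopifnot(is.matrix(expr), length(phenStatus) == ncol(expr))
  if (nrow(candidates) == 0)
    return(data.frame(modulator = character(), target = character(),
                      cmi = numeric(), p_value = numeric()))
  present <- candidates$gene_a %in% rownames(expr) &
             candidates$gene_b %in% rownames(expr)
  if (any(!present))
    message(sum(!present), " candidate pair(s) skipped: gene absent ",
            "from the expression matrix")
  candidates <- candidates[present, , drop = FALSE]
  binExpr <- suppressWarnings(binarizeExpression(expr))
  constant <- apply(expr, 1, function(v) all(v == v[1]))
  set.seed(params$seed)
  out <- vector("list", 2L * nrow(candidates))
  k <- 0L
  for (i in seq_len(nrow(candidates))) {
    pair <- c(candidates$gene_a[i], candidates$gene_b[i])
    for (d in 1:2) {
      target <- pair[d]; modulator <- pair[3 - d]
      if (constant[target]) {
        warning("target gene ", target,
                " binarizes to a constant; direction skipped")
        next
      }
      res <- permutationPvalue(binExpr[target, ], phenStatus,
                               expr[modulator, ], params)
      if (res$p_value <= params$alpha) {
        k <- k + 1L
        out[[k]] <- data.frame(modulator = modulator, target = target,
                               cmi = res$cmi, p_value = res$p_value)
      }
    }
  }
  if (k == 0)
    return(data.frame(modulator = character(), target = character(),
                      cmi = numeric(), p_value = numeric()))
  do.call(rbind, out[seq_len(k)])
}

#' Write a screened dependency-pair table
#' @param pairs data.frame from \code{\link{screenPairs}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDependencyPairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
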