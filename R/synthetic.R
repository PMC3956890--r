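#' Configuration for the synthetic data generators
#'
#' Collects the knobs of the two generators: modulator-gated dependency
#' datasets (binary phenotype whose association with a target gene exists
#' only in one expression stratum of a modulator gene) and survival families
#' (several cohorts sharing planted hazard genes).
#'
#' @param nSamples Samples per dataset.
#' @param nGenes Total genes (planted plus background).
#' @param nModulatedPairs Number of planted modulator-gates-target triples.
#' @param gateStrength Probability, within the active modulator stratum,
#'   that the binarized target equals the phenotype (1 = deterministic
#'   coupling, 0 = no planted effect).
#' @param activeSide Which modulator stratum carries the coupling
#'   (\code{"low"} or \code{"high"}).
#' @param stratumFraction Fraction of samples per stratum; matches the
#'   screen's default so planted effects are exactly what the CMI measures.
#' @param nHazardGenes Number of genes with a planted hazard effect.
#' @param hazardBeta Log-hazard per unit expression of each hazard gene.
#' @param censoringRate Approximate fraction of samples censored before
#'   their event.
#' @param nDatasets Number of cohorts in a survival family.
#' @param seed Integer seed; same seed, same outputs.
#' @return A list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(nSamples = 300, nGenes = 200,
                            nModulatedPairs = 10, gateStrength = 1,
                            activeSide = c("low", "high"),
                            stratumFraction = 0.35,
                            nHazardGenes = 5, hazardBeta = 0.8,
                            censoringRate = 0.3, nDatasets = 3,
                            seed = 1L) {
  activeSide <- match.arg(activeSide)
  stopifnot(nSamples >= 10, nGenes >= 1,
            2 * nModulatedPairs <= nGenes,
            gateStrength >= 0, gateStrength <= 1,
            stratumFraction > 0, stratumFraction <= 0.5,
            nHazardGenes <= nGenes,
            censoringRate >= 0, censoringRate < 1, nDatasets >= 1)
  structure(list(nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes),
                 nModulatedPairs = as.integer(nModulatedPairs),
                 gateStrength = gateStrength, activeSide = activeSide,
                 stratumFraction = stratumFraction,
                 nHazardGenes = as.integer(nHazardGenes),
                 hazardBeta = hazardBeta, censoringRate = censoringRate,
                 nDatasets = as.integer(nDatasets), seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# Continuous encoding of a binary vector whose median-binarization
# reproduces it exactly; requires sum(bin) == ceiling(n/2).
.encodeBinary <- function(bin) {
  bin + stats::runif(length(bin), 0, 0.9)
}

#' Generate a modulator-gated dependency dataset
#'
#' Produces an expression matrix, a balanced binary phenotype, a candidate
#' pair list and the planted ground truth. For each planted triple the
#' binarized target gene equals the phenotype with probability
#' \code{gateStrength} inside the active stratum of its modulator's
#' expression and is independent of the phenotype elsewhere; background
#' genes are i.i.d. Gaussian noise. Candidate pairs hold all planted pairs
#' plus an equal number of null pairs between background genes.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @return List with \code{expr} (matrix), \code{status} (binary phenotype
#'   aligned with samples), \code{candidates} (data.frame gene_a/gene_b),
#'   and \code{truth} (data.frame modulator/target/active_side).
#' @examples
#' d <- generateDependencyDataset(generatorConfig(nSamples = 60,
#'   nGenes = 20, nModulatedPairs = 2, seed = 7))
#' dim(d$expr)
#' @export
generateDependencyDataset <- function(cfg = generatorConfig()) {
  set.seed(cfg$seed)
  n <- cfg$nSamples
  npairs <- cfg$nModulatedPairs
  if (4 * npairs > cfg$nGenes)
    stop("need at least 4 genes per planted pair (modulator, target, ",
         "and a background pair for the matched null)")
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  samples <- sprintf("s%03d", seq_len(n))
  # balanced phenotype in random sample order
  status <- sample(rep(c(0L, 1L), length.out = n))
  expr <- matrix(stats::rnorm(cfg$nGenes * n), cfg$nGenes, n,
                 dimnames = list(genes, samples))
  k <- floor(cfg$stratumFraction * n)
  truth <- NULL
  for (i in seq_len(npairs)) {
    mod <- genes[2 * i - 1]; tgt <- genes[2 * i]
    b <- expr[mod, ]
    ord <- order(b)
    active <- if (cfg$activeSide == "low") ord[seq_len(k)]
              else ord[seq.int(n - k + 1L, n)]
    abin <- integer(n)
    # inside the active stratum: copy the phenotype with probability
    # gateStrength, otherwise an independent fair coin
    coupled <- stats::runif(k) < cfg$gateStrength
    abin[active] <- ifelse(coupled, status[active],
                           stats::rbinom(k, 1, 0.5))
    outside <- setdiff(seq_len(n), active)
    needed <- ceiling(n / 2) - sum(abin[active])
    needed <- max(0L, min(length(outside), needed))
    ones <- sample(outside, needed)
    abin[ones] <- 1L
    expr[tgt, ] <- .encodeBinary(abin)
    truth <- rbind(truth, data.frame(modulator = mod, target = tgt,
                                     active_side = cfg$activeSide))
  }
  planted <- if (npairs > 0)
    data.frame(gene_a = truth$modulator, gene_b = truth$target)
  else data.frame(gene_a = character(), gene_b = character())
  bg <- genes[seq.int(2 * npairs + 1, cfg$nGenes)]
  nullPairs <- if (npairs > 0)
    data.frame(gene_a = bg[seq_len(npairs)],
               gene_b = bg[seq.int(npairs + 1, 2 * npairs)])
  else data.frame(gene_a = character(), gene_b = character())
  list(expr = expr, status = stats::setNames(status, samples),
       candidates = rbind(planted, nullPairs),
       truth = if (is.null(truth))
         data.frame(modulator = character(), target = character(),
                    active_side = character()) else truth)
}

#' Generate a family of survival datasets with shared hazard genes
#'
#' Each cohort draws i.i.d. Gaussian expression; the first
#' \code{nHazardGenes} genes carry a log-linear effect \code{hazardBeta} on
#' an exponential event-time hazard (baseline rate 0.1 per year, memoryless
#' so closed-form checks apply). Censoring times are independent
#' exponentials tuned so that roughly \code{censoringRate} of samples are
#' censored; \code{censoringRate = 0} leaves every event observed. The
#' hazard genes (the ground truth) are shared across cohorts, emulating one
#' signature evaluated on several independent datasets.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @return List with \code{datasets} (named list of \code{expr} +
#'   \code{clin} pairs) and \code{truth} (data.frame gene/true_beta).
#' @export
generateSurvivalFamily <- function(cfg = generatorConfig()) {
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  hz <- genes[seq_len(cfg$nHazardGenes)]
  truth <- data.frame(gene = hz,
                      true_beta = rep(cfg$hazardBeta, cfg$nHazardGenes))
  lambda0 <- 0.1
  lambdaC <- if (cfg$censoringRate > 0)
    lambda0 * cfg$censoringRate / (1 - cfg$censoringRate) else 0
  datasets <- list()
  for (d in seq_len(cfg$nDatasets)) {
    n <- cfg$nSamples
    samples <- sprintf("d%d_s%03d", d, seq_len(n))
    expr <- matrix(stats::rnorm(cfg$nGenes * n), cfg$nGenes, n,
                   dimnames = list(genes, samples))
    lp <- if (cfg$nHazardGenes > 0)
      colSums(expr[hz, , drop = FALSE] * cfg$hazardBeta) else rep(0, n)
    tEvent <- stats::rexp(n, rate = lambda0 * exp(lp))
    tCens <- if (lambdaC > 0) stats::rexp(n, rate = lambdaC) else rep(Inf, n)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    clin <- data.frame(sample_id = samples, time = time, event = event)
    datasets[[paste0("dataset", d)]] <- list(expr = expr, clin = clin)
  }
  list(datasets = datasets, truth = truth)
}

#' Materialize a small demo dataset on disk
#'
#' Writes a modulator-gated expression matrix, a matching clinical table,
#' the candidate edge list, the planted truth, and a gene-set file in the
#' package's tab-delimited interchange formats.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A \code{\link{generatorConfig}}.
#' @return Invisibly, a named list of the written paths.
#' @export
makeFixtures <- function(dir, cfg = generatorConfig(nSamples = 80,
                                                    nGenes = 30,
                                                    nModulatedPairs = 3,
                                                    seed = 1L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dep <- generateDependencyDataset(cfg)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    edges = file.path(dir, "candidate_pairs.tsv"),
    truth = file.path(dir, "planted_truth.tsv"),
    geneset = file.path(dir, "modulators.txt"))
  writeExpression(dep$expr, paths$expression)
  # survival consistent with the phenotype: cases get early events
  n <- length(dep$status)
  set.seed(cfg$seed + 1L)
  time <- ifelse(dep$status == 1, stats::runif(n, 0.5, 4.5),
                 stats::runif(n, 5.5, 12))
  event <- ifelse(dep$status == 1, 1L,
                  stats::rbinom(n, 1, 0.3))
  writeClinical(data.frame(sample_id = names(dep$status),
                           time = round(time, 3), event = event),
                paths$clinical)
  utils::write.table(dep$candidates, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dep$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(unique(dep$truth$modulator), paths$geneset)
  invisible(paths)
}
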