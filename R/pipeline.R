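#' Read a flat key=value run configuration
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Recognised keys: input paths (\code{expression}, \code{clinical},
#' \code{edges}, \code{hubs}, \code{signature}, \code{datasets},
#' \code{null_pool}), \code{outdir}, and numeric parameters
#' (\code{seed}, \code{alpha}, \code{permutations}, \code{stratum_fraction},
#' \code{hub_fraction}, \code{min_out_degree}, \code{runs},
#' \code{subsample_fraction}, \code{per_run_alpha},
#' \code{stability_threshold}, \code{p_floor}, \code{horizon},
#' \code{null_reps}, \code{null_k}).
#'
#' @param path Path to the config file, or \code{NULL} for defaults only.
#' @param overrides Named list overriding file values (e.g. from the command
#'   line).
#' @return Named list of configuration values with defaults filled in.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(seed = 1, alpha = 0.05, permutations = 1000,
              stratum_fraction = 0.35, hub_fraction = 0.20,
              min_out_degree = 4, runs = 400, subsample_fraction = 0.75,
              per_run_alpha = 0.05, stability_threshold = 0.90,
              p_floor = 1e-17, horizon = 5, null_reps = 0, null_k = 0,
              outdir = ".")
  numeric_keys <- c("seed", "alpha", "permutations", "stratum_fraction",
                    "hub_fraction", "min_out_degree", "runs",
                    "subsample_fraction", "per_run_alpha",
                    "stability_threshold", "p_floor", "horizon",
                    "null_reps", "null_k")
  if (!is.null(path)) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      cfg[[key]] <- if (key %in% numeric_keys) as.numeric(val) else val
    }
  }
  for (key in names(overrides))
    if (!is.null(overrides[[key]])) cfg[[key]] <- overrides[[key]]
  cfg
}

# run manifest: parameters, seed, input digests, package version
.writeManifest <- function(cfg, inputs, path) {
  digests <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else "missing", "")
  lines <- c(
    paste0("package_version = ", as.character(utils::packageVersion("depnet"))),
    paste0(names(cfg), " = ", vapply(cfg, function(x)
      paste(format(x), collapse = ","), "")),
    paste0("md5_", names(inputs), " = ", digests))
  writeLines(lines, path)
  invisible(path)
}

#' Run the network-construction pipeline
#'
#' Reads expression, clinical and candidate-pair inputs, dichotomizes the
#' phenotype, screens all candidate pairs for modulator-dependent
#' associations, builds the directed dependency network, restricts to the
#' main component, selects hubs, and fits in/out degree power laws. Writes
#' the edge table, node table (with hub flags), power-law summary and a run
#' manifest into \code{cfg$outdir}.
#'
#' @param cfg Configuration list from \code{\link{readRunConfig}}; needs
#'   \code{expression}, \code{clinical}, \code{edges}, \code{outdir}.
#' @return Invisibly, a list with the network, main component, hubs and
#'   output paths.
#' @export
cmdNetwork <- function(cfg) {
  for (key in c("expression", "clinical", "edges"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("missing input: ", key)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- readExpression(cfg$expression)
  clin <- readClinical(cfg$clinical)
  edges <- readEdgeList(cfg$edges)
  phen <- dichotomizePhenotype(clin, cfg$horizon)
  keep <- intersect(colnames(expr), phen$sample_ids)
  status <- phen$status[match(keep, phen$sample_ids)]
  pairs <- if (cfg$alpha <= 0) {
    warning("alpha = 0: no edge can be significant")
    data.frame(modulator = character(), target = character(),
               cmi = numeric(), p_value = numeric())
  } else {
    params <- cmiParams(stratumFraction = cfg$stratum_fraction,
                        nPermutations = cfg$permutations,
                        alpha = min(cfg$alpha, 1 - 1e-12),
                        seed = cfg$seed)
    screenPairs(expr[, keep, drop = FALSE], status, edges, params)
  }
  net <- buildNetwork(pairs)
  main <- mainComponent(net)
  hubs <- if (length(networkNodes(main)) > 0)
    selectHubs(main, hubParams(cfg$hub_fraction, cfg$min_out_degree))
  else character()
  paths <- list(edges = file.path(cfg$outdir, "network_edges.tsv"),
                nodes = file.path(cfg$outdir, "network_nodes.tsv"),
                powerlaw = file.path(cfg$outdir, "powerlaw_summary.tsv"),
                hubs = file.path(cfg$outdir, "hub_genes.txt"),
                manifest = file.path(cfg$outdir, "manifest_network.txt"))
  writeNetwork(net, paths$edges, paths$nodes, hubs)
  writeLines(hubs, paths$hubs)
  pl <- lapply(c("in", "out"), function(dir) {
    fit <- tryCatch(fitPowerLaw(degreeDistribution(main, dir)),
                    error = function(e) list(exponent = NA, correlation = NA,
                                             r_square = NA))
    data.frame(direction = dir, exponent = fit$exponent,
               correlation = fit$correlation, r_square = fit$r_square)
  })
  utils::write.table(do.call(rbind, pl), paths$powerlaw, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeManifest(cfg, list(expression = cfg$expression,
                           clinical = cfg$clinical, edges = cfg$edges),
                 paths$manifest)
  invisible(list(network = net, main = main, hubs = hubs, paths = paths))
}

#' Run the signature-selection pipeline
#'
#' Resampled univariate Cox candidate selection followed by intersection
#' with the hub gene set; writes the signature table and a manifest.
#'
#' @param cfg Configuration list; needs \code{expression}, \code{clinical},
#'   \code{hubs} (gene-set file, e.g. written by \code{\link{cmdNetwork}})
#'   and \code{outdir}.
#' @return Invisibly, a list with the signature and output paths.
#' @export
cmdSignature <- function(cfg) {
  for (key in c("expression", "clinical", "hubs"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("missing input: ", key)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- readExpression(cfg$expression)
  clin <- readClinical(cfg$clinical)
  hubs <- readGeneSet(cfg$hubs)
  params <- resamplingParams(nRuns = cfg$runs,
                             subsampleFraction = cfg$subsample_fraction,
                             perRunAlpha = cfg$per_run_alpha,
                             stabilityThreshold = cfg$stability_threshold,
                             seed = cfg$seed)
  candidates <- resampledCandidateSelection(expr, clin, params)
  sig <- hubSignature(candidates, hubs)
  paths <- list(candidates = file.path(cfg$outdir, "cox_candidates.tsv"),
                signature = file.path(cfg$outdir, "signature.tsv"),
                manifest = file.path(cfg$outdir, "manifest_signature.txt"))
  utils::write.table(candidates, paths$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeSignature(sig, paths$signature)
  .writeManifest(cfg, list(expression = cfg$expression,
                           clinical = cfg$clinical, hubs = cfg$hubs),
                 paths$manifest)
  invisible(list(signature = sig, candidates = candidates, paths = paths))
}

# parse "name=expr.tsv,clin.tsv;name2=..." into a dataset list
.parseDatasets <- function(spec) {
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed dataset spec: '", p, "'")
    files <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    if (length(files) != 2) stop("dataset needs expression,clinical: '", p, "'")
    out[[trimws(kv[1])]] <- list(expr = readExpression(files[1]),
                                 clin = readClinical(files[2]))
  }
  out
}

#' Run the signature-evaluation pipeline
#'
#' Scores every dataset with the signature, splits each into equal-size risk
#' groups, runs the log-rank test, and writes a per-dataset report (dataset,
#' HR, CI, log-rank p) plus a summary line with the Dscore. With
#' \code{null_reps > 0}, also draws random signatures from \code{null_pool}
#' (defaults to all genes of the first dataset) and reports the empirical
#' p-value of the observed Dscore against their null Dscores.
#'
#' @param cfg Configuration list; needs \code{signature}, \code{datasets}
#'   (spec \code{"name=expr.tsv,clin.tsv;..."}) and \code{outdir}. The first
#'   dataset is the training set for random-null sign estimation.
#' @return Invisibly, a list with the evaluation table, Dscore, optional
#'   null Dscores and empirical p, and output paths.
#' @export
cmdEvaluate <- function(cfg) {
  for (key in c("signature", "datasets"))
    if (is.null(cfg[[key]])) stop("missing input: ", key)
  if (!file.exists(cfg$signature)) stop("missing input: signature")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sig <- readSignature(cfg$signature)
  datasets <- .parseDatasets(cfg$datasets)
  dparams <- dscoreParams(pFloor = cfg$p_floor)
  ev <- evaluateSignature(sig, datasets, dparams)
  paths <- list(report = file.path(cfg$outdir, "evaluation_report.tsv"),
                manifest = file.path(cfg$outdir, "manifest_evaluate.txt"))
  con <- file(paths$report, "w")
  utils::write.table(ev$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0("# Dscore\t", format(ev$dscore, digits = 10)), con)
  nullD <- NULL; empP <- NULL
  if (cfg$null_reps > 0) {
    training <- datasets[[1]]
    pool <- if (!is.null(cfg$null_pool) && file.exists(cfg$null_pool))
      readGeneSet(cfg$null_pool) else rownames(training$expr)
    k <- if (cfg$null_k > 0) cfg$null_k else length(sig)
    nullD <- randomSignatureNull(datasets, training, pool, k,
                                 nReps = cfg$null_reps, seed = cfg$seed,
                                 params = dparams)
    empP <- empiricalPvalue(ev$dscore, nullD)
    writeLines(paste0("# random_null_empirical_p\t", format(empP)), con)
  }
  close(con)
  .writeManifest(cfg, list(signature = cfg$signature), paths$manifest)
  invisible(list(table = ev$table, dscore = ev$dscore, nullDscores = nullD,
                 empirical_p = empP, paths = paths))
}
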