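#' Build a directed dependency network from screened pairs
#'
#' @param pairs data.frame with columns \code{modulator}, \code{target},
#'   \code{cmi}, \code{p_value} (one significant directed pair per row).
#' @return A \linkS4class{DependencyNetwork}. Reciprocal pairs (B->A and
#'   A->B) are allowed; duplicate ordered pairs are an error.
#' @examples
#' p <- data.frame(modulator = c("B", "A"), target = c("A", "B"),
#'                 cmi = c(0.4, 0.3), p_value = c(0.01, 0.02))
#' buildNetwork(p)
#' @export
buildNetwork <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0 &&
      anyDuplicated(paste(pairs$modulator, pairs$target, sep = "\r")))
    stop("duplicate ordered pair in input")
  nodes <- sort(unique(c(pairs$modulator, pairs$target)))
  new("DependencyNetwork",
      edges = pairs[, c("modulator", "target", "cmi", "p_value"),
                    drop = FALSE],
      nodes = nodes)
}

# igraph view of the network (directed, nodes without edges included)
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    networkEdges(net)[, c("modulator", "target")],
    directed = TRUE, vertices = networkNodes(net))
}

#' Largest weakly connected component
#'
#' Edge direction is ignored for connectivity. If two components tie for the
#' largest size, the one containing the lexicographically smallest gene id
#' wins.
#'
#' @param net A \linkS4class{DependencyNetwork}.
#' @return The sub-network induced by the main component.
#' @export
mainComponent <- function(net) {
  if (length(networkNodes(net)) == 0) return(net)
  g <- .asIgraph(net)
  comp <- igraph::components(g, mode = "weak")
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # tie-break: component holding the lexicographically smallest member
    firsts <- vapply(best, function(b)
      min(names(comp$membership)[comp$membership == b]), "")
    best <- best[order(firsts)][1]
  }
  keep <- names(comp$membership)[comp$membership == best]
  e <- networkEdges(net)
  e <- e[e$modulator %in% keep & e$target %in% keep, , drop = FALSE]
  new("DependencyNetwork", edges = e, nodes = sort(keep))
}

#' Node degrees of a dependency network
#'
#' @param net A \linkS4class{DependencyNetwork}.
#' @param direction \code{"in"}, \code{"out"} or \code{"total"}.
#' @return Integer vector of degrees named by gene id.
#' @export
nodeDegrees <- function(net, direction = c("out", "in", "total")) {
  direction <- match.arg(direction)
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  outd <- table(factor(e$modulator, levels = nodes))
  ind <- table(factor(e$target, levels = nodes))
  d <- switch(direction, out = outd, `in` = ind, total = outd + ind)
  stats::setNames(as.integer(d), nodes)
}

#' Degree distribution of a dependency network
#'
#' @inheritParams nodeDegrees
#' @return data.frame with columns \code{degree}, \code{frequency}
#'   (number of nodes with that degree); zero-frequency degrees omitted.
#' @export
degreeDistribution <- function(net, direction = c("out", "in", "total")) {
  d <- nodeDegrees(net, direction)
  if (length(d) == 0)
    return(data.frame(degree = integer(), frequency = integer()))
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)),
             frequency = as.integer(tab))
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares on the log10-log10 points (degree, frequency) over
#' degrees >= 1, as done for scale-free checks of biological networks.
#' Reports the slope magnitude as the exponent, the magnitude of the Pearson
#' correlation of the log-log points, and the coefficient of determination.
#'
#' @param dist data.frame with \code{degree}, \code{frequency} columns
#'   (from \code{\link{degreeDistribution}}).
#' @return List with \code{exponent}, \code{correlation}, \code{r_square}.
#' @examples
#' d <- data.frame(degree = 1:10, frequency = round(1000 * (1:10)^-2))
#' fitPowerLaw(d)
#' @export
fitPowerLaw <- function(dist) {
  dist <- dist[dist$degree >= 1 & dist$frequency > 0, , drop = FALSE]
  if (nrow(dist) < 3)
    stop("power-law fit needs at least 3 distinct positive degrees")
  lx <- log10(dist$degree); ly <- log10(dist$frequency)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  r <- if (stats::sd(ly) == 0) 0 else abs(stats::cor(lx, ly))
  list(exponent = abs(slope), correlation = r, r_square = r^2)
}

#' Select hub genes by out-degree cutoff
#'
#' Hubs are the genes with the largest out-degrees: the smallest out-degree
#' cutoff \code{d*} (at least \code{minOutDegree}) is chosen such that the
#' number of nodes with out-degree >= \code{d*} does not exceed
#' \code{hubFraction} of the nodes — i.e. the selection gets as close to the
#' target fraction as possible from below without ever splitting a tie.
#'
#' @param net A \linkS4class{DependencyNetwork} (typically the main
#'   component).
#' @param params A \code{\link{hubParams}} object.
#' @return character vector of hub gene ids (possibly empty).
#' @export
selectHubs <- function(net, params = hubParams()) {
  nodes <- networkNodes(net)
  if (length(nodes) == 0) stop("cannot select hubs from an empty network")
  outd <- nodeDegrees(net, "out")
  target <- params$hubFraction * length(nodes)
  cutoffs <- sort(unique(outd[outd >= params$minOutDegree]))
  dstar <- NA_integer_
  for (d in cutoffs) {           # ascending: first feasible = most inclusive
    if (sum(outd >= d) <= target) { dstar <- d; break }
  }
  if (is.na(dstar)) return(character())
  sort(names(outd)[outd >= dstar])
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the given overlap when
#' \code{|setA|} genes are drawn without replacement from a universe
#' containing \code{|setB|} "successes".
#'
#' @param setA,setB Character vectors of gene ids, both subsets of
#'   \code{universe}.
#' @param universe Character vector: the background gene universe.
#' @return List with \code{overlap}, \code{p_value}, \code{universe_size},
#'   \code{set_a_size}, \code{set_b_size}.
#' @examples
#' u <- letters[1:10]
#' overlapTest(letters[1:4], letters[c(1:3, 5, 6)], u)
#' @export
overlapTest <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  ov <- length(intersect(setA, setB))
  p <- stats::phyper(ov - 1, length(setB),
                     length(universe) - length(setB), length(setA),
                     lower.tail = FALSE)
  list(overlap = ov, p_value = p, universe_size = length(universe),
       set_a_size = length(setA), set_b_size = length(setB))
}

#' Write node and edge tables of a network
#'
#' The edge table holds (modulator, target, cmi, p_value); the node table
#' holds (gene, in_degree, out_degree, is_hub).
#'
#' @param net A \linkS4class{DependencyNetwork}.
#' @param edgePath,nodePath Output paths.
#' @param hubs Optional character vector of hub gene ids.
#' @return Invisibly, a list of the two paths.
#' @export
writeNetwork <- function(net, edgePath, nodePath, hubs = character()) {
  utils::write.table(networkEdges(net), edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- networkNodes(net)
  nd <- data.frame(gene = nodes,
                   in_degree = nodeDegrees(net, "in"),
                   out_degree = nodeDegrees(net, "out"),
                   is_hub = as.integer(nodes %in% hubs))
  utils::write.table(nd, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = edgePath, nodes = nodePath))
}

#' Read a network back from its edge table
#' @param edgePath Path written by \code{\link{writeNetwork}} or
#'   \code{\link{writeDependencyPairs}}.
#' @return A \linkS4class{DependencyNetwork}.
#' @export
readNetwork <- function(edgePath) {
  e <- utils::read.delim(edgePath, colClasses = c("character", "character",
                                                  "numeric", "numeric"))
  names(e) <- c("modulator", "target", "cmi", "p_value")
  buildNetwork(e)
}
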