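#' @import methods
NULL

#' DependencyNetwork: a directed modulator-to-target gene network
#'
#' Holds the significant directed dependency pairs as an edge table
#' (modulator, target, cmi, p_value) together with the node set. The edge
#' B -> A means the association between gene A and the phenotype depends on
#' the expression stratum of gene B; the CMI score is the edge weight.
#'
#' @slot edges data.frame with columns \code{modulator}, \code{target},
#'   \code{cmi}, \code{p_value}; one row per directed edge.
#' @slot nodes character vector of all gene ids appearing in the network.
#' @exportClass DependencyNetwork
setClass("DependencyNetwork",
         representation(edges = "data.frame", nodes = "character"))

setValidity("DependencyNetwork", function(object) {
  e <- object@edges
  need <- c("modulator", "target", "cmi", "p_value")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) > 0) {
    if (any(e$modulator == e$target)) return("self-loops are not allowed")
    key <- paste(e$modulator, e$target, sep = "\r")
    if (anyDuplicated(key)) return("duplicate ordered edge")
    if (!all(c(e$modulator, e$target) %in% object@nodes))
      return("edge endpoints missing from node set")
  }
  if (anyDuplicated(object@nodes)) return("duplicate node ids")
  TRUE
})

#' @describeIn DependencyNetwork-class Number of directed edges.
#' @param object A \code{DependencyNetwork}.
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname DependencyNetwork-class
#' @export
setMethod("numEdges", "DependencyNetwork", function(object) nrow(object@edges))

#' @describeIn DependencyNetwork-class Node identifiers.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname DependencyNetwork-class
#' @export
setMethod("networkNodes", "DependencyNetwork", function(object) object@nodes)

#' @describeIn DependencyNetwork-class Edge table
#'   (modulator, target, cmi, p_value).
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname DependencyNetwork-class
#' @export
setMethod("networkEdges", "DependencyNetwork", function(object) object@edges)

setMethod("show", "DependencyNetwork", function(object) {
  cat("DependencyNetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "directed edges\n")
  if (nrow(object@edges) > 0) {
    cat("  CMI range:",
        sprintf("[%.4f, %.4f]", min(object@edges$cmi), max(object@edges$cmi)),
        "\n")
  }
})

#' GeneSignature: Cox-selected prognostic genes with coefficient signs
#'
#' A signature is a set of genes with run-averaged univariate Cox
#' coefficients; the sign of the coefficient decides whether a gene's
#' expression adds to or subtracts from the risk score.
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{cox_beta},
#'   \code{cox_p}, \code{stability}.
#' @exportClass GeneSignature
setClass("GeneSignature", representation(genes = "data.frame"))

setValidity("GeneSignature", function(object) {
  g <- object@genes
  need <- c("gene_id", "cox_beta", "cox_p", "stability")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id)) return("duplicate gene ids")
  if (nrow(g) > 0 &&
      (any(g$stability < 0, na.rm = TRUE) ||
       any(g$stability > 1, na.rm = TRUE)))
    return("stability must lie in [0, 1] where known")
  TRUE
})

#' @describeIn GeneSignature-class Gene table of the signature.
#' @param object A \code{GeneSignature}.
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))

#' @rdname GeneSignature-class
#' @export
setMethod("signatureGenes", "GeneSignature", function(object) object@genes)

#' @describeIn GeneSignature-class Ids of genes with positive Cox
#'   coefficients.
#' @export
setGeneric("positiveGenes", function(object) standardGeneric("positiveGenes"))

#' @rdname GeneSignature-class
#' @export
setMethod("positiveGenes", "GeneSignature",
          function(object) object@genes$gene_id[object@genes$cox_beta > 0])

#' @describeIn GeneSignature-class Ids of genes with negative Cox
#'   coefficients.
#' @export
setGeneric("negativeGenes", function(object) standardGeneric("negativeGenes"))

#' @rdname GeneSignature-class
#' @export
setMethod("negativeGenes", "GeneSignature",
          function(object) object@genes$gene_id[object@genes$cox_beta < 0])

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature with", nrow(object@genes), "genes (",
      length(positiveGenes(object)), "positive /",
      length(negativeGenes(object)), "negative coefficients )\n")
})

setMethod("length", "GeneSignature", function(x) nrow(x@genes))

#' RiskPartition: samples split into low- and high-risk halves
#'
#' Samples are sorted by risk score (stable in input order for ties); the
#' lower ceiling(n/2) form the low-risk group, the rest the high-risk group.
#'
#' @slot sample_ids character vector of sample ids, in input order.
#' @slot risk numeric risk score per sample.
#' @slot group factor with levels \code{low}, \code{high}.
#' @exportClass RiskPartition
setClass("RiskPartition",
         representation(sample_ids = "character", risk = "numeric",
                        group = "factor"))

setValidity("RiskPartition", function(object) {
  n <- length(object@sample_ids)
  if (length(object@risk) != n || length(object@group) != n)
    return("sample_ids, risk and group must have equal length")
  if (!identical(levels(object@group), c("low", "high")))
    return("group levels must be low, high")
  nl <- sum(object@group == "low")
  if (n > 0 && nl != ceiling(n / 2))
    return("low group must hold ceiling(n/2) samples")
  if (n > 0 && nl > 0 && nl < n &&
      max(object@risk[object@group == "low"]) >
      min(object@risk[object@group == "high"]) + 1e-12)
    return("every low-group risk must be <= every high-group risk")
  TRUE
})

#' @describeIn RiskPartition-class Group labels, named by sample id.
#' @param object A \code{RiskPartition}.
#' @export
setGeneric("riskGroups", function(object) standardGeneric("riskGroups"))

#' @rdname RiskPartition-class
#' @export
setMethod("riskGroups", "RiskPartition", function(object) {
  stats::setNames(object@group, object@sample_ids)
})

#' @describeIn RiskPartition-class Risk scores, named by sample id.
#' @export
setGeneric("riskScores", function(object) standardGeneric("riskScores"))

#' @rdname RiskPartition-class
#' @export
setMethod("riskScores", "RiskPartition", function(object) {
  stats::setNames(object@risk, object@sample_ids)
})

setMethod("show", "RiskPartition", function(object) {
  cat("RiskPartition:", sum(object@group == "low"), "low /",
      sum(object@group == "high"), "high risk samples\n")
})
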