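#' Parameters for the CMI dependency screen
#'
#' Bundles the tuning constants of the conditional mutual-information screen:
#' the fraction of samples in each modulator stratum, the number of
#' permutations for the significance test, the significance level, and the
#' RNG seed.
#'
#' @param stratumFraction Fraction of samples in each of the bottom and top
#'   modulator strata. Must lie in (0, 0.5].
#' @param nPermutations Number of permutations for the null distribution.
#' @param alpha Significance level applied to permutation p-values.
#' @param seed Integer seed controlling the permutation stream.
#' @return A list of class \code{CMIParams}.
#' @examples
#' cmiParams(nPermutations = 200, seed = 7)
#' @export
cmiParams <- function(stratumFraction = 0.35, nPermutations = 1000,
                      alpha = 0.05, seed = 1L) {
  stopifnot(stratumFraction > 0, stratumFraction <= 0.5,
            nPermutations >= 1, alpha > 0, alpha < 1)
  structure(list(stratumFraction = stratumFraction,
                 nPermutations = as.integer(nPermutations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "CMIParams")
}

#' Parameters for hub selection
#'
#' @param hubFraction Maximum fraction of network nodes that may be called
#'   hubs (selection never exceeds it).
#' @param minOutDegree Smallest out-degree a hub may have.
#' @return A list of class \code{HubParams}.
#' @examples
#' hubParams()
#' @export
hubParams <- function(hubFraction = 0.20, minOutDegree = 4L) {
  stopifnot(hubFraction > 0, hubFraction <= 1, minOutDegree >= 0)
  structure(list(hubFraction = hubFraction,
                 minOutDegree = as.integer(minOutDegree)),
            class = "HubParams")
}

#' Parameters for resampled Cox candidate selection
#'
#' @param nRuns Number of resampling runs.
#' @param subsampleFraction Fraction of samples drawn (without replacement)
#'   per run.
#' @param perRunAlpha Per-run significance level for the univariate Cox
#'   Wald p-value.
#' @param stabilityThreshold Minimum fraction of significant runs a gene
#'   needs to enter the candidate list.
#' @param seed Integer seed; run \code{r} uses a stream derived from
#'   \code{(seed, r)} so partial reruns reproduce.
#' @return A list of class \code{ResamplingParams}.
#' @examples
#' resamplingParams(nRuns = 100, seed = 3)
#' @export
resamplingParams <- function(nRuns = 400, subsampleFraction = 0.75,
                             perRunAlpha = 0.05, stabilityThreshold = 0.90,
                             seed = 1L) {
  stopifnot(nRuns >= 1, subsampleFraction > 0, subsampleFraction <= 1,
            perRunAlpha > 0, perRunAlpha < 1,
            stabilityThreshold > 0, stabilityThreshold <= 1)
  structure(list(nRuns = as.integer(nRuns),
                 subsampleFraction = subsampleFraction,
                 perRunAlpha = perRunAlpha,
                 stabilityThreshold = stabilityThreshold,
                 seed = as.integer(seed)),
            class = "ResamplingParams")
}

#' Parameters for the Dscore
#'
#' The Dscore sums \eqn{-\log_{10} p} over datasets; p-values below
#' \code{pFloor} are raised to it to keep the contribution of any single
#' dataset finite (at most \eqn{-\log_{10}} of the floor).
#'
#' @param pFloor Numerical floor applied to each p-value (default 1e-17).
#' @return A list of class \code{DscoreParams}.
#' @examples
#' dscoreParams()
#' @export
dscoreParams <- function(pFloor = 1e-17) {
  stopifnot(pFloor > 0, pFloor < 1)
  structure(list(pFloor = pFloor, logBase = 10), class = "DscoreParams")
}
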