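# depnet

Phenotype-specific gene dependency networks and hub-based prognostic
signatures from expression and survival data.

## The problem

Standard network inference asks whether gene B regulates gene A's
expression. In cancer cohorts the more useful question is often
conditional: does gene B's level *gate* how strongly gene A's expression
tracks a clinical phenotype such as 5-year distant metastasis? Genes that
modulate many such gene–phenotype links behave like drivers even when their
own expression barely correlates with outcome — which is exactly why
signatures built from the most outcome-correlated genes tend to collapse on
independent cohorts.

depnet is for computational biologists with a genes × samples expression
matrix, matching time-to-event clinical data, and a candidate pair list
(typically protein–protein interactions). It infers a directed **gene
dependency network**, characterizes its hubs, and turns the
outcome-associated hubs into a prognostic signature evaluated across
cohorts.

## The method

For each candidate pair, samples are sorted by the modulator B's
expression. With the target A binarized at its per-gene median and the
phenotype P dichotomized at a survival horizon (default 5 years), the
plug-in mutual information I(A; P), in bits, is computed in the bottom and
top 35% strata of B:

    CMI = | I_high(A; P) − I_low(A; P) |

Significance comes from jointly permuting the (A, P) pairs against B
(preserving the marginal A–P association, breaking only its dependence on
B), with p = min(1, (1 + #{null ≥ obs})/N). Significant directions B → A
form the network; hubs are selected by out-degree cutoff (top ~20%, minimum
out-degree 4) on the main weakly connected component.

Prognostic genes are selected by resampled univariate Cox regression (400
runs on 75% subsamples; kept if Wald p < 0.05 in ≥ 90% of runs), then
intersected with the hubs. Each sample's risk score is the unweighted GGI-style
sum Σ x(positive-β genes) − Σ x(negative-β genes); cohorts are split at the
median rank into equal risk groups and compared by log-rank test. Cross-cohort
performance is summarized by

    Dscore = Σ_i −log10 max(p_i, 1e-17)

with random-signature null distributions (whole-genome or candidate-pool
draws) for significance.

## Worked example

```r
library(depnet)

# synthetic cohort with 4 planted modulator-gated pairs among 40 genes
d <- generateDependencyDataset(generatorConfig(nSamples = 300, nGenes = 40,
  nModulatedPairs = 4, gateStrength = 1, seed = 7))
pairs <- screenPairs(d$expr, d$status, d$candidates,
                     cmiParams(nPermutations = 200, seed = 7))
head(pairs[order(pairs$p_value, -pairs$cmi), ], 5)
#>   modulator target   cmi p_value
#> 8     g0007  g0008 1.000   0.005
#> 2     g0001  g0002 0.998   0.005
#> 4     g0003  g0004 0.992   0.005
#> 6     g0005  g0006 0.945   0.005
#> 3     g0004  g0003 0.103   0.005
```

All four planted directions top the list with CMI near 1 bit (the
target–phenotype association is perfect in one modulator stratum and absent
in the other) at the smallest achievable p-value, 1/200. The fifth row is a
reverse direction picked up at a much weaker score.

```r
# survival side: 3 planted hazard genes shared by 3 cohorts
fam <- generateSurvivalFamily(generatorConfig(nSamples = 200, nGenes = 40,
  nModulatedPairs = 0, nHazardGenes = 3, hazardBeta = 0.8,
  censoringRate = 0.2, nDatasets = 3, seed = 7))
cand <- resampledCandidateSelection(fam$datasets[[1]]$expr,
  fam$datasets[[1]]$clin, resamplingParams(nRuns = 50, seed = 7))
cand
#>   gene_id cox_beta    cox_p stability
#> 1   g0001    0.342 1.70e-03      1.00
#> 2   g0002    0.607 5.74e-09      1.00
#> 3   g0003    0.379 1.09e-04      1.00
#> 4   g0025    0.255 1.57e-02      0.94

sig <- hubSignature(cand, cand$gene_id)
ev <- evaluateSignature(sig, fam$datasets[-1])
ev$table
#>    dataset hazard_ratio ci_low ci_high logrank_p
#> 1 dataset2         3.57   2.52    5.04  3.32e-14
#> 2 dataset3         3.89   2.74    5.51  7.58e-16
round(ev$dscore, 4)
#> [1] 28.5989
```

The three planted hazard genes are perfectly stable across resampling runs
(one background gene sneaks in at stability 0.94); the resulting signature
separates the two held-out cohorts into risk groups with hazard ratios
near 3.6–3.9, and the Dscore adds the two −log10 p contributions.

A command-line wrapper ships in `exec/depnet` with subcommands
`make-fixtures`, `network`, `signature` and `evaluate`, driven by a flat
`key = value` config file plus `--seed` / `--alpha` / `--permutations` /
`--runs` overrides; every run writes a manifest with parameters, seed and
input checksums.

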