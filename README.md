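# SpotBlock

Joint Bayesian bi-clustering of spatially resolved transcriptomics (SRT)
count matrices with gene selection. Given a genes × spots count matrix and
the spot coordinates, SpotBlock simultaneously

* partitions the spots into `K` spatially contiguous **domains**,
* partitions the informative (**discriminating**) genes into `R` groups,
  and
* separates out **non-discriminating genes** — genes whose normalized mean
  is constant across the tissue — into a null set,

in one generative model, avoiding the double-dipping of
cluster-then-test pipelines. It is aimed at analysts of ST / 10x Visium /
STARmap-style data who want spatial domains *and* the marker-gene groups
that explain them, with honest uncertainty from MCMC.

## The model

Counts follow a Poisson latent block model. With spot labels
`z_i ∈ {1..K}`, gene labels `ρ_j ∈ {0, 1..R}` (0 = non-DG):

```
y_ji | z_i = k, ρ_j = r  ~  Poi(s_i g_j μ_rk)      (r ≥ 1)
y_ji | ρ_j = 0           ~  Poi(s_i g_j μ_0)
```

where `s_i` (spot depth share, Σ s_i = 1) and `g_j` (gene total) are
plug-in scaling factors and `μ_rk` is the normalized mean of block
`(r, k)`. Conjugate Gamma priors on all block means are integrated out
analytically, so a collapsed Gibbs sampler (C++ core) explores only the
discrete labels and the null probability `π_0`. Spot labels carry a Markov
random field prior on the lattice neighbourhood graph (interaction `h`,
abundances `b_k`); gene labels carry a zero-inflated Pólya urn prior with
`π_0 ~ Beta(α_π, β_π)`. Partitions are summarised by posterior pairwise
co-clustering probabilities (PPM) pooled over chains, and `K`, `R` are
selected by a modified integrated completed likelihood (mICL) grid search.
A synthetic-data generator with full ground truth and evaluation metrics
(adjusted Rand index, DG confusion) round out the toolkit.

## A worked example

```r
library(SpotBlock)

sim <- simulateSRT(width = 10, height = 10, p = 150, K = 3, R = 2,
                   delta = 3, pi0 = 0.2, seed = 7)
fit <- spotBlock(sim$counts, coords = sim$coords, K = 3, R = 2,
                 iters = 1000, burnin = 500, nChains = 2, seed = 7)
fit
#> SpotBlockFit: 100 spots, 150 genes; K = 3  R = 2
#>   domains: 40/30/30  gene groups (0 = non-DG): 65/58/27
#>   pi0_hat = 0.445  ( 65 genes in the null set )
#>   chains pooled: 2
adjustedRandIndex(spotDomains(fit), sim$z_true)
#> [1] 1
adjustedRandIndex(geneGroups(fit), sim$rho_true)
#> [1] 0.8061078
round(blockMeans(fit), 3)
#>       [,1]  [,2]  [,3]
#> [1,] 0.850 1.115 1.005
#> [2,] 1.386 0.727 0.959
```

The three spatial domains are recovered exactly (spot ARI 1). Gene-group
recovery is good but not perfect (ARI 0.81): the estimated null set (65
genes) absorbs some true group members whose depth-adjusted profiles are
nearly flat — see the vignette's discussion of identifiability under
total-count normalisation. `blockMeans()` is on the normalized scale
(global depth and per-gene level are absorbed by the plug-in factors), so
entries spread around 1; within a gene group, the profile across domains
is what distinguishes it.

Model-order selection and fit artifacts:

```r
sel <- selectModel(sim$counts, buildLatticeAdjacency(sim$coords), 
                   Krange = 2:4, Rrange = 1:3, iters = 1000, burnin = 500, seed = 7)
bestModel(sel)         # named c(K =, R =) with the lowest mICL
writeFit(fit, "out/")  # spot_labels.csv, gene_labels.csv, mu_hat.csv, summary.json
```

A command-line front end with `simulate | fit | select | evaluate`
subcommands is installed at `inst/scripts/spotblock.R`.

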