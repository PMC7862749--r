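# zinlda

Zero-inflated latent Dirichlet allocation for sparse microbiome count
matrices.

## What problem this solves

Microbial count tables (samples × taxa, e.g. genus-level 16S data) mix two
kinds of zeros: taxa that truly do not belong to a subcommunity
(*structural zeros*) and taxa that belong with low probability but were
missed at finite sequencing depth (*sampling zeros*). Topic models such as
LDA recover the subcommunity structure — each subcommunity is a
distribution β⁽ʲ⁾ over taxa, each sample mixes subcommunities with weights
θ⁽ᵈ⁾, and every sequencing read picks a subcommunity and then a taxon —
but the Dirichlet prior on β smooths every entry to be strictly positive,
erasing the distinction. `zinlda` replaces that prior with a
**zero-inflated generalized Dirichlet** (ZIGD): each stick-breaking
variable Qᵢ is 0 with probability π and Beta(a, b) otherwise, so profile
entries can be *exactly* zero, with indicator Δᵢⱼ = I(βᵢⱼ = 0) marking
structural zeros. Inference is a collapsed Gibbs sampler over read
assignments z and indicators Δ jointly, both conjugate pieces (θ, β)
integrated out.

For whom: anyone decomposing a nonnegative count matrix into sparse
"topic" profiles with an explicit presence/absence posterior — microbiome
subcommunity analysis being the motivating case.

## Worked example

```r
library(zinlda)
set.seed(11)

# simulate a small cohort from the zinLDA generative process,
# keeping the ground truth
sim <- simulate_zinlda(D = 12, V = 15, K = 2,
                       depth_min = 200, depth_max = 400)
sim
#> Simulated cohort: 12 samples x 15 taxa, 2 subcommunities
#> depths: 207 - 397  structural zeros in truth: 11

fit <- zinlda(sim, K = 2, n_iter = 60, burn_in = 30)
fit
#> Zero-inflated LDA fit
#>   12 samples x 15 taxa, K = 2 subcommunities
#>   hyperparameters: alpha = 25, pi = 0.4, a = 0.05, b = 10
#>   chain: 60 iterations (30 burn-in, thin 1, 30 retained)
#>   structural zeros in beta-hat: 6 of 30 entries
```

`coef(fit)` is the K × V profile matrix with exact zeros where the
posterior mean of Δ is at least 0.5 (`fit$pi_hat` holds those posterior
means); `fit$theta` holds per-sample mixture weights. The estimated
structural zeros can be scored against the simulation truth after
resolving label switching:

```r
perm <- match_communities(sim$beta, fit$beta)   # greedy Pearson matching
structural_zero_metrics(sim$delta, fit$delta_hat, match = perm)
#> structural-zero confusion: tp 5 fp 1 tn 18 fn 6
#> sensitivity 0.455  specificity 0.947  ppv 0.833  npv 0.750
```

Five of the eleven true structural zeros are recovered with one false
positive — a small cohort at shallow depth leaves little evidence per
cell. At the reference design (150 samples, depths 5000–25000,
well-separated profiles) recovery is far stronger, rising toward the
0.8–0.9 range as the chain lengthens; the acceptance script below
recomputes those metrics at a stated desk-scale chain length.

Model fit is assessed by posterior predictive checks against an LDA
baseline:

```r
lda <- lda_gibbs(sim, K = 2, n_iter = 60, burn_in = 30)
ppc_z <- ppc_summary(sim$counts, simulate(fit, nsim = 50, seed = 1))
ppc_l <- ppc_summary(sim$counts, simulate(lda, nsim = 50, seed = 1))
plot(ppc_z, ppc_l, labels = c("zinLDA", "LDA"))   # asinh counts per sample
```

`ppc_zero_median()` condenses the over-smoothing comparison: the median
replicate count at positions observed as zero (closer to zero is
better). On cohorts with real structural sparsity and non-trivial depth
the zero-inflated fit reproduces observed zeros that LDA smooths upward;
the package's test suite asserts that direction on a full-size simulated
cohort.

A thin command-line wrapper ships in `inst/exec/zinlda`
(`simulate`, `fit-lda`, `fit-zinlda`, `filter`, `ppc`, `eval`); see
`?zinlda_cli`.

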