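---
title: "Zero-inflated LDA for microbiome count matrices: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflated LDA for microbiome count matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A 16S rRNA survey reduces each biological sample to a vector of taxon
counts. Two features dominate such matrices: they are mixtures (a gut
sample is not one community but several co-occurring assemblages in varying
proportions), and they are extremely sparse. Crucially, the zeros are of
two kinds. A *structural zero* is a taxon that genuinely does not belong
to a subcommunity; a *sampling zero* is a taxon that belongs with low
probability but was missed at finite sequencing depth. Latent Dirichlet
allocation (LDA) captures the mixture structure — each subcommunity is a
distribution $\beta^{(j)}$ over the $V$ taxa, each sample draws mixture
weights $\theta^{(d)}$, and every read picks a subcommunity and then a
taxon — but its Dirichlet prior forces every entry of $\beta$ to be
strictly positive, smoothing true absences into small positive
probabilities. This package implements the zero-inflated variant
(zinLDA), which replaces the Dirichlet prior on the rows of $\beta$ with a
zero-inflated generalized Dirichlet (ZIGD) so that entries can be exactly
zero, and the model can say *which* zeros are structural.

## The ZIGD prior

A composition of length $V$ is built from $V-1$ independent stick-breaking
variables $Q_i$. Each $Q_i$ is exactly $0$ with probability $\pi$ and
otherwise $\mathrm{Beta}(a,b)$; then

$$\beta_1 = Q_1,\qquad \beta_i = Q_i \prod_{l<i}(1-Q_l),\qquad
\beta_V = \prod_{l<V}(1-Q_l).$$

The indicator $\Delta_i = I(\beta_i = 0) = I(Q_i = 0)$ marks the
structural zeros. Three consequences shape the implementation:

* the last component absorbs the remaining stick and is never zero, so
  indicators exist only for positions $1,\dots,V-1$;
* the construction is order-sensitive. We take the column order of the
  input count matrix as the stick order, record it in every fit manifest,
  and never reorder taxa silently;
* structural zeros are represented as true floating-point zeros plus the
  $\Delta$ mask — never as small positive values — so $\Delta = I(\beta=0)$
  is exactly testable.

With $\pi = 0$ the ZIGD is the generalized Dirichlet, and at the nesting
point $a=\eta,\ b_i=\eta(V-i)$ the generalized Dirichlet is the symmetric
$\mathrm{Dirichlet}(\eta)$. The sampling function `rzigd()` accepts a
vector `b` so this nesting can be exercised directly; the *fitted* model
keeps $(\pi, a, b)$ as symmetric scalars.

## Collapsed Gibbs sampling

Both $\beta$ and $\theta$ are conjugate to the multinomial and are
integrated out. The chain state is the per-read subcommunity assignment
$z_{dn}$ together with the indicator matrix $\Delta$ ($K \times V$). Writing
$n_j^{(i)}$ for reads of taxon $i$ in community $j$ and $m_j^{(d)}$ for
reads of sample $d$ in community $j$, a read of taxon $i$ is reassigned
with probability proportional to

$$\hat\beta_{ij}^{(-n)} \cdot
\frac{m_{j,-n}^{(d)}+\alpha}{m_{\cdot,-n}^{(d)}+K\alpha},$$

where $\hat\beta^{(-n)}_{ij}$ is the stick-breaking posterior mean of the
community's taxon distribution with the read removed: for a support member
$i$ it is $\frac{a+n_j^{(i)}}{a+n_j^{(i)}+b_{ij}}$ times the product of the
complementary factors of earlier support members, with
$b_{ij} = b + \sum_{t > i} n_j^{(t)}$; it is exactly $0$ off support.
An indicator can switch on only where the community holds no reads of the
taxon, with probability
$\pi \big/ \big(\pi + (1-\pi)\,B(a, b_{ij})/B(a,b)\big)$, the Beta-function
ratio evaluated in log space.

One design note on the trailing sum $b_{ij}$: we take it over *all* later
positions, including the terminal one. This is the form implied by
ZIGD–multinomial conjugacy — it is the only choice for which the two full
conditionals are the conditionals of a single joint posterior — and it is
validated in the test suite by comparing long-run chain frequencies on
fully enumerable instances ($V=3$, $K=2$, a handful of reads) against the
exact posterior computed in closed form, and the assignment conditional
against exact joint-probability ratios at $10^{-10}$. Because
$\Delta_{ij}=1$ forces $n_j^{(i)}=0$, the sum is identical whether taken
over all taxa or support members only; the sampler's `check` mode asserts
the underlying invariant every sweep.

Each iteration performs a full systematic scan of reads (decrement →
sample → increment) and then a full scan of indicators in fixed
(community, ascending taxon) order; given $z$ the indicators are
conditionally independent, so the scan order affects nothing but
reproducibility.

### Mixing moves

The per-read scan alone mixes very poorly between the two modes of a
(community, taxon) cell — "taxon present" and "taxon absent". An occupied
cell is self-reinforcing (its posterior-predictive mass grows with its
count), and a switched-on indicator blocks re-entry while itself being
strongly held in place by the trailing-count evidence; moving between the
modes requires many reads to cross together, which one-read-at-a-time
updates essentially never do. Chains initialised at a simulation's ground
truth sit stably at the posterior's structural-zero recovery level, while
identically specified chains started from an LDA fit take thousands of
sweeps to approach it — a textbook entropy barrier, not a wrong
stationary distribution (the enumeration tests confirm the kernel
targets the exact posterior).

Each sweep therefore also applies two Metropolis–Hastings block moves,
both leaving the posterior invariant and both validated against the
enumeration oracle:

* **taxon-block exchange** — move *all* reads of one taxon held by one
  community to a community currently holding none, exchanging the two
  cells' indicators along with the reads (the proposal is an involution
  on cell pairs, so it is symmetric and the Bernoulli prior cancels);
* **pair repartition** — for one taxon and one community pair, re-assign
  every read of that taxon held by the pair via an informed sequential
  urn (per-sample Dirichlet-multinomial affinity times a
  rich-get-richer count term), and resample the pair's indicators for
  sides left empty. The same urn replay scores the current assignment,
  making this an independence-type MH step that can move a taxon's whole
  allocation — including across an evidence-locked indicator — in one
  accepted move.

The move pass is cheap relative to the read scan and is repeated
`move_reps` times per sweep (default 10); `block_moves = FALSE` recovers
the plain two-scan sampler. One practical consequence deserves emphasis:
because the plain sampler is near-frozen at realistic scale, published
structural-zero recovery figures for this model family are sensitive to
chain length and initialisation. With the mixing moves, chains from
different initialisations agree, and the fully converged posterior
detects structural zeros slightly more aggressively (higher sensitivity,
lower specificity) than a short, initialisation-anchored chain would
suggest. The validation suite therefore reports its chain configuration
alongside every recovery number. Initialisation offers two further mixing
aids, `init_threshold` and `init_sharpen`, which prune or concentrate
the LDA-derived initial assignment so that candidate structural-zero
cells do not start seeded with smoothing leakage; both affect only the
starting point. The per-community posterior-mean profile is cached and
rebuilt in $O(V)$ whenever a read moves; prefix products are kept in
linear double precision rather than log space — at realistic counts the
stick products stay far above underflow, and the cached row is exactly
the per-draw profile estimate, so no separate estimation pass is needed.
If a taxon with remaining reads is transiently excluded from every
community's support (posterior-null but reachable in a finite chain), the
sampler falls back to the no-inflation conditional for that read and
counts the event rather than halting.

## Initialisation, burn-in, estimates

Following standard practice for this model family the chain is
initialised from a plain LDA fit: each read of taxon $i$ starts in
community $j$ with probability proportional to the LDA estimate
$\hat\beta^{LDA}_{ij}$, and all indicators start at zero. The LDA baseline
itself (`lda_gibbs()`) uses a uniform-random initial assignment, defaults
$\alpha = 50/K$, $\eta = 0.1$, and is the comparison model throughout.

Defaults are `n_iter = 2000`, `burn_in = 1000`, `thin = 1`; per retained
draw the sampler records the profile estimate, the mixture-weight estimate
$(m_j^{(d)}+\alpha)/(m_\cdot^{(d)}+K\alpha)$, and $\Delta$. Finalisation
averages: $\hat\theta$ is the posterior mean; $\hat\pi_{ij}$ is the mean
of the indicator draws; entries with $\hat\pi_{ij} \ge 0.5$ (tie zeroed —
the indicator is inclusive) are set to exactly zero and the remaining
posterior means renormalised within each community. A community zeroed
everywhere raises an error rather than returning an undefined profile.
The posterior mean is taken over per-draw profile estimates (not pooled
counts), matching the per-run estimator framing.

## The simulator

`simulate_zinlda()` draws $K$ ZIGD profiles, per-sample depths from a
discrete uniform (inclusive bounds), mixture weights from a symmetric
Dirichlet, and reads by the two-stage multinomial, realised as nested
multinomials over aggregated counts — exactly equidistributed with a
read-by-read loop because reads are exchangeable, and orders of magnitude
faster. Its defaults are the reference design used throughout the
package's validation: $V=120$ taxa, $D=150$ samples, depths uniform on
$[5000, 25000]$, $K=5$, $\alpha=50/K$, $(\pi,a,b)=(0.4, 0.05, 10)$ —
values chosen to mimic genus-level human-gut surveys. Under these settings
roughly a quarter of taxa are never observed at all (the simulator's
`drop_unobserved_taxa()` removes them, as a real study never sees them),
and the retained ground truth ($\theta$, $\beta$, $\Delta$, read-level
community counts) enables exact bookkeeping tests. Ground-truth $\beta$ is
*not* renormalised after column drops; comparisons use the recorded index
map, which is lossless.

What the simulator does not emulate: sequencing error, compositional
library-size artifacts, phylogenetic correlation between taxa, or
overdispersion beyond what the ZIGD mixture itself induces. Passing tests
on simulated cohorts therefore demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to real-data
misspecification.

## Evaluation machinery

* **Label matching** (`match_communities()`): mixture posteriors are
  invariant to label permutation, so estimated communities are aligned to
  a reference by greedy Pearson matching — best pair first, then best
  among the rest. Correlations are computed on raw profile rows (the
  least-assumption choice; recorded in output metadata). Ties break
  deterministically by lowest reference then estimate index;
  zero-variance rows are flagged and treated as unmatchable until forced.
  Greedy matching can differ from the optimal assignment in adversarial
  cases; with well-separated communities (the regime where evaluation is
  meaningful) they coincide, and the tests verify this against exhaustive
  search.
* **Structural-zero diagnostics** (`structural_zero_metrics()`):
  entry-wise confusion over all (community, taxon) cells with *positive =
  structural zero*; undefined ratios are reported as missing, never 0.
* **Posterior predictive checks** (`simulate()` + `ppc_summary()`): each
  replicate data set draws one retained posterior draw uniformly and
  simulates a cohort at the observed depths — the posterior predictive
  proper, not the plug-in point estimate. The test statistic is the
  per-taxon count, reported on the asinh scale in within-sample ascending
  observed order (ties by taxon index). `ppc_zero_median()` condenses the
  over-smoothing comparison: median replicate counts at observed-zero
  positions, per sample. Defaults follow the convention of simulating 100
  replicate data sets and plotting 50; both are arguments.
* **Model comparison**: `logLik()` is the plug-in mixed-multinomial
  log-likelihood $\sum_{d,i} x_{di}\log(\sum_j \hat\theta_{dj}
  \hat\beta_{ij})$ — a deliberate design choice, stated as such; it lets a
  user tabulate fits across $K$ but the package automates no selection
  rule. An observed count on a taxon zeroed in every community yields
  $-\infty$ with the offending cells attached.
* **Stability** (`stability_cosine()`): fits on independent cohorts are
  matched, then compared by mean cosine similarity of matched rows.

## Numerical and scale choices

Enumeration-based validation uses $10^5$ sweeps on instances with at most
five reads, where total-variation distance below $0.02$ separates a
correct sampler from a subtly wrong one. The package's heavier validation
runs (structural-zero recovery at the reference design, with $V=50$ and
larger `a` giving the well-separated regime; posterior-predictive
comparisons against the LDA baseline) use the reference cohort dimensions
with chains of a few hundred to ~1500 iterations and, for the
posterior-predictive direction check, reduced depths — sizes chosen so
the full validation suite completes on a desktop while the qualitative and
quantitative behaviour of interest is preserved. Chain length is the
binding resource at full depth: structural-zero posteriors equilibrate
slowly because a handful of misassigned reads block an indicator from
switching on, so short chains understate sensitivity. The acceptance
script states the problem sizes and chain lengths it uses alongside every
number it reports.

## Known limitations

* $K$ is fixed, not inferred; hyperparameters are not estimated.
* Single chain; no cross-chain convergence diagnostics beyond the
  deterministic-seed contract and the enumeration checks.
* Greedy (not optimal-assignment) label matching, by design.
* The ZIGD's order sensitivity means results can depend on taxon column
  order; the order is recorded, but no canonical ordering is imposed.
* Variational inference is out of scope; estimation is MCMC only.
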