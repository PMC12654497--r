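---
title: "Multi-kingdom microbiome subtyping with kingdomFuse: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kingdom microbiome subtyping with kingdomFuse: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the fusion model and its assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate, the
numerical choices, and the places where the design was genuinely open.

## Why fuse, and what is being fused

A shotgun-metagenomic cohort yields one taxon-by-sample count table per
kingdom. The kingdoms differ by orders of magnitude in how many taxa
they contribute (in large gut cohorts, thousands of bacterial species
against a couple hundred archaea, dozens of fungi and a few dozen
viruses), so any analysis that simply concatenates the tables is a
bacteria-only analysis in disguise. The alternative implemented here
keeps each kingdom as a separate *view* of the same patients, builds one
patient-similarity network per view, and lets the views exchange
information through iterative cross-diffusion until they agree on a
single fused network. Patient subtypes are then communities in that
fused network.

The per-view pipeline is: relative abundance (per kingdom, so each
view's composition is self-contained) → Hellinger transformation →
Bray–Curtis distance → similarity kernel. The Hellinger square root
damps the influence of dominant taxa and gives the downstream Euclidean
geometry a proper distance interpretation; Bray–Curtis is the field's
default for abundance profiles and is bounded in [0, 1].

### The similarity kernel

The default conversion from distance to similarity is the
scaled-exponential kernel used throughout the similarity-network-fusion
literature:

$$W(i,j) = \exp\!\left(-\frac{d^2(i,j)}{\mu\,\varepsilon_{ij}}\right),
\qquad
\varepsilon_{ij} = \tfrac13\!\left(\bar d_{N_K(i)} + \bar d_{N_K(j)} + d(i,j)\right),$$

where $\bar d_{N_K(i)}$ is the mean distance from $i$ to its $K$ nearest
neighbours. The local bandwidth adapts to density, which matters because
cohorts mix tight and diffuse community clusters. A plain complement
kernel ($W = 1 - d$) is retained as an ablation option
(`kernel = "complement"`).

### Kingdom weights

The fusion is *weighted*: each view's kernel enters the diffusion and
the final average with a weight derived from its taxon count $m_k$. Two
candidate schemes bracket the design space. Proportional weights
$m_k/\sum m$ would give bacteria ≈ 95% of the weight at realistic
kingdom sizes, reducing the method to bacterial clustering — exactly
what multi-kingdom fusion exists to avoid. Equal weights ignore the very
real information asymmetry. The default is the compromise
$w_k = \log_{10}(1+m_k)/\sum_l \log_{10}(1+m_l)$: monotone in kingdom
size, but compressed so the small kingdoms stay numerically relevant
(at taxon counts 200/40/30/20 the weights are roughly
0.34/0.24/0.22/0.20). All three schemes are exposed
(`weightScheme = "log" | "proportional" | "equal"`).

### The diffusion and its normalization

Each view keeps two operators: the full kernel $P_k$ (row-normalized
with half the mass on the diagonal, the standard stabilizing convention)
and the sparse local kernel $S_k$ (row-normalized over the $K$ nearest
neighbours, zero elsewhere). One iteration updates

$$P_k \leftarrow S_k \left(\frac{\sum_{l \neq k} w_l P_l}
{\sum_{l \neq k} w_l}\right) S_k^\top,$$

i.e. each view diffuses the *weighted* consensus of the other views
through its own neighbourhood graph — the weights act inside every
iteration, not only in the final average. Iteration stops after `T`
rounds or when no kernel moves by more than `tol` in max norm.

The update must leave every kernel symmetric, non-negative and
row-stochastic. Plain row normalization destroys symmetry and plain
symmetrization destroys row sums, so the normalization step here is
symmetric Sinkhorn scaling, $M \leftarrow M / \sqrt{d\,d^\top}$ iterated
to convergence: it preserves symmetry exactly and drives every row sum
to 1 (tolerance 1e-12, at most 500 sweeps). The initial kernels receive
the same normalization, which makes two useful identities exact: with
`T = 0` the fused output is precisely the weighted average of the
initial normalized kernels, and a single view (or one view holding all
the weight — zero-weight views are dropped before diffusion) returns its
own normalized kernel unchanged. Both identities are asserted in the
test suite, as are the per-iteration invariants (non-negativity,
symmetry to 1e-9, row sums to 1e-9), which are checked inside the loop
on every iteration.

### Choosing the number of subtypes

The fused matrix is clustered by normalized spectral clustering: the
top-$k$ eigenvectors of $D^{-1/2} W D^{-1/2}$, rows unit-normalized,
k-means with at least 10 restarts under a fixed seed. Candidate $k$
values (default 2–8) are scored by the mean silhouette computed on the
surrogate distance $1 - \tilde W$, where $\tilde W$ is the fused matrix
rescaled to [0, 1] over off-diagonal entries with a zero diagonal; the
chosen $k$ maximizes the score, ties going to the smallest $k$, and
singleton clusters score 0 by convention. Cluster names are assigned by
size (C1 largest), with exact ties broken by the lexicographically
smallest member id, so labels are reproducible.

### Defaults

`K = 20` neighbours (capped at $n/3$ for small cohorts), `mu = 0.5`,
`T = 20` iterations, `tol = 1e-6`. These are standard
similarity-network-fusion practice; the method is not sensitive to them
within reasonable ranges, and they are all exposed in
`fusionConfig()`.

## Preprocessing

The order of operations is rarefy → sample-richness filter →
taxon-prevalence filter → relative abundance → Hellinger. Rarefaction
comes first because the richness screen counts *observed* taxa, which is
depth-dependent; prevalence is filtered after the sample screen so that
discarded samples cannot distort prevalence estimates.

* **Rarefaction** pools all kingdoms per sample and draws exactly
  `depth` reads without replacement (vegan's `rrarefy`, so per-taxon
  expectations are hypergeometric: $\mathbb{E}[c_i] = \text{depth}\cdot
  c_i/\text{total}$). Pooling is deliberate: sequencing depth is a
  whole-sample property, not a per-kingdom one. Samples below depth are
  dropped and reported. At cohort scale the conventional depth is the
  minimum library size; the pipeline default for desk-scale synthetic
  data is 50,000 reads.
* **Richness filter**: a sample is kept iff its number of nonzero taxa
  *summed over all kingdoms* is strictly greater than `minSpecies`
  (default 300, the cohort-scale screen; the strict inequality is
  intentional). A per-kingdom reading would contradict a single
  species-count cutoff.
* **Prevalence filter**: a taxon is kept iff present (count > 0) in at
  least `ceiling(minPrevalence * n)` samples, per kingdom, default 10%.
  Presence is evaluated after rarefaction, which is the simplest
  testable reading of prevalence.
* **Relative abundance** defaults to per-kingdom normalization for
  fusion inputs (each kingdom's Bray–Curtis is self-contained); a
  global scope is available for pooled diversity summaries.

## What the generator emulates — and what it does not

`simulateCounts()` draws, per sample, latent log-normal abundances
$z_{it} = b_t + \delta_t\,\mathbb{1}[\text{C2}] + \sigma\,\epsilon_{it}$:
a per-taxon basis $b_t \sim N(0, 2^2)$ giving a realistic
rank-abundance curve, per-taxon noise with `baseAbundanceSD`
$\sigma = 1$ (natural log), a subtype shift
$\delta_t = \pm\,\text{signalLog2FC}\cdot\ln 2$ on the planted signal
taxa, independent zero-inflation masking (default probability 0.3), and
one multinomial draw per sample at `sequencingDepth` over all kingdoms
jointly, so per-sample totals are conserved exactly. Planted taxon
pairs share a standard-normal latent factor with loadings
$\lambda_a = \sqrt{|\rho|}$, $\lambda_b = \text{sign}(\rho)\sqrt{|\rho|}$,
so the latent log-abundance correlation equals the target in closed
form. Outcomes follow the subtype: Bernoulli response, exponential
survival with a subtype hazard ratio (default 2) under independent
exponential censoring, and a PFS>6-months flag linked to response
(p = 0.75 for responders, 0.25 for non-responders — the real
generative link is unknown, and any monotone link suffices for
testing).

Two generator choices deserve justification:

* **Signal breadth.** The default plants shifts in 40% of each
  kingdom's taxa (80/16/12/8 of 200/40/30/20) at |log2FC| 2.5. The
  subtypes this package targets are community-wide states — in cohort
  data the majority of genera differ between subtypes — not a handful
  of marker shifts, and a sparse-signal default would misrepresent the
  regime the clustering operates in.
* **Scale.** Default cohorts are 60+60 samples, 290 taxa, 100,000
  reads/sample. This preserves the kingdom-size ordering and the
  compositional sparsity of real data at a size where the full test
  suite runs in seconds. The generator does *not* emulate batch or
  cohort effects, strain-level structure, phylogenetic correlation, or
  depth variation between samples; passing tests therefore demonstrate
  correctness of the machinery under the stated generative model, not
  robustness to those real-data complications.

The single shared seed drives a fixed substream per stage
(counts, metadata, rarefaction, fusion, permutation, split, models,
bootstrap), so any stage can be re-run independently without
perturbing the others' draws.

## Downstream statistics

* **Diversity.** Shannon uses the natural log (the convention of the
  ecology stack this field uses); observed species counts nonzero taxa.
  Welch t-tests compare subtypes, making no equal-variance assumption.
  PERMANOVA is implemented from its definition — pseudo-F from total and
  within-group sums of squared distances, p-value
  $(1 + \#\{F_\pi \ge F\})/(n_\pi + 1)$ over label permutations, default
  999 — and is checked against vegan's `adonis2` in the tests.
* **Outcomes.** Pearson chi-square without continuity correction for
  response and PFS contrasts (unknown outcomes dropped per test, never
  imputed); Kaplan–Meier with the simultaneous-death convention for
  ties; the two-group log-rank test with the hypergeometric variance.
  The survival package serves as the independent oracle in tests.
* **Differential abundance.** A deliberately transparent
  negative-binomial Wald test: median-of-ratios size factors (over taxa
  positive in every sample, with a library-size fallback), per-group
  normalized means, a pooled method-of-moments dispersion from
  $\mathrm{Var}(y) = \mu/f + \alpha\mu^2$ floored at 1e-8, fold change
  $\log_2((\mu_{C2}+pc)/(\mu_{C1}+pc))$ with pseudo-count
  $pc = 0.5/\mathrm{median}(f)$, a delta-method standard error and a
  two-sided normal reference. BH correction is applied jointly across
  kingdoms by default (per-kingdom behind a flag; the joint pool is the
  stricter and simpler choice), and significance additionally requires
  the per-kingdom |log2FC| thresholds (1 bacteria, 0.5 archaea/fungi,
  0.25 viruses). Note the pseudo-count makes fold changes of taxa with
  near-zero group means only asymptotically invariant to global count
  rescaling; the bulk of the table is invariant, as the tests assert.
  This estimator trades the shrinkage machinery of the large packages
  for auditability; its calibration (type-I error, sensitivity, FDR
  under planted effects at twice the thresholds, n = 100+100) is
  established by simulation in the acceptance suite rather than by
  equivalence to any reference implementation.
* **Panels and classifiers.** The marker panel takes, per kingdom, the
  significant taxa with the largest |log2FC| (ties by padj, then id),
  default sizes 12 bacteria, 7 archaea, 7 fungi, 6 viruses — a 32-taxon
  multi-kingdom panel. Features are per-kingdom relative abundances
  (the simplest choice; CLR was considered and left out to keep the
  feature space interpretable). Random forest (500 trees) and RBF-SVM
  with probability scores are evaluated by stratified 10-fold
  cross-validation on the 70% training split and by ROC/AUC on the
  untouched 30% test split; AUC is the rank statistic, which equals
  trapezoidal integration of the ROC (asserted to 1e-9). The multi- vs
  single-kingdom comparison is descriptive — mean test AUC per feature
  set — with no hypothesis test, since the claim being probed is a
  trend, not a significance statement.
* **Co-occurrence.** SparCC from first principles: fractions from
  counts plus pseudo-count 0.5 (point estimate rather than Dirichlet
  averaging, for determinism), log-ratio variances
  $t_{ij} = \mathrm{Var}(\ln x_i/x_j)$, basis variances solved from the
  aggregated linear system under the sparsity assumption, correlations
  $\rho_{ij} = (\omega_i+\omega_j-t_{ij})/(2\sqrt{\omega_i\omega_j})$
  clipped to [−1, 1], and iterative exclusion of the strongest pair
  (at most 10 iterations, threshold 0.1 — the literature defaults). Two
  numerical guards: non-positive solved basis variances are floored at
  machine epsilon with a warning (a known degeneracy), and a pair is
  never excluded if that would leave a taxon with three or fewer
  included partners, which can make the system exactly singular at
  small taxon counts. Null p-values come from per-taxon permutation
  bootstraps (breaking association, preserving marginals), BH-adjusted
  on the upper triangle; edges with padj below 0.05 form the
  co-occurrence network, summarized by per-kingdom-pair strong-edge
  counts (|ρ| > 0.5) and per-kingdom maximum-degree core taxa, and
  exported as GraphML and GEXF.

## Problem sizes, determinism, limitations

The test and acceptance suites run at desk scale by design: 120-sample
cohorts for fusion properties, 200 samples for differential
calibration, up to 1000 samples for correlation recovery, 200 null
replicates for PERMANOVA calibration, 100-iteration bootstraps in the
null-rate study (the production default is 500). Every stochastic step
is seeded; identical configurations produce byte-identical outputs, and
the pipeline manifest records md5 hashes to make that checkable.

Known limitations: the NB test uses a per-taxon moment dispersion with
no information sharing, so it is noisier than shrinkage estimators at
small n; SparCC's sparsity assumption breaks under dense correlation
structure, where the exclusion heuristic only partially compensates;
silhouette-based model selection cannot distinguish k = 1 from k = 2
(it never considers k = 1, so a null cohort still receives two labels —
the silhouette magnitude, not the labels, is the evidence of absent
structure); and the fusion has no notion of batch, so cohort effects in
real data must be handled upstream.
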