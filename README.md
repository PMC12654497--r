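# kingdomFuse

Multi-kingdom gut microbiome subtyping by weighted similarity network
fusion, with subtype characterization end to end.

Shotgun-metagenomic cohorts profile four microbial kingdoms at once —
bacteria, archaea, fungi and viruses — but the kingdoms come in wildly
unequal sizes (thousands of bacterial taxa versus tens of viral ones), so
naive concatenation lets bacteria drown out everything else.
`kingdomFuse` treats each kingdom as one *view* of the same patients and
fuses the views into a single patient-similarity network, then asks
whether the resulting community subtypes track clinical outcomes
(treatment response, progression-free survival, overall survival), which
taxa distinguish them, how well small multi-kingdom marker panels predict
them, and how the subtypes' co-occurrence networks differ. It is aimed at
microbiome researchers analyzing taxon-by-sample count tables, e.g. from
immune-checkpoint-inhibitor cohorts.

## The method

For each kingdom *k* the pipeline computes relative abundances, applies
the Hellinger transformation (elementwise square root), and forms the
Bray–Curtis distance matrix

&nbsp;&nbsp;&nbsp;&nbsp;d(i,j) = Σ<sub>t</sub>|x<sub>it</sub> − x<sub>jt</sub>| / Σ<sub>t</sub>(x<sub>it</sub> + x<sub>jt</sub>),

converted to a similarity by the scaled-exponential kernel
W(i,j) = exp(−d²(i,j)/(μ·ε<sub>ij</sub>)) with a K-nearest-neighbour
bandwidth ε. Each kingdom receives a weight
w<sub>k</sub> = log₁₀(1+m<sub>k</sub>)/Σ log₁₀(1+m) from its taxon count
m<sub>k</sub>, and a weighted cross-diffusion iterates

&nbsp;&nbsp;&nbsp;&nbsp;P<sub>k</sub> ← S<sub>k</sub> (Σ<sub>l≠k</sub> w<sub>l</sub>P<sub>l</sub> / Σ<sub>l≠k</sub> w<sub>l</sub>) S<sub>k</sub>ᵀ,

where S<sub>k</sub> is the row-normalized K-nearest-neighbour kernel,
re-imposing symmetry and unit row sums after every update. The fused
network Σ w<sub>k</sub>P<sub>k</sub> is clustered by normalized spectral
clustering, with the number of subtypes chosen by a silhouette scan.
Downstream, subtypes are characterized by Shannon/observed-species alpha
diversity, Bray–Curtis/Jaccard beta diversity with a permutation
PERMANOVA, chi-square outcome contrasts, Kaplan–Meier curves with the
log-rank test, a negative-binomial Wald differential-abundance test
(median-of-ratios normalization, method-of-moments dispersion, BH
correction, per-kingdom |log₂FC| thresholds of 1 / 0.5 / 0.5 / 0.25 for
bacteria / archaea+fungi / viruses), a 32-taxon multi-kingdom marker
panel evaluated by random-forest and RBF-SVM classifiers with stratified
10-fold cross-validation and held-out ROC/AUC, and SparCC compositional
correlation networks (ρ<sub>ij</sub> = (ω<sub>i</sub>+ω<sub>j</sub>−t<sub>ij</sub>)/(2√(ω<sub>i</sub>ω<sub>j</sub>)))
with permutation-bootstrap p-values.

A synthetic-data generator (`simulateCounts`, `simulateMetadata`) plants
two latent subtypes, per-kingdom abundance shifts, outcome differences,
exponential survival with a subtype hazard ratio, and taxon–taxon
correlations, so every stage is testable with known ground truth.

## Worked example

```r
library(kingdomFuse)

cfg <- simulationConfig(seed = 42)        # 60+60 samples, 290 taxa, 4 kingdoms
sim <- simulateCounts(cfg)
sim$table
#> MultiKingdomTable (counts, species level)
#>   120 samples; taxa: bacteria=200, archaea=40, fungi=30, virus=20

fit <- runWSNF(sim$table, fusionConfig(kRange = 2:5, seed = 42))
fit
#> FusionResult: 120 samples fused from 4 kingdom(s) (10 iterations)
#>   weights: bacteria=0.342, archaea=0.240, fungi=0.222, virus=0.196
#>   chosen k = 2; subtype sizes: C1=60, C2=60

mclust::adjustedRandIndex(subtypeLabels(fit), sim$truth$subtype)
#> [1] 1
```

The silhouette scan picked two subtypes and recovered the planted labels
exactly (adjusted Rand index 1). The log-scaled kingdom weights keep the
small kingdoms relevant: bacteria carry 200 of 290 taxa but only 34% of
the weight. Subtypes then differ in outcomes as planted:

```r
md <- simulateMetadata(sim$truth$subtype, cfg)
ct <- contingencyTest(md, "response", subtypeLabels(fit))
round(c(chi2 = ct$chi2, p = ct$p), 4)
#>    chi2       p
#> 16.8056  0.0000
lr <- logrankTest(md$os_months, md$death_event,
                  subtypeLabels(fit)[md$sample_id])
round(c(chi2 = lr$chi2, p = lr$p), 4)
#>   chi2      p
#> 3.9692 0.0463
```

Responders concentrate in subtype C2 (chi-square 16.8) and survival
differs (log-rank p = 0.046 at this cohort size). Differential analysis
on a stratified 70% training split flags the shifted taxa and ranks a
marker panel:

```r
d <- runDifferential(sim$table, subtypeLabels(fit), seed = 42)
d$result
#> DifferentialResult: 290 taxa tested; 120 significant (padj < 0.05 + per-kingdom |log2FC|)
#>   per kingdom: archaea=16, bacteria=83, fungi=12, virus=9
head(d$panel, 3)
#>         taxon kingdom    log2fc         padj
#> 1 archaea|a38 archaea -3.397171 2.712884e-12
#> 2  archaea|a8 archaea  2.855052 1.102181e-08
#> 3  archaea|a5 archaea -2.828205 3.456357e-09
```

`runPipeline(pipelineConfig(...))` chains all eight stages (simulate →
preprocess → cluster → diversity → outcomes → differential → predict →
network) with one seed and writes TSV outputs plus a hashed run manifest.

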