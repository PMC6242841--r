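---
title: "Models and methods: from cheese volatilome peaks to genomic architecture"
author: "volatilomeGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from cheese volatilome peaks to genomic architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volatilomeGWAS)
```

## The scientific question

Cheese flavour is largely carried by volatile organic compounds (VOCs)
released during ripening. PTR-ToF-MS profiling of the headspace of model
cheeses made from single-cow milk yields, per animal, a spectrum of peak
intensities (ppbv) indexed by m/z. If the cow's genotype explains a share of
the variation in those peaks, cheese flavour is in principle selectable.
This package implements the full analysis chain for that question: peak
preprocessing, genomic heritability, a mixed-model association scan, a
cross-trait network built from SNP effects, and gene-set enrichment — with a
synthetic-data generator so every stage can be exercised and tested without
animal data.

## Peak preprocessing

Three steps, in this order:

1. **Intensity filter.** Peaks whose mean intensity across animals is below
   1 ppbv are removed. The original filtering rule does not name the summary
   statistic; the mean is the default here and `filterPeaks(stat=)` offers
   median and max. Known interfering ions can be removed by an explicit m/z
   exclusion list — no algorithmic rule exists for them.
2. **Isotope removal.** An isotope satellite is a peak ~1.00336 m/z (the
   ^13^C spacing) above a parent, correlated with it almost perfectly.
   `removeIsotopes()` deletes the higher-m/z member of every pair with
   r > 0.95 and correlation-test p < 0.001. On top of the correlation rule
   we gate on the m/z spacing (±0.01); correlation alone would also delete
   genuinely co-varying distinct compounds. `requireSpacing = FALSE`
   restores the literal correlation-only rule.
3. **Compositional log transform.** Each animal's spectrum is converted to
   fractions of its total intensity and mapped through
   `ln((f + 1) * 1e6)`. The "+1" is applied to the fraction, following the
   stated operator order; a zero peak maps to ln(10^6) ≈ 13.8155 and a
   single-peak spectrum to ln(2×10^6) ≈ 14.5087. The transform tames the
   strong right skew of raw intensities; because cheese-VOC fractions are
   typically small, it is close to linear in f and its Gaussianising effect
   is mild — downstream inference relies on regression residuals, not on
   exact normality.

Genotype QC retains SNPs with call rate ≥ 0.95, MAF ≥ 0.005 and an exact
Hardy-Weinberg test p ≥ α/m with α = 0.001 (Bonferroni over the m SNPs
reaching that stage), applied in that order. The QC sentence in the source
literature reads, literally, as excluding markers *with* high call rates;
only the retention reading is consistent with the reported retained counts,
so that is what is implemented.

## The polygenic model and GRAMMAR-GC

For each trait y (a transformed peak or a composition trait):

$$
\mathbf{y} = \mathbf{X}\beta + \mathbf{a} + \mathbf{e},\qquad
\mathbf{a} \sim N(0, \mathbf{G}\sigma_g^2),\qquad
\mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2)
$$

with fixed effects of 30-day days-in-milk class, parity class (1, 2, 3, 4+)
and herd-date, and **G** a genomic relationship matrix. Genomic heritability
is $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.

**GRM.** The default is the frequency-weighted identity-by-state form,
$G_{ij} = m^{-1}\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k) / (2p_k(1-p_k))$, whose
diagonal averages 1 under HWE; this is the variant the GenABEL lineage uses
for variance components. Plain IBS sharing (`method = "plain-ibs"`) is
provided to mirror the literal "identity-by-state coefficients" wording.
Missing dosages are mean-imputed for the GRM only.

**REML.** The likelihood is profiled over the ratio
δ = σ²g/σ²e on the eigenbasis of **G** (one eigendecomposition, reused by
every trait), maximising over log δ ∈ [log 1e-6, log 1e6] with tolerance
1e-8. Herd-date and the other class effects enter as ordinary fixed-effect
columns of **X** (with pivoted-QR removal of rank deficiencies); at these
sample sizes the GLS solve is cheap, so no absorption trick is needed.
Boundary estimates are flagged, not errors; a GRM with a flat eigenvalue
spectrum (e.g. the identity) cannot separate the two components and is
flagged `identifiable = FALSE`.

**GRAMMAR-GC.** Three steps: (1) fit the polygenic model; (2) regress the
mixed-model residuals $\hat{\mathbf e} = \hat\sigma_e^2 \mathbf V^{-1}
(\mathbf y - \mathbf X\hat\beta)$ on each SNP dosage by simple linear
regression (missing dosages dropped pairwise — the documented asymmetry
with the GRM's imputation); (3) genomic control: λ = median(χ²)/0.4549,
corrected χ²/λ, p from the 1-df upper tail, significance at p < 5×10⁻⁵.
λ is applied as estimated, without clamping at 1: GRAMMAR residual
regression is *conservative* (λ < 1 is the expected direction) and the GC
step exists precisely to undo that; `clampLambda = TRUE` restores
conventional GC.

**Effect de-attenuation.** Because every tested SNP also sits inside the
GRM, the polygenic BLUP absorbs part of its own effect: the residual
regression estimate of the allele-substitution effect *a* is shrunk by
$\gamma_k = \sigma_e^2\, x_k' \mathbf P x_k / x_k'x_k$, where **P** is the
GLS projection of $\mathbf V^{-1}$ (the fixed effects absorb a further
share). Test statistics are nearly unaffected (the standard error shrinks
by the same factor), but $2pqa^2$ — the variance explained by a SNP — is
biased down by γ². `grammarGamma()` computes the per-SNP factors and
`varianceExplained(gamma=)` divides the effect by them before squaring;
this analytic rescaling follows the GRAMMAR-Gamma idea from the same method
family. Expressed relative to $\hat\sigma_g^2$, the result is the share of
additive genetic variance attributable to one SNP.

## The SNP-effect similarity network

The unfiltered allele-substitution effects form a SNPs × traits matrix.
Trait pairs whose effect vectors have |Pearson r| strictly above 0.80 *and*
two-sided correlation-test p < 0.01 (t transformation, df = complete pairs
− 2) are joined by an edge of weight |r|; with ~37k SNPs the p-gate is
vacuous next to the |r|-gate, but both are applied for fidelity to the
stated rule. The absolute value means strongly negative genetic
correlations cluster together. Components with ≥ 3 nodes are reported as
sub-networks.

Dense clusters are found by the cohesiveness formulation: for a node set V,

$$\mathrm{coh}(V) = \frac{w_{in}}{w_{in} + w_{boundary} + p\,|V|},$$

grown greedily (add or remove one node per step, strict improvement only)
from every node as seed in alphabetical order, skipping covered nodes —
alphabetical order also breaks ties, making detection deterministic.
Defaults: penalty p = 2, minimum size 3 (matching the ≥ 3-node reporting
convention), overlap-merge threshold 0.8 on $|A\cap B|^2/(|A||B|)$.
Surviving clusters are screened by a one-sided Mann-Whitney test of
in-cluster versus boundary edge weights at α = 0.05; a cluster with no
boundary edges is maximally separated and is assigned p = 0. Note the
screen needs a handful of boundary edges to be able to reach significance
(with one boundary edge the best achievable p is 1/(n_in+1)). Clustering is
applied to the whole graph, with components reported alongside, since the
original description does not say whether it ran per sub-network.

## Gene-set enrichment

SNPs with corrected p < 0.05 are "relevant" — a deliberately permissive
screen so that small-effect loci excluded by the genome-wide threshold
still inform the pathway level. A SNP maps to every gene whose interval
extended by 15 kb on both sides contains it (boundary inclusive: exactly
15,000 bp away is in; 15,001 is out; strand ignored, multi-assignment
allowed). The enrichment universe is the set of genes with at least one
genotyped SNP in their window — only such genes can ever be relevant, so a
wider universe would inflate enrichment. Term sizes are bounded strictly
(> 10 and < 1000 genes, counted on the universe). Each set is tested by the
one-sided hypergeometric (Fisher) upper tail with Benjamini-Hochberg FDR
across sets, enriched at q < 0.05. The length-bias weighting of goseq-style
samplers is *not* reproduced: the stated test is Fisher's exact, and that
is what is implemented. Coordinates are 1-based inclusive in memory, BED
files are converted on read/write.

## The synthetic-data generator

`simConfig()` defaults mirror the study design: 1,011 animals in 72
herd-date groups, 37,568 SNPs on 29 autosomes, 4 parity classes, 30-day DIM
classes, missingness 1%. Each trait is fixed effects + planted QTLs +
polygenic background + Gaussian noise, with the components rescaled
in-sample so the realised genetic-variance share equals the target h²
exactly; pleiotropy blocks share QTL positions with effects correlated at
`blockEffectCor` (QTL sets are disjoint across blocks, so only planted
pleiotropy creates shared signal). Peaks arise from traits via an
exponential link `exp(log(5) + 0.25·z)` — right-skewed, ~5 ppbv mean like
typical reported peaks; isotope satellites are planted at +1.00336 m/z with
ratios 0.25-0.5 of the parent (large enough to survive the 1-ppbv filter,
as real satellites of abundant parents do) plus noise keeping r > 0.95;
a few all-sub-ppbv peaks are planted for the filter to remove. Parent m/z
values are spaced ≥ 1.4 apart so no non-satellite pair mimics the isotope
spacing. Fixed-effect magnitudes are not reported anywhere, so herd-date
gets SD 0.5 and parity/DIM 0.25 phenotype-SD — herd/date is the dominant
environmental axis in this kind of field data.

What the generator deliberately does **not** emulate: linkage
disequilibrium (genotypes are in linkage equilibrium by default; an AR(1)
block-LD mode exists via `ldRho` for region-reporting tests), pedigree or
breed structure, and raw mass-spectral artefacts beyond isotope satellites.
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to LD-induced confounding.

## Test regimes and numerical choices

Recovery tests run at desk scale, with regimes set by power calculations
rather than by the full study dimensions:

* **Heritability recovery** uses one 2,000-animal × 5,000-SNP panel with 20
  replicate traits at each of h² ∈ {0, 0.10, 0.22, 0.40} — the spread of
  reported composition/VOC heritabilities; the REML sampling SD of ĥ² is
  ≈ √(2m)/n ≈ 0.05 per trait, so 20-trait means resolve ±0.05 comfortably.
* **Null calibration** pools ≥ 2×10⁶ SNP-tests (500 animals × 5,000 SNPs ×
  400 pure-polygenic traits) and checks the 5×10⁻⁵ tail within 3 binomial
  SDs and mean λ within [0.95, 1.05].
* **Variance-share recovery** plants one QTL at 60% of σ²g in a trait with
  h² = 0.22 (n = 1,000, m = 800): the relative SE of σ̂²g, √(2m)/(n·h²),
  must stay near 20% or the ratio's denominator noise dominates.
* **Network recovery** plants 3 pleiotropy blocks of 5 traits (6 shared
  QTLs each, 90% of genetic variance, within-block effect correlation 0.98)
  at n = 1,500, m = 150. Between estimated effect vectors, the
  signal-to-noise ratio scales as n·mean(2pq)·Σa²/m; |r| > 0.8 edges need
  that ratio ≳ 10, which is unattainable at full study scale in linkage
  equilibrium — in the real data LD and shared architecture do that work.
* **Enrichment power** uses 15 QTLs at h² = 0.6 (n = 600, m = 1,500) and a
  planted set of genes near the QTLs; the null control replaces relevant
  genes by random draws.

Numerical details: REML tolerance 1e-8 on log δ with bounds [1e-6, 1e6];
GRM eigenvalues clipped at 0 when numerically negative (logged);
p-values floored at the smallest positive double to avoid literal zeros
from extreme χ²; monomorphic SNPs carry NA statistics and are excluded
pairwise from the effect-correlation step; all randomness flows from a
single seed through fixed per-stage child seeds, so reruns are
byte-identical.

## A small worked run

```{r pipeline, eval = FALSE}
out <- file.path(tempdir(), "demo")
man <- runPipeline(list(paths = list(out_dir = out), seed = 1,
                        sim = list(nAnimals = 300, nSnps = 1000,
                                   nTraits = 8, h2 = 0.3, nQtl = 4)))
str(man$counts)
```

The manifest records the package version, a hash of the effective
parameters, the seed and per-stage row counts; every tabular result is a
TSV under `out_dir`, the network additionally as GraphML.

## Known limitations

* Single-trait REML only; no dominance/epistasis, no pedigree matrices.
* GRAMMAR is an approximation to exact mixed-model association; its
  residual tests are conservative before GC, and effect sizes need the
  gamma correction for unbiased variance-explained estimates.
* The enrichment test ignores gene length bias; with windowed SNP mapping,
  long genes are more likely testable *and* more likely relevant, which the
  shared universe only partly offsets.
* Linkage-equilibrium simulations cannot probe LD-driven false-positive
  clustering of association signals into regions.
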