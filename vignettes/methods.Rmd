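---
title: "Models and methods behind vesselmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesselmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vesselmix)
```

`vesselmix` analyses laser-microdissected brain microvessel transcriptomes
alongside matched whole-brain samples, in mouse and human. This vignette
explains the models the package fits, the assumptions behind them, the
parameters that matter, and the design choices made where the design was
genuinely open. It is the package's reference for *why* things are
computed the way they are; the README shows *how* to run them.

## Expression units

Counts are converted to FPKM and TPM per sample:

$$\mathrm{FPKM}_i = \frac{\mathrm{counts}_i}{L_i \sum_i \mathrm{counts}_i} \times 10^6,
\qquad
\mathrm{TPM}_i = \frac{\mathrm{FPKM}_i}{\sum_i \mathrm{FPKM}_i} \times 10^6,$$

with $L_i$ the transcript length in **kilobases**. TPM columns therefore
sum to $10^6$ exactly (the tests check conservation to a relative
$10^{-9}$), and the composition is invariant to sequencing depth. Gene
length is a required input column: the package deliberately does not
compute lengths from annotation, because alignment and counting are
upstream of its scope and different counters report different effective
lengths. Samples with zero total counts are carried through as flagged
all-zero columns rather than erroring, so degraded inputs still flow
through a pipeline run. Per-sample sums accumulate in gene order, fixing
floating-point results across runs.

Reference profiles for purified cell types are built by averaging raw
counts across all single cells of a type and then length-normalising the
average to a single TPM vector — averaging in count space first means
deep and shallow cells contribute proportionally to their evidence.

## Mixture composition of microvessel samples

A microvessel capture is modelled as a two-component mixture of
endothelial and pericyte transcripts. For a pericyte fraction
$\alpha \in [0,1]$ the blended reference is

$$\mathrm{TPM}_\alpha = \alpha\,\mathrm{TPM}_{\mathrm{peri}} + (1-\alpha)\,\mathrm{TPM}_{\mathrm{endo}},$$

and `scan_mixture_ratio()` reports the $\alpha$ maximising the Pearson
correlation with the bulk TPM vector. Choices fixed here:

- **Grid step 0.01** (parameter `step`): compositions are conventionally
  reported to the nearest percent; the curve is smooth in $\alpha$ so a
  finer grid adds nothing.
- **Raw TPM, zeros included**: correlations are computed on untransformed
  values over the full intersection of gene universes, before any
  detection filtering; log transforms are for plotting only. This makes
  the Pearson coefficient sensitive to high-abundance genes — which is
  exactly what makes the blend identifiable, since cell-type markers are
  the high-abundance discriminating genes.
- **Replicates are averaged before scanning** (arithmetic mean of TPM),
  not scanned separately.
- **Ties** in the Pearson curve resolve to the smallest $\alpha$, keeping
  the output deterministic.
- P-values for correlation coefficients use the Student-$t$ transform of
  $r$ with $n-2$ degrees of freedom, for Spearman as well (average ranks
  at ties).

The scan is a point estimate by design; no confidence interval is
attached, and regression-style deconvolution with more than two reference
types is out of scope.

## Paired differential expression

Microvessel-vs-whole-brain contrasts are paired (each animal or donor
contributes both compartments). Per gene, the package fits a log-link
negative-binomial regression

$$\mu_{gj} = s_j \exp(\beta_0 + \sum_p \beta_p \mathbb{1}[\text{pair } p] + \beta_c \mathbb{1}[\text{microvessel}]),$$

by iteratively reweighted least squares at fixed per-gene dispersion, and
tests $\beta_c = 0$ with a Wald $z$ against the standard normal;
$\log_2\mathrm{FC} = \beta_c/\ln 2$. This is a deliberately simplified
stand-in for full count-model machinery: no Cook's-distance outlier
handling, no independent filtering, no fold-change shrinkage. Components:

- **Size factors** $s_j$: median-of-ratios over genes positive in every
  sample, rescaled to geometric mean 1; when no gene is positive
  everywhere the ratio set falls back to genes positive in at least half
  the samples.
- **Dispersion.** The exported `estimate_dispersion()` is the plain
  method-of-moments estimator on normalised counts,
  $\hat\alpha_g = \max\{(s^2_g-\bar\mu_g)/\bar\mu_g^2,\,10^{-8}\}$. The
  test itself uses `moderated_dispersion()`: the same estimator applied
  *within* each condition group (so a real fold change is not absorbed
  into the variance), pooled with degree-of-freedom weights, and floored
  at the cross-gene median. The floor is the one concession to
  moderation, and it is load-bearing: with 2–5 residual degrees of
  freedom per gene a sizeable fraction of raw estimates collapse toward
  zero by chance, and an unfloored estimate turns those genes into
  arbitrarily large Wald statistics. The design-blind estimator without
  grouping is calibrated but loses essentially all power for strong
  effects at three-vs-three designs, because the effect itself inflates
  the variance estimate. The median floor keeps the null calibrated (the
  acceptance tests verify ≤1% of genes called and a raw-p KS statistic
  below 0.05 under a simulated global null) while preserving power
  (sensitivity ≥ 0.8 at 6 pairs with four-fold effects, empirical FDR
  ≤ 0.1).
- **Degenerate genes.** All-zero genes are skipped
  (`status = "low_count_skipped"`); completely separated genes (one group
  all zero) are refit with a 0.5 pseudocount and flagged; non-converging
  fits are flagged with absent p-values.
- **Multiple testing**: Benjamini–Hochberg step-up, implemented in
  `bh_adjust()` and checked in the tests against a literal enumeration of
  the step-up definition and against `stats::p.adjust`. "Enriched" means
  adjusted p < 0.05 with positive fold change; the threshold is an
  argument everywhere it is used.

## Cross-species comparison

Mouse and human expression are compared on a curated homology table.
Classification is by multiplicity: 1:1 pairs pass through; a human gene
with several mouse homologs has the mouse TPM values **summed** per
sample; a mouse gene with several human homologs keeps only the
top-expressed human homolog when the runner-up is negligible or much
smaller, and otherwise each similarly-expressed human homolog is compared
individually. Two knobs make "negligible" and "similar" precise, both
exposed as arguments:

- `negligible_tpm = 1`: a runner-up below 1 TPM (mean across samples) is
  treated as unexpressed — the same 1-TPM convention used by the
  endothelial subtraction.
- `similar_ratio = 0.2`: a runner-up within 20% of the top homolog counts
  as similar. Conservative, so that genuinely bimodal homolog pairs are
  split rather than silently collapsed.

Many-to-many components are rejected with an error naming the component;
they cannot be resolved by these rules. An audit attached to the output
verifies that every table entry lands in exactly one bucket (direct,
summed, max, split, dropped).

Because homologs differ in transcript length between species, raw counts
are not comparable. TPM rows are instead converted back to a count-like
scale using the **human** gene length
($\mathrm{raw}_{ij} = \mathrm{TPM}_{ij} \cdot L^{\mathrm{human}}_i$), each
sample rescaled to a common target depth and rounded to integers. The
target depth defaults to $2\times10^7$, the order of a typical bulk
library; whether to round or pass reals onward was an open point, and
rounding was chosen because the count model downstream expects integers —
the tests verify the TPM round-trip survives rounding to relative
$10^{-2}$ at depth $10^7$ (and $10^{-6}$ before rounding). The species
contrast then runs the same Wald machinery unpaired, human over mouse.

## Species filters and pericyte subtraction

Three complementary filters turn the DE tables into biological claims:

1. **Intersection**: species-enriched genes that are also
   microvessel-enriched within their own species — species differences
   attributable to the vasculature.
2. **No compartment enrichment**: species-enriched genes with adjusted
   p ≥ 0.05 in the within-species compartment contrast — catches
   pan-tissue species differences the intersection filter discards.
   Genes absent from the compartment table are retained but flagged
   `untested`, so users can tighten if they prefer.
3. **Direct list comparison**: genes microvessel-enriched in one species
   whose homolog is not microvessel-enriched in the other, *including*
   genes with no known homolog (flagged `homolog_less`) — the only
   filter able to see them.

Putative pericyte genes are identified subtractively: of the human
microvessel-enriched genes, those with **1 TPM or greater** in the
averaged endothelial reference profile are considered endothelial-derived
and excluded; the boundary is inclusive on the exclusion side, and the
reference summary is the mean profile (not a per-cell detection rate),
matching how the reference is constructed. Genes absent from the
reference universe count as 0 TPM and are flagged. The intersection with
the filter-1 human list, ranked by cross-species fold change, gives the
human-specific pericyte candidates.

## Enrichment and QC

Genes are ranked by $-\log_{10}(p)\,\mathrm{sign}(\log_2\mathrm{FC})$
(p = 0 clamped to the smallest positive double; ties broken by gene
identifier). The enrichment score of a set is the extremum of the
weighted Kolmogorov–Smirnov running sum (weight exponent 1 by default;
increments $|s|^w/\sum|s|^w$ at members, decrement $1/(N-N_{hit})$
otherwise). Nominal p-values come from **gene-set permutation** — random
same-size sets from the ranked universe — because the ranking metric is
derived from the DE output, leaving no phenotype labels to permute. With
$B$ permutations, $p = (1 + \#\{|ES^*| \ge |ES|\})/(1+B)$, so p is never
zero and is exactly reproducible under a fixed seed. FDR q-values are not
computed; nominal p at 0.05 is the reported criterion. Sets outside
5–500 members (after intersection with the ranked universe) are skipped.

Sample clustering uses one-minus-Pearson distance with average (UPGMA)
linkage; heat-map-style gene views first normalise each gene as the
z-score of $\log_2(\mathrm{TPM}+1)$. PCA is gene-centred and unscaled,
on TPM by default (a log transform is an option, off by default), with
per-component variance fractions reported.

## The synthetic-study generator

`simulate_study()` emulates the statistical structure the analysis
assumes, so that every stage can be scored against known truth:

- **Design**: 2 species × 3 pairs × 2 compartments (12 bulk samples), the
  replication level of the motivating study design.
- **Cell types**: endothelial, pericyte, neuron, astrocyte. Microglia and
  finer parenchymal types are deliberately omitted; two parenchymal types
  suffice to emulate contamination.
- **Compositions**: microvessels 0.45 endothelial / 0.40 pericyte / 0.15
  parenchyma (a roughly 1:1 vascular mixture with realistic
  contamination; the implied pericyte share of vascular transcripts,
  0.471, is recorded as the planted truth); whole brain 0.90 parenchyma /
  0.10 vascular, the vascular sliver split in the same proportions.
  Parenchyma is 70% neuron, 30% astrocyte. For pure two-reference
  mixture-recovery experiments the conventional planted fraction is
  α = 0.42, passed as an explicit composition.
- **Noise**: negative-binomial with dispersion 0.1 (typical for bulk
  tissue replicates), library size log-normally jittered around
  $2\times10^6$ expected reads. These desk-scale sizes (2 000 genes by
  default, 5 000 for mixture-recovery checks) keep the full pipeline
  under half a minute while leaving every estimator in its intended
  regime.
- **Planted truth**: 50 markers per cell type at 8-fold in the home type
  (near-silenced elsewhere, leakage $10^{-4}$); 40 human-up species
  differences restricted to vascular signatures, 40 pan-tissue ones, and
  10 pericyte markers additionally up-regulated in the human pericyte
  signature (the human-specific pericyte truth); gene lengths log-normal
  around 2 kb, jittered between species; a homology table that is 92%
  1:1, 2% one-human-to-many-mouse, 2% one-mouse-to-many-human (half with
  a negligible runner-up, half similarly expressed, exercising both
  collapsing branches) and 4% unmapped.

What passing tests on this generator do **not** show: real microvessel
data have continuous cell-type gradients rather than four discrete
signatures, correlated genes, batch structure, and reference profiles
measured on different platforms than the bulk samples — the generator's
single shared baseline makes profiles more mutually correlated than real
purified references, and its marker-driven identifiability is cleaner
than reality. Recovery results on synthetic data bound what the methods
can do under their own assumptions, not what any particular tissue
dataset will yield.

## Reproducibility

All randomness flows through explicit seeds; `simulate_study()` and
`gsea_preranked()` save and restore the global RNG state.
`run_pipeline()` writes a manifest with the config snapshot, seed,
per-stage timings and an md5 checksum of every output file; identical
configs produce byte-identical outputs, which the tests verify by
hashing two independent runs.

## Known limitations

- The DE engine is a simplified count-model stand-in: no outlier
  handling, no shrinkage beyond the dispersion median floor, single
  pairing factor plus one condition only. It is validated by parameter
  recovery, not by numerical agreement with any external implementation.
- The mixture scan assumes exactly two reference components; parenchymal
  contamination biases the estimated pericyte share toward whatever the
  contamination correlates with.
- Homology collapsing resolves only 1:many structures; many:many
  components are refused rather than modelled.
- Gene-set permutation calibrates against random sets of the same size,
  not against correlation structure among genes.
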