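---
title: "Partitioning non-additive genetic variance and predicting clonal performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning non-additive genetic variance and predicting clonal performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneGP)
```

## The problem

In clonally propagated crops such as sugarcane, the commercial unit is the
clone itself, not its offspring. What matters for variety selection is the
*total* genetic value — additive effects plus dominance (within-locus) and
epistatic (between-locus) interactions — because the whole genotype is
propagated intact. Yet most genomic evaluation models are purely additive.
`cloneGP` implements a second-stage genomic analysis that

1. partitions genetic variance into additive, dominance and
   additive-by-additive epistatic components from genome-wide SNPs,
2. regresses performance on genome-wide heterozygosity to capture
   directional dominance (inbreeding depression / heterosis),
3. predicts both breeding values (GEBV) and total clonal performance
   (GPCP) under six nested GBLUP models and a Gaussian-kernel RKHS model,
   and
4. evaluates forward-prediction accuracy the way a breeding program would
   deploy it: train on earlier series-years, predict the clones first
   tested later.

The package operates on *adjusted phenotypes*: clone BLUPs from a
first-stage spatial analysis of each trial. Stage one is out of scope —
records enter as one value per clone × year × crop × region × trial.

Genotypes are pseudo-diploid: in a highly polyploid genome, single-dose
markers segregate like diploid markers, and all heterozygous dosage
classes are collapsed into one class, so codes are 0/1/2. This is an
approximation; variance components estimated under it should be read as
statistical, not physiological, quantities.

## NOIA relationship matrices

The additive and dominance incidence matrices use the natural and
orthogonal interactions (NOIA) coding, which is built from *observed
genotype frequencies* (p_AA, p_Aa, p_aa) per locus rather than from
Hardy–Weinberg allele frequencies. For a locus the additive values are

h_A = (−(−p_Aa − 2p_aa), −(1 − p_Aa − 2p_aa), −(2 − p_Aa − 2p_aa))

for genotypes (AA, Aa, aa), i.e. the negated centred genotype code; the
dominance values are

h_D = (−2 p_Aa p_aa, 4 p_AA p_aa, −2 p_AA p_Aa) / D,
D = p_AA + p_aa − (p_AA − p_aa)²

Both codings have zero frequency-weighted mean at every locus, and under
HWE frequencies the two contrasts are orthogonal under the genotype
frequency weights — the property that makes the additive/dominance
partition stable when both terms are fitted. Relationship matrices are
trace-normalized cross-products, G = HH′/(tr(HH′)/n), so each has mean
diagonal exactly 1 and variance components attached to different kernels
are on a common scale. Epistatic kernels are Hadamard products of the
normalized matrices (G_AA = G_A ∘ G_A, rescaled), which approximates the
pairwise epistatic covariance under linkage equilibrium; with the strong
LD of elite breeding populations the components are not empirically
orthogonal, and estimates shift as terms are added — which is itself a
diagnostic the model-comparison workflow surfaces.

Degenerate loci are handled structurally: monomorphic columns (additive)
and D = 0 columns (dominance — no homozygotes or no heterozygote contrast)
become all-zero columns and are excluded from the heterozygosity
normalizer, so matrix shapes never change.

Genome-wide heterozygosity per clone is Het_k = Σ_l h_kl / Σ_l 2 p_l q_l
over the dominance incidence row; under HWE a fully heterozygous clone has
Het = 1. Fitted as a centred fixed covariate, its coefficient b measures
directional dominance; when it is in the model, part of what would
otherwise appear as dominance variance moves into b, mirroring what
happens in real data sets with heterosis.

## REML estimation

The six models A, AH, AD, ADH, ADE, ADEH add kernels (G_A; +G_D; +G_AA)
and optionally the Het covariate to the fixed part
(mean + Year + Crop + Region + Trial, treatment-coded, no interactions).
Because trials are nested in region × year, the main-effects fixed design
is rank-deficient by construction; aliased columns are dropped by QR
pivoting with a warning, the same resolution commercial mixed-model
software applies silently. Any full-rank reparameterization yields the
same REML likelihood (tested).

The solver is average-information (AI) REML with three initial EM steps,
components initialized at var(y)/(k+1). All algebra runs in clone space:
with V = Z K Z′ + σ²ε I and K = Σ_k σ²_k G_k over the q phenotyped clones,
the Woodbury identity through the Cholesky factor of K (never through
K⁻¹, which loses accuracy when a component approaches zero) gives
V⁻¹-products, determinants, traces and the AI matrix at O(q³) per
iteration regardless of the record count. AI steps are guarded by
step-halving against likelihood decrease; EM is the fallback. Convergence
is a relative log-likelihood change below 1e-8 (maximum 200 iterations).
Variances driven below 1e-6·var(y) are pinned there and flagged as
boundary ("~0"), with no standard error — under a true zero variance the
REML estimate follows a half-normal-like mixture, so pinning occurs in
roughly half of null replicates. Standard errors come from the inverse AI
matrix; a numerically singular AI system (non-identifiable kernel sets)
is flagged rather than inverted.

Heritabilities are h² = σ²_A/σ²_P and H² = (Σ genetic σ²)/σ²_P with σ²_P
the sum of all fitted components. Model comparison uses the plain χ²(1)
likelihood-ratio test at α = 0.05. Because the null value of a variance
lies on the boundary of the parameter space, the plain χ²(1) reference is
conservative (true size below the nominal 5%); we keep it deliberately —
it is the standard applied procedure for this analysis — and verify the
conservatism by simulation in the test suite.

GEBV is the additive BLUP; GPCP stored in a fit is exactly the sum of the
fitted genetic BLUPs. For H models, `predict()` adds b·(Het − mean Het) to
GPCP by default: the heterozygosity regression is part of the expected
clonal performance and carries precisely the directional-dominance signal
that motivates those models. It can be excluded with
`include_het = FALSE`.

## RKHS regression

The Bayesian alternative fits y = 1μ + Σ_m g_m + ε with
g_m ~ N(0, K_m σ²_gm) and Gaussian kernels
K(x_i, x_j) = exp(−h Σ_k (x_ik − x_jk)²/p) built from raw (imputed) 0/1/2
codes. The default single-kernel bandwidth grid is
h ∈ {0.1, 0.5, 1.0, 2.5, 5.0, 10}, searched by forward validation; the
default multi-kernel model uses h ∈ {0.1, 0.5, 1.0}. Chains run 5,000
Gibbs iterations with 1,000 burn-in (thinning 1), matching the settings
under which the reference accuracies were produced.

Each g_m is sampled in the eigenbasis of its kernel: after one symmetric
eigendecomposition the coordinate updates are independent, so an
iteration costs two n×n matrix–vector products per kernel. Eigenvalues
below 1e-8 of the largest are truncated (count reported). Variance priors
are scaled-inverse-χ² with df = 5; scales are set so the prior mode
assigns half of var(y) to the genetic side, split equally among kernels —
weakly informative defaults comparable to standard Bayesian genomic
regression software, and documented rather than hidden. The intercept has
a flat prior. Chains are bit-reproducible given a seed; equivalence with
a naive full-covariance Gibbs sampler is verified on small instances in
the test suite.

## Forward-prediction evaluation

A scenario trains on clones recorded in the training series-years and
evaluates clones recorded in the test year; any clone present in both
periods is evaluated, never trained on, so reference and validation sets
are disjoint. Accuracy is the Pearson correlation between clone-level
predictions and per-clone mean adjusted phenotypes, computed within each
region (a clone with test records in several regions is scored in each)
and summarized as the unweighted mean across regions; per-region standard
errors use se = sqrt((1 − r²)/(n − 2)). Unweighted averaging across
regions is a deliberate choice (region sizes differ; the alternative
n-weighted mean is a one-line change via the per-region table). Relative
improvements are reported as integer percent, rounded half away from
zero. Connectedness between reference and validation sets is measured as
the mean of each validation clone's top-10% relationships to the
reference set (the fraction's count is floor(fraction·|ref|), at least
one).

## The synthetic trial system

The generator emulates the structure the analysis assumes, with recorded
ground truth for recovery testing:

* **Genotypes.** Per-locus alternate-allele frequencies uniform on a
  configurable range (default 0.05–0.5); genotype classes drawn with a
  heterozygote deficit controlled by an inbreeding-style parameter f
  (default 0.1, reflecting related parents; f = 0 gives HWE); optional
  missingness (default 1%).
* **Genetic values.** Additive: centred codes × normal substitution
  effects. Dominance: NOIA dominance incidence × effects with mean equal
  to the directional-dominance parameter — so the dominance covariance
  matches G_D and, when the mean is positive, heterozygosity correlates
  with genetic value by construction. Epistasis: products of centred
  codes over random locus pairs (additive-by-additive only, the one
  interaction component with material variance in practice). Each
  component is rescaled so its realized clone variance equals its target
  exactly, which makes "estimate within 2 SE of realized truth" a sharp
  recovery criterion.
* **Trial design.** Four regions × five series-years × three crops
  (plant, two ratoons), four trials per region-year; each clone belongs
  to one region and one series, and is replicated into a second trial
  with probability 0.22 — the average partial replication of the
  emulated system. Year/crop/region/trial effects are normal with
  configurable spreads; residuals are i.i.d. per record.

The `TCH`-like preset targets σ²_A = 50, σ²_D = 30, σ²_AA = 40,
σ²_ε = 36 (broad-sense ratio 120/156 ≈ 0.77) with directional dominance;
`CCS`- and `Fibre`-like presets are mostly additive, Fibre with high
heritability. The `mini` scale is 500 clones × 2,000 SNPs — the routine
validation scale used throughout the tests — and `full` is 3,000 ×
25,000.

What the generator does *not* emulate: linkage disequilibrium between
loci (independent loci by default, so additive/dominance partitions are
cleanly recoverable — real elite populations are harder), true polyploid
dosage, genotype-by-environment interaction, and spatial field trends
(stage one's job). Passing recovery tests therefore demonstrates
correctness of the machinery under the model's own assumptions, not that
real sugarcane data would partition as cleanly.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:
NOIA coefficients against direct evaluation of the printed formulas; the
GRM builder against a brute-force pairwise loop; REML against a dense
grid search of the restricted likelihood on a 6-clone instance (within
1e-4 log-likelihood) and against a dense-matrix optimizer; the eigenbasis
Gibbs sampler against a naive full-covariance sampler; and the derived
ratios of the bundled published reference tables (variance shares,
heritabilities, the 71.78 likelihood-ratio statistic, the 6/14/31/17/12/9%
accuracy improvements) against the package's own share/LRT/improvement
functions. Simulation-based checks use 20 replicates at the mini scale
for variance-component recovery (both components within 2 SE of realized
truth in ≥90% of replicates), 200 null replicates for LRT calibration
(rejection ≤ 5%), and 20 replicates of the forward-prediction contrast:
with large simulated non-additive variance the mean GPCP (ADEH) accuracy
exceeds the mean GEBV (A) accuracy, and the gap vanishes for a purely
additive trait — the qualitative pattern that distinguishes a
yield-like trait from a fibre-like one. Recovery simulations use an
AD-generative truth (epistatic target zero) because fitting an AD model
to data that truly contains epistasis would bias both components by
construction; the epistatic machinery is exercised separately by the
accuracy contrast and the monotone-likelihood tests.

A worked end-to-end run:

```{r example, eval = FALSE}
cfg <- sim_preset("mini", "TCH", seed = 1)
g   <- simulate_genotypes(cfg)
sim <- simulate_phenotypes(g, cfg)
qc  <- apply_qc(g)
kset <- build_kernel_set(qc$genotypes)
fit_a  <- fit_gblup(sim$phenotypes, kset, "trait", model = "A")
fit_x  <- fit_gblup(sim$phenotypes, kset, "trait", model = "ADEH")
lrt(fit_x, fit_a)
scen <- build_scenario(sim$phenotypes, 2013:2015, 2016)
```

## Known limitations

* Pseudo-diploid coding discards dosage information; the NOIA machinery
  here is the diploid parameterization.
* Hadamard epistatic kernels assume linkage equilibrium; under strong LD
  the partition is biased even though prediction is not compromised.
* The plain χ²(1) LRT is conservative for boundary hypotheses.
* The RKHS model contains no fixed covariates beyond the intercept, so it
  is fitted to clone-level response summaries rather than raw records.
* Variance-component standard errors from the AI matrix are asymptotic;
  for pinned components they are undefined and reported as NA.
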