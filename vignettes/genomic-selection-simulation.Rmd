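---
title: "Simulating genomic selection in a goat-like breeding population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic selection in a goat-like breeding population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gselsim` implements a complete in-silico genomic-selection study for a
cashmere/meat-goat-like breeding population: a forward-in-time simulator
whose output feeds six genomic breeding-value (GEBV) estimators, and the
evaluation machinery that turns their validation accuracies into the
fixed-effects ANOVA and Duncan multiple-range reports breeders use to choose
a marker density, a reference-population size and an estimation method.
This vignette is the package's account of the science: the models, the
parameters that matter, the numerical choices, and what the bundled
desk-scale checks do and do not demonstrate.

## The simulated population

The population process has three phases, mirroring how commercial
small-ruminant populations are modelled:

1. **Historical phase.** Discrete non-overlapping generations of random
   union of gametes with no selection: 5,000 generations at a constant size
   of 1,000 (500 males, 500 females), then 500 generations growing linearly
   to 3,000 (400 males, 2,600 females). Its only purpose is to let
   recurrent mutation and drift build a realistic allele-frequency spectrum
   and linkage disequilibrium (LD).
2. **Expansion.** 400 founder males and 2,600 founder females drawn from the
   last historical generation; 10 generations with 5 offspring per dam,
   random mating, no selection.
3. **Recent phase.** 40 sires and 400 dams drawn from the expanded
   population; 10 breeding seasons with 1–2 progeny per dam, 50% male
   progeny, truncation selection on pedigree-BLUP EBV, replacement of 80%
   of sires and 30% of dams per season, and age culling.

The genome is 29 autosomes totalling 2,922 cM. Markers and QTLs (both
biallelic) are placed uniformly at random; panels of 15–60 K markers and
50–150 QTLs are drawn after filtering. Recurrent mutation flips alleles at
9.4 × 10⁻⁶ per locus per meiosis.

### Meiosis and crossover interference

Crossovers on each chromosome follow a **stationary gamma renewal process**
with shape equal to the interference parameter (5.0 by default) and unit
mean spacing in Morgans, so the expected crossover count equals the map
length in Morgans. Shape 1 reduces to a Poisson (no-interference) process;
larger shapes regularise spacings and suppress nearby double crossovers,
which the tests verify as a strictly smaller coefficient of variation of
inter-crossover distances. There is no obligate chiasma. For integer shape
the first crossover position is drawn exactly from the renewal process's
forward-recurrence (Erlang mixture) distribution; for non-integer shapes
the process is burnt in from 20 mean spacings upstream of the chromosome.
The gamete starts on a random parental strand and alternates at each
crossover. These choices follow common livestock-simulator practice; the
interference parameter's value is standard for ruminants, but the renewal
model itself is a package decision since only the parameter, not the
process, is conventionally reported.

### Founders, mutation–drift, and the marker panel

Founder haplotypes are initialised with allele frequency 0.5 at every locus;
the historical phase then shapes the spectrum. This is a deliberate,
recorded choice — equilibrium is established *by* the historical
generations rather than assumed at their start. Because drift fixes a
substantial fraction of loci, the simulator places twice as many candidate
loci as the target panel and, at the end of the historical phase, retains
exactly the requested number of segregating markers with minor allele
frequency ≥ 0.05 (and segregating QTLs) by random subsampling.

### Demographic bookkeeping decisions

Several production-system details are under-determined by convention and
were fixed once:

* **Expansion founders**: 400 males / 2,600 females from the historical
  population — deliberately distinct from the much smaller recent-phase
  founder set of 40 sires and 400 dams.
* **Expansion cap**: a literal 5-offspring-per-dam expansion from 2,600
  dams is astronomically large; the expansion is capped (default 15,000)
  by random culling that preserves the realised sex ratio.
* **Litter size** in the recent phase: 1 + Bernoulli(0.5) per dam per
  season ("one or two progeny per dam per year").
* **Maximum breeding age**: 5 seasons (age culling is specified without a
  number).
* The two traits are simulated in **separate single-trait runs**; no
  selection index is modelled.

## Trait model

A trait is defined by its narrow-sense heritability *h²* (0.34 for fiber
diameter, selected downwards; 0.11 for live body weight, selected upwards)
and phenotypic variance σ²ₚ = 1. QTL effect magnitudes are drawn from
Gamma(shape 0.40, scale 1) with random signs, then multiplied by one
constant so that the variance of true breeding values (TBV = Σ genotype ×
effect) over the recent-phase base generation equals *h²σ²ₚ*; the TBV
offset centres the base mean at zero. Phenotypes add an independent normal
residual with variance σ²ₚ(1 − *h²*). Selection direction is a property of
the trait, not a sign flip of effects. Variance components are treated as
known throughout (the study supplies *h²* as an input); no REML is run
inside the generation loop or in the predictors.

## Breeding-value estimation

All models use the overall mean as the only fixed effect.

**Pedigree BLUP** solves Henderson's mixed-model equations with variance
ratio λ = (1 − h²)/h², using the sparse A⁻¹ assembled directly from
Henderson's rules with inbreeding from the Meuwissen–Luo ancestor walk.
A Jacobi-preconditioned conjugate-gradient solver is available alongside
the sparse Cholesky and agrees to 10⁻⁶, which the tests assert.

**GBLUP** replaces A with the VanRaden genomic relationship matrix
G = M꜀M꜀ᵀ / (2Σpⱼqⱼ) built from allele counts centred at twice the allele
frequencies. For numerical stability G is blended with 5% of the identity;
with the blend at zero, GBLUP is algebraically identical to ridge-regression
BLUP on marker effects with σ²ₘ = σ²ₐ/(2Σpⱼqⱼ), an identity the tests check
to 10⁻⁶. Marker effects are recovered by back-solving, which is what
`predict()` uses for new genotypes.

**Single-step GBLUP** combines A and G into H: H⁻¹ = A⁻¹ plus the
genotyped-block correction G_w⁻¹ − A₂₂⁻¹, where G is first rescaled so its
mean diagonal and off-diagonal match A₂₂ and then blended
G_w = 0.95·G_tuned + 0.05·A₂₂. With blend weight 1 (or G forced equal to
A₂₂) the correction vanishes and ssGBLUP reproduces pedigree BLUP exactly.
Ungenotyped relatives contribute phenotypes through the A-side, which is
where ssGBLUP's advantage over GBLUP comes from.

**Bayesian alphabet.** The whole-genome regression y = 1μ + Σ Zⱼaⱼ + e is
sampled by single-site Gibbs with four marker priors:

* **BRR** — one common marker variance with a scaled-inverse-χ² prior;
* **BayesA** — per-marker variances σ²gⱼ ~ χ⁻²(ν, S);
* **BayesB** — point mass π at σ²gⱼ = 0 and the BayesA slab otherwise, with
  the indicator sampled with the effect integrated out;
* **Bayesian LASSO** — double-exponential effects via the Park–Casella
  normal/exponential mixture with λ² ~ Gamma(0.55, 0.1).

Hyperparameters follow the standard expectation-matching rule: ν = 4.2 and
S chosen so E[σ²gⱼ] = h²σ²ₚ/(2Σpⱼqⱼ) (divided by 1 − π for BayesB's slab);
π is fixed at 0.95, configurable, rather than estimated. Chains default to
20,000 iterations, 5,000 burn-in, thinning 10; the conjugate special case
(BRR with variances held fixed) matches the closed-form ridge solution
within Monte-Carlo error, and the posterior-mean residual variance falls
within three posterior SDs of the simulating value on conjugate test data.

## Accuracy and the experiment design

The reference set is sampled from recent generations 2–7, the validation
set (fixed at 1,000 at full scale) from generations 8–10. Accuracy is the
Pearson correlation between predicted and realized values in validation.

**What is "realized"?** The package's default realized vector is the true
breeding value. The alternative — simulated phenotypes — is available
(`realized = "phenotype"` in the pipeline), but phenotype prediction is
theoretically capped at √h² ≈ 0.58 for h² = 0.34, whereas full-scale
single-step accuracies of interest in this setting exceed 0.7; TBV is the
only reading consistent with such magnitudes, so it is the default.

The experiment is one-factor-at-a-time: marker density (15/30/45/60 K),
QTL number (50/100/150) and reference size (500–3,000) each varied from a
per-trait baseline, crossed with six methods and three replicates — 216
records; the sex-composition study adds 6 compositions × 6 methods × 3
replicates = 108 records. Default baselines are per trait — fiber diameter:
60 K, 1,500, 150 QTLs; live body weight: 45 K, 3,000, 100 QTLs — and are
configurable. The ANOVA is an additive fixed-effects linear model with
**sequential (Type I) sums of squares** in the listed factor order — the
design is not a full factorial,
so an orthogonal Type III decomposition is not defined without further
convention. Duncan's multiple range test uses protected levels
α_p = 1 − (1 − α)^(p−1) with studentized-range quantiles from `qtukey`,
and letters are assigned to maximal homogeneous runs with the usual
protection rule (nothing inside a non-significant span is declared
significant).

## Numerical and reproducibility choices

* Positions are continuous centimorgans (converted to Morgans internally);
  locus order is the sole addressing scheme, and exported base-pair
  coordinates are round(cM × 10⁶).
* PED alleles are coded 1/2 with 1 the ancestral 0-allele; round-trip
  identity is tested.
* G stabilisation: 5% blend toward the identity (GBLUP) or A₂₂ (ssGBLUP)
  plus the mean-diagonal/off-diagonal tuning described above; a singular
  stabilised G is an error, not silently repaired.
* Degenerate inputs error loudly: monomorphic panels, zero genetic variance
  at scaling, infeasible MAF thresholds or sex compositions, cyclic or
  disordered pedigrees, zero-variance accuracy vectors.
* Every pipeline run derives its stage seeds deterministically from one
  master seed and stamps every artifact with a config hash; re-running a
  config reproduces all outputs byte-identically.

## The desk-scale profile: what it shows and what it cannot

`sim_profile("full")` is the full-scale configuration (hours of runtime).
`sim_profile("desk")` exists so that the entire study logic can run in
minutes: 250 + 50 historical generations at N = 200 growing to 400, a
capped expansion, 10 recent seasons from 25 sires and 250 dams, and 3,000
markers with 50 QTLs on a 5 × 100 cM genome.

The desk genome is deliberately **shrunk along with the population**.
Useful marker–QTL LD extends over distances of order 1/(4Nc); at N = 200 a
full 2,922 cM genome with 3,000 markers would leave adjacent markers
effectively unlinked to the QTLs, and "genomic" prediction would degenerate
into family capture through G's pedigree information. With 3,000 markers on
500 cM the ratio of marker spacing to LD extent is back in the regime of
the full-scale study, and the qualitative conclusions become testable:
accuracy rising with reference size 500 → 1,500, the h² = 0.34 trait
beating the h² = 0.11 trait method-for-method, and ssGBLUP at least
matching GBLUP on average. The acceptance tests check exactly these
orderings over 10 desk-scale replicates (one-sided paired tests at
α = 0.05 for the first two, a non-negative mean paired difference for the
third), plus calibration on unselected cohorts of 10,000 (realized h²
within ±0.02, phenotypic variance within ±0.05), the drift-decay law
(1 − 1/(2N))ᵗ at N = 50, binomial mutation counts, and the exact
degree-of-freedom ledger of the 216-record design.

Desk-scale success does **not** demonstrate the full-scale accuracy values
themselves: those are overnight stochastic runs requiring the full-scale
profile (the pipeline supports them unchanged), and real goat data would
additionally bring genotyping error, non-random mating, maternal and
permanent environmental effects, and multi-trait selection, none of which
are modelled.

## Known limitations

Biallelic loci only; no dominance, epistasis, maternal effects or repeated
records; no sex chromosomes, indels or CNVs; uniform recombination within
the gamma-renewal model; single-trait selection; variance components fixed
at their simulated values (no REML); BayesB's π fixed rather than
estimated; ssGBLUP scores only animals present in the fitted pedigree.

## A worked desk-scale cell

```{r example}
library(gselsim)
set.seed(2026)
cfg <- sim_profile("desk")
sim <- simulate_breeding(cfg, trait_config(0.34, "low", name = "fiber diameter"))

split <- split_reference_validation(sim, ref_size = 1000, val_size = 800)
ped <- sim$pop$ped
rows <- match(as.numeric(c(split$ref, split$val)), ped$id)
geno <- genotypes(sim$pop, sim$map, rows = rows)
y <- setNames(ped$phen[match(as.numeric(split$ref), ped$id)], split$ref)

fit <- gebv(y, geno, "GBLUP", h2 = 0.34)
tbv <- ped$tbv[match(as.numeric(split$val), ped$id)]
compute_accuracy(predict(fit)[split$val], tbv)
```

The same cell swapped over methods and factor levels, fed through
`run_factorial()`, `anova_glm()` and `duncan_mrt()`, reproduces the
study-style reports at any scale.
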