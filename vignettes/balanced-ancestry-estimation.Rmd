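---
title: "Balanced AIM panels and maximum-likelihood individual ancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced AIM panels and maximum-likelihood individual ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadmix)
```

## The model and its assumptions

`triadmix` estimates the proportions (m₁, m₂, m₃) of a person's genome
derived from three ancestral populations — European (EU), American Indian
(AI) and African (AF) — from biallelic SNP genotypes, with the allele
frequencies of the three reference populations treated as *fixed, known
constants* ("fixed parental allele" estimation). The assumptions are:

* **Known parental frequencies.** Uncertainty in the reference panel is
  ignored; the reference samples are assumed large and representative.
* **Hardy–Weinberg equilibrium within the admixed individual.** The
  allele-1 dosage at SNP *g* is Binomial(2, P_g) with the hybrid frequency
  P_g = p₃g + m₁Δ1g + m₂Δ2g, a convex combination of the parental
  frequencies.
* **Independence across markers.** No linkage disequilibrium; enforced in
  panel design by a ≥ 500 kb within-set spacing rule rather than by
  modelling LD.
* **Global, not local, ancestry.** One (m₁, m₂, m₃) per person.

The log-likelihood is concave in (m₁, m₂) (each term is the log of an
affine function of the parameters), which is what licenses the
coarse-to-fine search below.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `grid_step` | 0.001 | lattice resolution on the simplex (ancestry units) |
| `clamp` | 1e-3 | hybrid/parental frequencies clamped to [clamp, 1−clamp] so log-likelihoods stay finite when a reference frequency is 0 or 1 |
| `delta_max` / `delta_off` | 0.5 / 0.3 | a SNP "maximizes" a contrast when its δ (absolute frequency difference) is ≥ 0.5 there and < 0.3 in the other two contrasts |
| `spacing` | 500 000 bp | minimum within-set distance between syntenic AIMs (LD proxy) |
| `replicate_max` | 0.032 | replicate-typing discordance ceiling for candidate AIMs |
| `in_tolerance` | 0.10 | relative spread of the three all-SNP Iₙ values tolerated by the balance verdict |
| `info_type` | `"expected"` | Fisher information; `"observed"` (negated realized Hessian) available for sensitivity analysis |

Together δ_max = 0.5 and δ_off = 0.3 imply every δ < 0.6 (triangle
inequality), which caps the per-marker information; this matters for the
error budget discussed at the end.

## What the generator emulates — and what it does not

`simulate_panel()` reproduces the *structure* of a balanced three-way AIM
panel: three maximized-contrast sets (default 450/450/400 SNPs), maximized
δ drawn from Normal(0.53, 0.022) truncated to the feasible range, both
off-contrast δ below 0.3, all frequencies in [0.01, 0.99], and markers
laid out round-robin over 22 pseudo-chromosomes at 1 Mb spacing so the
three sets interleave along the genome. Subject to those constraints the
base frequency of the maximized pair is placed *uniformly* — the simplest
assumption given that the joint frequency distribution of real,
ascertainment-selected AIMs is not specified by any single summary
statistic. The generator deliberately does **not** model:

* linkage disequilibrium (marker independence is assumed, as in the
  estimator itself);
* genotyping error or missingness mechanisms other than
  missing-completely-at-random (`missing_rate`);
* the boundary-concentrated ("U-shaped") frequency spectra of real
  ascertained AIMs. A Beta-anchored placement was evaluated during
  development; it changes per-marker information by only ~10–15 % and was
  not adopted, keeping the simpler documented law.

Consequently, passing tests demonstrate the estimator's *statistical
correctness* (oracle equivalence, calibrated standard errors, balance
diagnostics) under the model's own assumptions; they do not certify
performance on real genotype data with LD, batch effects or reference
mis-specification.

`find_like_truth()` draws per-person truth from Dirichlet distributions
centred on the mean admixture of four self-identified heritage groups of a
large multi-ethnic diabetic-nephropathy cohort — European American
(0.961, 0.014, 0.025), American Indian (0.045, 0.945, 0.010), Mexican
American (0.476, 0.447, 0.077), African American (0.149, 0.021, 0.830).
The concentration default of 10 gives within-group standard deviations of
roughly 0.05–0.15, the order observed in such cohorts; the true
within-group law is unknown and the Dirichlet is a stated stand-in.

## Numerical choices

* **Grid domain.** m₁ and m₂ each range over [0, 1] but the lattice is
  restricted to the simplex m₁ + m₂ ≤ 1, since m₃ = 1 − m₁ − m₂ must be
  non-negative.
* **Coarse-to-fine search.** A global pass at 10× the step, then the
  full-resolution lattice inside ±2 coarse steps of the coarse optimum.
  By concavity the window contains the global lattice optimum; equality
  with the exhaustive grid is asserted on random instances in the test
  suite rather than assumed.
* **Tie-breaking.** Ties between lattice points (possible when no marker
  separates two ancestries) are resolved toward the smallest m₁, then the
  smallest m₂, with a warning. Both search modes and the test oracle use
  the same rule.
* **Boundary estimates.** Estimates on the simplex boundary still report
  variances from the inverse information at the boundary point;
  confidence intervals should be truncated to [0, 1] by the user.
* **Degenerate information.** A singular information matrix (e.g. a panel
  informative for only one contrast) raises an explicit error in
  `invert_information()`; in cohort estimation the affected individuals
  get `NA` variances and a counted warning. This is the practical
  "internal signal" that an estimate is untrustworthy.
* **0·log 0 = 0** throughout the entropy-based Iₙ statistic; natural
  logarithms everywhere.

## Design decisions in panel construction

* **Iₙ allele mode.** The informativeness-for-assignment statistic is
  computed in its standard biallelic form, summing the entropy term over
  both alleles (making Iₙ ≥ 0, and ln 2 per reciprocally fixed SNP at
  K = 2); a single-allele variant is available for sensitivity analysis.
* **Iₙ population scope.** Per-set Iₙ uses the two populations of the
  set's maximized contrast (K = 2); a K = 3 evaluation is available via
  `informativeness_in()` directly.
* **Greedy order.** Within a contrast class, candidates are taken in
  descending maximized-δ order (ties by position); the spacing rule is
  enforced within sets, not across them.
* **Set balancing.** With explicit `target_sizes` the sets are truncated
  from the low-δ end. Without targets, the most informative set is
  trimmed one SNP at a time (lowest δ first; Iₙ is additive over SNPs, so
  the update is exact) until the per-set Iₙ values agree within 2 %.
* **Fst summary.** Per-contrast Weir–Cockerham θ is summarized both as the
  mean of per-SNP θ (matching the per-locus mean ± SD presentation common
  for AIM panels) and as the ratio-of-sums multi-locus estimator, labelled.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run the experiments at the scale
of the default generator: a 1300-SNP balanced panel; 100 individuals per
group (four groups) for the standard-error accumulation curve, evaluated
at 200, 700 and 1300 markers; 100 individuals per vertex cohort for the
balance-failure experiment; 200 individuals and two disjoint 650-SNP
panels for replicate concordance; and 200 individuals at interior truth
(0.5, 0.3, 0.2) for calibration. Module tests use smaller panels
(40–150 SNPs) for speed.

## Known limitations

* **K = 3 only.** The estimator is specific to the three-population
  model; other K are rejected by construction of the panel format.
* **Error theory is exact only as far as the model is.** The standard
  errors are validated two ways in the tests: the analytic Fisher entries
  match numerical Hessians of the expected log-likelihood to 1e-4, and
  the mean reported SE matches the Monte-Carlo sampling SD of the
  estimator to three decimals under the generator. They are therefore
  *correct* standard errors for the HWE model — and correspondingly
  conservative relative to error claims derived by other algorithms.
* **The δ < 0.6 information cap.** Because the maximized/off-contrast
  thresholds force every δ below 0.6, the per-marker Fisher information
  at interior admixture is bounded (I ≤ 2δ²/(P(1−P)) with mid-range P),
  so a 1300-marker panel of this design cannot push mean standard errors
  at strongly admixed individuals much below ~0.02 — as the acceptance
  script's computed curve shows (≈ 0.065 at 200 SNPs, ≈ 0.034 at 700,
  ≈ 0.025 at 1300, averaged over the four cohort groups). Tighter errors
  require either more markers or relaxing the single-contrast design.
* **Replicate-panel concordance** is a consistency check, not external
  validation: two panels drawn from the same generator share its
  assumptions.
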