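---
title: "Methods: frequency and dosage spectra for autopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency and dosage spectra for autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysfs)
```

# The model

`polysfs` treats a sample of n autopolyploid individuals of even ploidy p
at biallelic sites with known derived orientation. The per-site state is
the dosage distribution (DD): counts I₀,…,I_p of individuals per derived
dosage, constrained by ΣI_d = n and Σ d·I_d = j, the derived chromosome
count out of pn. Only biallelic sites are handled (under low per-base
mutation rates, multi-allelic sites are rarer by another factor of θ);
multi-allelic VCF records are skipped with a warning, and any site with a
missing genotype is dropped from spectra rather than imputed.

Spectrum keys are *integer* derived counts j (1 ≤ j ≤ pn−1), never
floating-point frequencies, so empirical and expected tables join exactly.
SFDS keys store only the heterozygous DD components I₁,…,I_{p−1}; the
homozygote counts are implied by (n, j) and recovered by `complete_dd()`.

## Neutral expectations

Under neutrality with random mating and polysomic inheritance (double
reduction is excluded throughout), the population DD at frequency f is
binomial, the population SFS density is θ/f, and the finite-sample SDS at
derived count j is the multivariate-hypergeometric law of placing j
indistinguishable derived copies uniformly over n blocks of p
chromosomes:

P({I_d} | j) = n!/(∏_d I_d!) · ∏_d C(p,d)^{I_d} / C(pn, j),

with I_p = (j − Σ_{d<p} d·I_d)/p and I₀ = n − Σ_{d≥1} I_d; any key whose
implied homozygote counts are not non-negative integers has probability
zero (in particular the divisibility constraint on j − Σ d·I_d).
Published renderings of this formula are easy to mis-read around the two
implied factorial arguments, so the implementation was frozen only after
exact agreement (1e−12, actually ~1e−15) with brute-force enumeration of
all C(pn, j) chromosome placements for every (n, p, j) with pn ≤ 12; the
test suite re-runs that enumeration. The diploid p = 2 specialization
reproduces the classical joint frequency–heterozygosity spectrum,
including its parity constraint (j − I₁ even).

Support enumeration (`expected_sds()`) runs a bounded composition search
applying the divisibility constraint last-digit-first, because the
support is sparse; probabilities are computed in log-space
(`lfactorial`/`lchoose`), stable far beyond pn = 40.

# Read-count estimators

The estimators operate on per-individual depths r_i(x) and derived read
counts c_i(x), with no dosage calling. Two per-site units are unbiased
for the population heterozygosity 2f(1−f) under binomial read sampling
from the dosage:

- within individual j: (p/(p−1)) · 2c(r−c)/(r(r−1)), needing r ≥ 2; the
  p/(p−1) factor converts read pairs (chromosomes drawn *with*
  replacement) to chromosome pairs drawn without replacement;
- between individuals j,k: (c_j(r_k−c_k) + c_k(r_j−c_j))/(r_j r_k),
  needing both depths ≥ 1.

A θ estimate is a weighted average of these units. Two design points were
genuinely open and are resolved as follows:

1. **Normalization.** Weights must sum to one for unbiasedness. The
   equal-weight estimator `theta_pi()` uses weight 1 per within unit and
   2 per unordered cross pair, which at full coverage is
   (1/n²)[(p/(p−1))Σπ_j + 2Σ_{j<k}π_{jk}] — an average over ordered
   individual pairs with self-pairs served by the corrected within term.
   Renderings of this estimator with a 2/(n(n−1)) prefactor are *not*
   unbiased (their weights sum to 2n/(n−1)); the simulation suite pins
   the expectation at θ to within Monte-Carlo error.
2. **Per-site renormalization.** Units that are unobservable at a site
   (r < 2 within, r = 0 cross) are excluded and the remaining weights
   renormalized *at that site*, rather than entering as structural
   zeros. Without this, mean depth 2 biases θ̂ down by roughly 13%;
   with it the estimator stays unbiased at any depth. A site where no
   unit is observable contributes nothing (no information exists there).

`theta_pi_mvue()` keeps the same units but weights them by approximate
inverse variances, v_j = (4/r̄_j + 4/p)⁻¹ and
u_{jk} = (1/r̄_j + 1/r̄_k + 2/p)⁻¹, built from each individual's mean
depth r̄_j. With equal mean depths u = 2v exactly, so the weighted
estimator *coincides* with `theta_pi()`; under heterogeneous coverage it
down-weights noisy individuals and its empirical variance is lower.
Individuals with zero mean depth are excluded with a warning.

`theta_zeng()` weights segregating sites linearly in derived frequency:
it sums the pooled derived read fraction Σc/Σr over sites whose reads
show both alleles, each divided by a per-site normalizer

N_L(x) = Σ_{k=1}^{pn−1} [ 1/(pn) − A_k(x)/k ],

where A_k(x) = E[∏_i (k_i/p)^{r_i(x)}] is the probability, under the
neutral multivariate-hypergeometric DD at count k, that every read is
derived — i.e. that a segregating site masquerades as a fixed difference
and is lost from the SNP list. The constant is fixed by requiring exact
unbiasedness: E[Σc/Σr | k] = k/(pn) and the all-derived outcomes
contribute exactly their probability, so dividing by N_L makes the sum
unbiased for θ and reduces, at infinite depth, to the classical
frequency-weighted estimator Σ_j j·ξ_j/(pn−1). A_k is computed by
dynamic programming over the convolution of per-individual count
polynomials (O(n·p·pn) per site, with rescaling against overflow), so
n in the tens is cheap. N_L is non-decreasing in every depth.

Watterson's `theta_watterson()` is S/a_m. Because sequencing errors
masquerade as rare variants and inflate S, it should only be fed
quality-filtered SNP calls; the pairwise estimators, which give rare
alleles negligible weight, are the robust default.

## Neutrality tests

`tajima_d()` contrasts θ̂_π with S/a_m; `fay_wu_h()` uses the numerator
2(θ̂_π − θ̂_L) (equivalently θ̂_π − θ̂_H with θ_H = 2θ_L − θ_π, reported for
audit). Exact finite-depth variances of these numerators are
intractable, so the denominators are the classical neutral variance
formulas with the haploid sample size replaced by the effective number
of sequenced chromosomes n_eff = (1/L)ΣΣ p[1 − (1−1/p)^{r}]. Three
numerical decisions:

- n_eff is generally non-integer; every coefficient (a_m, b_m, and the
  normalized-H variance) uses the digamma/trigamma continuation of the
  harmonic sums, so the statistics vary smoothly with depth (rounding
  would make them discontinuous).
- θ and θ² inside the variances use the standard unbiased plug-ins
  S/a_m and S(S−1)/(a_m² + b_m) at m = n_eff.
- S counts sites whose reads show both alleles; S = 0 is an error
  (the test is undefined), as is n_eff ≤ 1.

The substitution is an approximation: the tests are centered near zero
under neutrality (verified by simulation), but their null spread is not
exactly one and depends on θ and depth — significance should come from a
parametric bootstrap with the simulator, not from ±2 rules. With sites
simulated independently (free recombination) the null spread is narrower
than under full linkage; at θ ≈ 2 per locus it sits in roughly
[0.6, 1.6].

# Hardy–Weinberg violations

One generation of random mating with polysomic inheritance maps a DD
I to Σ_{k′,k″} I_{k′}I_{k″}·(gamete convolution), where gametes draw p/2
of p chromosomes hypergeometrically (no double reduction). Every
binomial DD is a fixed point (`random_mating_residual()` verifies this to
1e−12). Perturbations at linear order:

- **Polysomic selfing** (`selfing_perturbation()`): ΔI = p_s(Self·I⁰ − I⁰)
  with both gametes drawn independently from the same parent. Mass- and
  frequency-conserving; excess homozygotes.
- **Disomic selfing** (`disomic_selfing_perturbation()`): the parent's k′
  derived alleles sit uniformly over p/2 fixed homolog pairs (h
  heterozygous pairs with probability C(p/2,h)C(p/2−h,(k′−h)/2)2^h /
  C(p,k′)); each heterozygous pair selfs like a diploid locus, so the
  offspring dosage is (k′−h) + Binomial(2h, ½). This kernel was
  reconstructed from the mechanism and validated against a per-pair
  mating simulation; at p = 2 it coincides with the polysomic kernel.
- **Mixed inheritance**: the convex combination with weights (1−p₂, p₂).
- **Selection** (`selection_perturbation()`): fitness 1 + s_k per dosage
  class, linearized about the HW point. The stationary linear system
  (I − M)ΔI = M(I⁰s) is *singular*: HW equilibria form a one-parameter
  family in f, so (I − M) has a null direction along dHW/df. For schemes
  that shift the allele frequency (recessive deleterious selection), the
  meaningful deviation is the quasi-steady shape relative to HW *at the
  drifting frequency*; it solves the drift-corrected system
  [(I − M) + w kᵀM/p]ΔI = b − w(kᵀb)/p with w = dHW/df, which is
  non-singular and matches a deterministic iteration of the full
  selection+mating map (re-based to HW at the current frequency) to
  three significant figures in the tests. For symmetric schemes at
  f = ½ the correction vanishes. A pseudoinverse fallback (projected
  onto the mass-conserving subspace) guards pathological inputs with a
  warning. Mass and frequency are conserved by construction.

Selfing rates and |s_k| above 0.2 trigger a warning: the theory is
first-order.

`integrate_over_neutral_frequencies()` averages ΔI(f) against the
neutral density θ/f on a uniform grid (default 197 points on
[0.01, 0.99]; the integrands are bounded near both ends because
ΔI ~ f and ~1−f there, so the cutoff is benign and the default grid is
converged to the third digit). Amplitudes are arbitrary — they scale
with p_s or s — so only shapes and signs are meaningful.

For a sample of one individual the SFS *is* the heterozygous DD slice
(`single_individual_sfs()`): classes d = 1..p−1 with neutral expectation
θ/d; homozygous sites are invisible as polymorphisms, so a deviation's
visible part need not sum to zero. `test_direction()` gives the unit
vector of linear responses of the D and H numerators (classical SFS
weights at m = p chromosomes).

**Sign convention.** The standard Fay–Wu/Zeng convention is used
throughout: H's numerator is 2(θ_π − θ_L), so an excess of
high-frequency derived variants drives H negative. Under this
convention and the θ/f measure, the computed directions are: selfing
(D > 0, H < 0, the singleton deficit dominating H through its positive
weight), disomic selfing the same signs, heterozygote advantage
(H > 0 with |D| ≪ |H| in tetraploids), recessive deleterious (H < 0,
driven by derived homozygotes resurfacing as visible dosage-(p−1)
variants at high f). Qualitative descriptions of the first two
scenarios sometimes state the opposite H sign; no single sign
convention reconciles all such statements with the mechanistic
kernels, which here are anchored to forward-simulation oracles, so the
package reports the standard-convention result. The relative magnitude
pattern — selfing more visible in H than D for tetraploids, the
reverse above ploidy 6 — follows from the same computation.

# The simulator and what passing tests mean

`simulate_neutral_genotypes()` draws S ~ Poisson(θ·a_pn) segregating
sites, site counts j ∝ 1/j, and places the j derived copies uniformly
over the pn chromosomes — sampling the finite-sample SDS exactly without
enumeration. Defaults in the test suite emulate a realistic small
resequencing study of a tetraploid: θ = 5 per locus, n = 10 individuals,
mean depth 8–10, error rate 0 for estimator calibration. Reads are
binomial in dosage with Poisson (or fixed) depth and an optional
symmetric per-read error flip.

Deliberate simplifications: sites are independent (free recombination —
no linkage disequilibrium, hence narrower null spread for D and H than
a single-genealogy locus would show); no error-rate modeling inside the
estimators (errors are a simulation stressor, not a corrected term); the
two-deme Wahlund generator (`simulate_two_deme_mixture()`) draws
Balding–Nichols deme frequencies around a shared ancestral frequency —
enough to exhibit the pooled homozygote excess, not a calibrated
demographic model. Passing tests therefore demonstrate correctness of
the estimators under the stated sampling model, not robustness to
linkage, base-calling artifacts or reference bias in real data.

Problem sizes in the routine suite were chosen to give tight Monte-Carlo
error at interactive runtimes: 2000 replicates for estimator
unbiasedness and the variance comparison (r̄ ∈ {2, 20} split for the
heterogeneous-coverage case), 1000 replicates per ploidy for test
centering, 120–400 replicates for secondary properties, enumeration
oracles exhaustive up to pn = 12 and constraint checks to pn = 40.

# Limitations

- Uniform, even ploidy across individuals; mixed-ploidy samples are
  rejected. Allopolyploids (homeologous divergence) are out of scope.
- Double reduction is excluded from all inheritance kernels.
- Derived orientation is required for the unfolded spectra and H;
  folded-spectrum analogues are not provided.
- Perturbation results are first-order and report arbitrary amplitude;
  they describe shapes and directions, not effect sizes.
- The test denominators inherit the n_eff approximation; use the
  simulator for null quantiles.
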