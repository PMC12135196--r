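---
title: "Estimating heritabilities and genetic correlations from predictivity in time slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heritabilities and genetic correlations from predictivity in time slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predslice)
```

## The problem

Under intense genomic selection, genetic parameters are not constants.
Directional selection builds negative linkage disequilibrium among causal
loci (the Bulmer effect) and erodes additive variance of selected traits,
while correlations between production and fitness traits can drift as
resource allocation shifts. Selection indices built on stale parameters
over-promise genetic gain and can let fitness decline unnoticed. The
established estimators (REML, Bayesian Gibbs sampling) scale cubically or
quadratically with the number of genotyped animals and are unusable for
routine monitoring at the scale of modern evaluations (10^5–10^6 genotypes).

`predslice` implements a closed-form alternative whose only expensive step is
an ordinary genomic evaluation. It combines two expressions for the accuracy
of genomic breeding values:

* from **predictivity**, the correlation between validation animals' adjusted
  phenotypes and their GEBVs computed without those phenotypes:
  \(acc = c / h\), with \(c = \mathrm{Corr}(y - X\hat b,\ \hat u)\);
* from population structure: \(acc = \sqrt{N h^2 / (N h^2 + M_e)}\), with
  \(N\) the number of genotyped-and-phenotyped reference animals and
  \(M_e\) the number of independent chromosome segments.

Equating the two and solving for the heritability gives

\[
\hat h^2 = \frac{c^2 + \sqrt{c^4 + 4 c^2 M_e / N}}{2},
\]

and the cross-trait predictivity \(c_{ij} = \mathrm{Corr}(y_i - X\hat
b_i,\ \hat u_j)\) yields the genetic correlation
\(\hat r_g = c_{ij} / (h_i\, acc_j)\). Applied to sliding windows of
consecutive generations (here two reference generations and one validation
generation), these formulas track parameter trajectories over time at the
cost of one single-trait GBLUP per trait and window.

## The estimation procedure

`timeslice()` (or `make_windows()` + `run_timeslice()` /
`estimate_window()`) executes, per window:

1. single-trait GBLUP per trait with reference phenotypes only; validation
   animals' genotypes enter the relationship matrix but their phenotypes are
   masked (`solve_gblup()`);
2. predictivities on the validation generation for every ordered trait pair
   (`predictivity()`), phenotypes adjusted by the fixed-effect estimates from
   the same solve;
3. heritability per trait from the within-trait predictivity, with \(N\) the
   count of reference animals having both genotype and a phenotype for that
   trait;
4. accuracy per trait as \(c/\hat h\) (not the expected-accuracy formula:
   the procedure's accuracy step precedes the correlation step);
5. genetic correlations for **both** trait orders — they are asymptotically
   equal but differ in finite samples, and their standard errors differ;
   the order using the phenotype of the faster-changing trait and the GEBV
   of the stabler trait is the less biased one in practice;
6. iteration: the GBLUP is re-run with the updated heritabilities until the
   largest per-trait change falls below `tol` (default 0.01, `max_iter`
   10). With large data the estimates are nearly insensitive to the starting
   values, so iteration usually stops after one refinement pass.

Standard errors use the closed forms
\(SE(acc) < 1/(h_i\sqrt n)\), \(SE(\hat r_g) < 1/(h_i\,acc_j\sqrt n)\) and
the delta-method form for \(SE(\hat h^2)\), all evaluated at the final
parameter values. A caveat worth stating: the printed delta-method form for
\(SE(\hat h^2)\) (whose large-\(N\) limit is \(1.5c/\sqrt n\)) is not the
exact derivative of the heritability formula — the exact derivative's limit
is \(2c/\sqrt n\). We implement the published closed form and document the
difference; the package's tests pin the exact algebraic relation between the
two.

### Applicability and numerical choices

* The estimator is designed for **large** reference populations. Its
  sensitivity to \(M_e\) is governed by \(M_e/(N h^2)\); the
  `min_reference_size()` rule (\(N > M_e/(3h^2)\), i.e. expected accuracy
  above about 0.7) marks the comfortable regime.
* Estimates are clamped to their natural ranges (\([0,1]\) for \(h^2\) and
  accuracy, \([-1,1]\) for \(r_g\)) with a warning; the raw value is kept in
  `attr(, "raw")` because an accuracy above 1 is itself a useful diagnostic
  of an overstated heritability.
* \(SE(\hat h^2)\) is undefined at \(c = 0\) (the linearisation degenerates);
  `NA` is returned rather than 0.
* The GRM is VanRaden method 1, allele frequencies computed from the
  combined reference + validation genotypes (a fixed, reproducible choice),
  blended as \((1-\alpha)G + \alpha I\) with \(\alpha = 0.05\) for guaranteed
  invertibility.
* The mixed model is solved by direct dense factorisation. The default route
  factorises the reference-block phenotypic covariance
  \(V = h^2 G_{rr} + (1-h^2) I\) (GLS for \(\hat b\), then
  \(\hat u = h^2 G_{\cdot r} V^{-1}(y - X\hat b)\)); `method = "mme"` builds
  Henderson's equations with \(G^{-1}\) explicitly. The two are algebraically
  identical for an invertible G; the package tests them against each other
  and against a from-scratch inversion oracle. The V-route is the default
  because its factorisation is of size \(n_{ref}\) rather than
  \(n_{all} + p\).
* Only the variance **ratio** \(\lambda = (1-h^2)/h^2\) matters for GEBVs up
  to scale, and predictivities are scale-free correlations, so phenotypic
  variances never need to be known.
* Fixed effects: an overall mean, optionally one categorical factor. Within
  a window the validation set is a single generation, so a mean adjustment
  suffices there; the adjustment uses the estimates from the same solve that
  produced the GEBVs.
* `me_from_ne_l()` implements \(M_e \approx 4 N_e L\);
  `me_from_grm_eigenvalues()` implements the alternative reading — the
  number of leading eigenvalues of the (unblended) GRM explaining 98% of its
  variation, computed on a random subset (default 5000) for large matrices,
  with negative numerical eigenvalues truncated at zero. Blending is removed
  first because it inflates the spectrum's tail. On a finite sample the
  eigenvalue count reads systematically below \(4N_eL\) unless the sample
  size is much larger than \(M_e\); treat it as an order-of-magnitude
  companion, not a replacement.

## The simulator

`run_generations()` emulates a closed nucleus under genomic truncation
selection, the setting in which parameter drift is fastest and monitoring
matters most:

* **Genome**: `genome_spec()`; the desk-scale default is 10 chromosomes of
  100 cM with 500 evenly spaced markers and 30 uniformly placed QTN each
  (the `scale = "paper"` preset has 30 chromosomes with ~1667 markers and
  100 QTN each). Meiosis follows the Haldane model: Poisson crossover counts
  per chromosome, uniform positions, no interference, no mutation.
* **Founders**: per-locus allele frequencies uniform on \([0.1, 0.5]\)
  (linkage equilibrium), followed by a bottleneck burn-in — a census of 200
  with 25 random sires and 25 random dams per generation (\(N_e = 50\),
  matching the selection scheme) — and an expansion to the founder count.
  The burn-in depth (default 10) was chosen with a diagnostic, not by
  convention: it is the depth at which the realized GEBV accuracy in
  no-selection pilots agrees with the expected-accuracy formula at
  \(M_e = 4 N_e L\), i.e. the depth at which the population actually *is*
  the population the estimator assumes. Shallower burn-in leaves too little
  linkage disequilibrium (effective \(M_e\) far above \(4N_eL\)); deeper
  burn-in overshoots it.
* **Traits**: two genetically independent base traits with gamma-distributed
  QTN effect magnitudes (shape 0.4 — a strongly leptokurtic, few-large-genes
  architecture; the shape is a design choice, as only the family is
  standard), random signs, effects rescaled so the founder additive variance
  is exactly 1. Residual variances 1.5 and 9 give founder heritabilities
  0.40 (production) and 0.10 (fitness scaffold). Breeding values are always
  recomputed from QTN genotypes, never drawn from a covariance matrix, so
  the genetic covariance structure is exactly the one the GRM sees.
* **Composite fitness trait**:
  \(u_3 = \alpha_j\,[u_2 - \beta u_1 (u_1 - \bar u_{1,0})]\), with
  \(\alpha_j\) restandardising the variance to 1 within each generation and
  the centering constant frozen at the generation-0 mean of \(u_1\). As
  selection moves \(u_1\) away from the centering point, the correlation
  between traits 1 and 3 drifts downward — an engineered stand-in for a
  trait whose biological definition changes over time. Its phenotypes use
  the trait-2 residual variance, so its realized heritability stays at 0.10
  by construction. Trait 2 itself is latent scaffolding: its phenotypes are
  generated but not analysed.
* **Selection**: each generation is evaluated by single-trait GBLUP on the
  production trait with the fixed initial heritability 0.4 (the evaluation
  the breeder would run, not the estimator under study); the top 13 males
  and top 500 females (desk scale; 10,000 at full scale) become parents,
  dams with equal family sizes and sires drawn uniformly per mating, for
  \(N_e = 4 N_m N_f/(N_m+N_f) \approx 50\). A `"random"` criterion provides
  the no-selection control.
* **β calibration**: `calibrate_beta()` finds the \(\beta\) whose mean
  per-generation decline of the realized \(\mathrm{corr}(u_1, u_3)\) matches
  a target (default −0.1). Because trait 3 never feeds back into selection,
  one pilot run fixes the \(u_1, u_2\) trajectories and the decline implied
  by any \(\beta\) can be evaluated exactly on the pilot data; the search is
  a monotone grid plus bisection. The shipped default \(\beta = 0.0794\) is
  the desk-scale calibration; an independent seed reproduces the target
  within ±0.03.

### What the desk scale does and does not show

The shipped default configuration (2000 offspring per generation, 7
generations, 4–8 replicates) runs the whole study in minutes on one CPU.
Two quantitative differences from the full-scale setting matter when
interpreting results:

* With 300 QTN instead of 3000, individual QTN effects are larger and
  selection fixes them faster; the realized production heritability falls
  roughly three times faster per generation. The estimator has a known lag
  of about 1.5 generations (the reference window trails the validation
  generation), so its deviation from realized values grows in proportion to
  the decline rate: ~0.02 at full scale, ~0.04–0.07 at desk scale. This is
  a property of the estimator under rapid change, not a defect of the
  implementation — the package's acceptance checks report the honest number.
* At desk scale \(M_e/N = 0.5\) (versus ~0.075 at full scale), well below
  the `min_reference_size()` comfort zone, so the estimates are far more
  sensitive to the \(M_e\) assumption and to the close-family structure that
  the independent-segments model ignores.

The simulator also idealises real data: no genotyping errors, no missing
genotypes or phenotypes, no pedigree errors, discrete generations, a single
fixed effect, and founders from a drift bottleneck rather than a realistic
demographic history. Passing recovery tests here shows the estimator does
what its algebra promises under its own assumptions; it does not certify
performance under selective genotyping or model misspecification, which the
source analyses flag as the main practical risks.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config()                      # desk-scale study conditions
sim <- run_generations(cfg, seed = 1)    # ~20 s
summary(sim)                             # realized parameters per generation

me <- me_from_ne_l(50, 10)$me            # 2000 segments
fit <- timeslice(sim$genotypes, sim$individuals, traits = c("y1", "y3"),
                 me = me, initial_h2 = c(0.4, 0.1), first_validation = 3)
summary(fit)
plot(fit)
```

The same pipeline is scriptable from a shell via the `exec/predslice`
entry point (`calc`, `me`, `simulate`, `estimate` subcommands), and
`scripts/acceptance.R` reruns the full study — closed forms, calibration,
replicated simulation, estimation, sensitivity to starting values — from one
seed.

## Known limitations

* No REML/Gibbs reference estimates, no single-step GBLUP, no multi-trait
  mixed model, no missing-genotype handling (pre-impute or drop).
* The expected-accuracy model ignores close-relative information; with
  strong family structure and small \(N h^2/M_e\) the heritability is
  overestimated (see above).
* The eigenvalue \(M_e\) estimator needs sample sizes well above \(M_e\) to
  be read quantitatively.
* Adjustment of phenotypes for estimated fixed effects assumes a model with
  a single random effect; correlated random effects (e.g. random regression)
  break the predictivity identity.
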