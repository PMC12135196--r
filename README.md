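# predslice

Estimation of heritabilities and genetic correlations in **time slices** for
large genomic-prediction settings, from **predictivity** — the correlation
between validation animals' phenotypes adjusted for fixed effects and their
genomic breeding values (GEBVs).

## Who this is for

Breeding programs under genomic selection see genetic parameters change
within a few generations: additive variance of selected traits erodes (the
Bulmer effect) and correlations between production and fitness traits can
turn antagonistic. REML or Gibbs-sampling estimators scale cubically or
quadratically with the number of genotyped animals and cannot be run
routinely on evaluations with 10^5–10^6 genotypes. `predslice` implements a
closed-form estimator whose only expensive step is an ordinary single-trait
genomic evaluation, making per-generation parameter monitoring feasible at
any scale at which GEBVs themselves can be computed.

## The estimator

Two expressions for the accuracy of GEBVs are equated: from predictivity
`c = Corr(y − Xb̂, û)` on `n` validation animals, `acc = c/h`; and from the
reference size `N` and the number of independent chromosome segments `Me`,
`acc = sqrt(N h² / (N h² + Me))`. Solving for the heritability:

    ĥ² = ( c² + sqrt(c⁴ + 4 c² Me / N) ) / 2

Cross-trait predictivity `c_ij = Corr(y_i − Xb̂_i, û_j)` gives the genetic
correlation `r̂_g = c_ij / (h_i · acc_j)` (both trait orders are reported —
they differ in finite samples). Standard errors: `SE(acc) < 1/(h_i √n)`,
`SE(r̂_g) < 1/(h_i acc_j √n)`, and a delta-method form for `SE(ĥ²)` that
simplifies to `1.5 c/√n` for `N ≫ Me`. Applied over sliding windows of
generations (2 reference + 1 validation by default), the estimates trace
parameter trajectories over time.

The package also provides: `Me` estimation (`4·Ne·L` or the 98% eigenvalue
rule on the GRM), a VanRaden-GRM GBLUP solver used to compute the
predictivities, and a forward-in-time breeding-program simulator (truncation
selection on GEBV, Haldane meiosis, gamma QTN effects, and an engineered
composite fitness trait whose correlation with the selected trait declines
by a calibrated amount per generation) for validating parameter recovery.

## Worked example

Scalar calculator — the published large-dairy case (predictivity 0.55,
580,000 reference animals, Me = 15,000):

```r
library(predslice)
h2_from_predictivity(0.55, 580000, 15000)
#> [1] 0.3264716
se_h2(0.55, 381000, 15000, 580000)
#> [1] 0.001346223
min_reference_size(15000, 0.05)
#> [1] 100000
```

A heritability of 0.33 recovered from predictivity alone (close to the 0.35
the study assumed), with a negligible standard error at that validation
size; and a trait with h² = 0.05 needs a reference population of about
100,000 for the expected accuracy to clear ~0.7.

Full pipeline on simulated data (desk scale, ~1 min):

```r
cfg <- sim_config()                     # 2000 offspring/gen, 13 sires + 500 dams,
sim <- run_generations(cfg, seed = 1)   # 7 generations under GEBV selection
summary(sim)                            # realized h2 and cor(u1,u3) per generation

fit <- timeslice(sim$genotypes, sim$individuals, traits = c("y1", "y3"),
                 me = me_from_ne_l(50, 10)$me, initial_h2 = c(0.4, 0.1),
                 first_validation = 3)
coef(fit)        # heritability estimates per window and trait
summary(fit)     # tidy table: h2, accuracy, r_g (both orders), SEs
plot(fit)        # trajectories with 95% bands
```

Each window row reports the predictivity-based heritability of the selected
production trait (declining across generations as selection erodes variance),
the fitness-trait heritability (stable at ~0.1 by construction), and the
genetic correlation between them estimated from both predictivity orders,
with closed-form standard errors.

A command-line wrapper with `calc`, `me`, `simulate` and `estimate`
subcommands is installed at `exec/predslice`:

```sh
Rscript exec/predslice calc h2 --predictivity 0.55 --n-ref 580000 --me 15000 --json
Rscript exec/predslice simulate --out runs/ --seed 1 --replicates 2
```

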