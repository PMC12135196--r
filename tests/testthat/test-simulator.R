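# Forward-in-time simulator: determinism, inheritance, meiosis, trait
# construction, selection response and realized parameters.

test_that("a fixed seed reproduces the population bit for bit", {
  cfg <- tiny_config()
  a <- run_generations(cfg, seed = 99)
  b <- run_generations(cfg, seed = 99)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$effects, b$effects)
  c2 <- run_generations(cfg, seed = 100)
  expect_false(identical(a$individuals$y1, c2$individuals$y1))
})

test_that("founder allele frequencies honour the configured range", {
  g <- tiny_genome(founder_maf_range = c(0.2, 0.4))
  pop <- simulate_founders(g, 50, seed = 41, burn_in = 0, burn_in_size = 50)
  expect_true(all(pop$founder_freq >= 0.2 & pop$founder_freq <= 0.4))
})

test_that("burn-in builds linkage disequilibrium that decays with distance", {
  g <- tiny_genome(n_chromosomes = 1, markers_per_chromosome = 120,
                   qtn_per_chromosome = 2)
  pop <- simulate_founders(g, 400, seed = 42, burn_in = 10,
                           burn_in_size = 120, burn_in_parents = 20)
  dos <- pop$H0 + pop$H1
  keep <- which(apply(dos, 2, sd) > 0)
  r2 <- cor(dos[, keep])^2
  m <- length(keep)
  adjacent <- r2[cbind(1:(m - 1), 2:m)]
  distant <- r2[cbind(1:(m - 60), 61:m)]
  expect_gt(mean(adjacent), mean(distant))
})

test_that("offspring haplotypes are mosaics of parental alleles", {
  g <- tiny_genome()
  pop <- simulate_founders(g, 60, seed = 43, burn_in = 2,
                           burn_in_size = 60, burn_in_parents = 10)
  scheme <- selection_scheme(n_sires = 4, n_dams = 10,
                             offspring_per_generation = 40,
                             n_generations = 1,
                             selection_criterion = "random")
  off <- select_and_mate(pop, NULL, scheme, generation = 1)
  for (o in seq_len(10)) {
    s <- match(off$sire[o], pop$ids)
    d <- match(off$dam[o], pop$ids)
    expect_true(all(off$H0[o, ] == pop$H0[s, ] | off$H0[o, ] == pop$H1[s, ]))
    expect_true(all(off$H1[o, ] == pop$H0[d, ] | off$H1[o, ] == pop$H1[d, ]))
  }
  # parent bookkeeping
  expect_true(all(off$sire %in% pop$ids[pop$sex == "M"]))
  expect_true(all(off$dam %in% pop$ids[pop$sex == "F"]))
})

test_that("crossover counts follow the Haldane model", {
  # fully heterozygous parent with known phase: strand switches along a
  # 1-Morgan chromosome count the realized crossovers
  g <- genome_spec(n_chromosomes = 1, chromosome_length_cm = 100,
                   markers_per_chromosome = 200, qtn_per_chromosome = 1)
  map <- predslice:::.make_map(g)
  n <- 10000
  H0 <- matrix(0L, 2, map$n_loci); H1 <- matrix(1L, 2, map$n_loci)
  set.seed(44)
  gam <- predslice:::.meiosis(H0, H1, rep(1L, n), map)
  switches <- rowSums(abs(gam[, -1, drop = FALSE] -
                          gam[, -ncol(gam), drop = FALSE]))
  expect_equal(mean(switches), 1.0, tolerance = 0.05)
  # and offspring sexes are assigned about 1:1
  pop <- simulate_founders(g, 400, seed = 45, burn_in = 0, burn_in_size = 400)
  expect_equal(mean(pop$sex == "M"), 0.5, tolerance = 0.01)
})

test_that("QTN effects are variance-scaled, independent and leptokurtic", {
  set.seed(46)
  dos <- matrix(rbinom(2000 * 3000, 2, 0.3), 2000, 3000)
  eff <- sample_qtn_effects(3000, gamma_shape = 0.4, qtn_dosage = dos)
  u <- dos %*% eff
  expect_equal(apply(u, 2, var), c(1, 1), tolerance = 1e-6)
  expect_lt(abs(cor(u[, 1], u[, 2])), 3 / sqrt(2000))
  expect_gt(max(abs(eff[, 1])) / median(abs(eff[, 1])), 10)
})

test_that("the composite trait is variance-standardised and reduces at beta 0", {
  set.seed(47)
  u1 <- rnorm(5000); u2 <- rnorm(5000)
  ct <- composite_trait(u1, u2, beta = 0, ref_mean_u1 = mean(u1))
  expect_equal(var(ct$u3), 1, tolerance = 1e-12)
  expect_equal(cor(u1, ct$u3), cor(u1, u2), tolerance = 1e-12)
  ct2 <- composite_trait(u1, u2, beta = 0.4, ref_mean_u1 = mean(u1))
  expect_equal(var(ct2$u3), 1, tolerance = 1e-12)
  expect_error(composite_trait(rep(1, 5), rep(1, 5), 0, 1), "zero variance")
})

test_that("a centered symmetric u1 adds no composite correlation", {
  # for a symmetric centered u1, cor(u1, u1*(u1 - mean)) ~ 0, so the beta
  # term contributes no correlation: independent base traits stay
  # uncorrelated with the composite for any beta, and for correlated base
  # traits the correlation is attenuated exactly by the variance the beta
  # term adds to the composite
  set.seed(48)
  n <- 100000
  u1 <- rnorm(n); u2 <- rnorm(n)
  ct <- composite_trait(u1, u2, beta = 0.5, ref_mean_u1 = mean(u1))
  expect_lt(abs(cor(u1, ct$u3)), 3 / sqrt(n) + 0.01)
  u2c <- 0.3 * u1 + rnorm(n, 0, sqrt(1 - 0.09))
  ct2 <- composite_trait(u1, u2c, beta = 0.5, ref_mean_u1 = mean(u1))
  attenuation <- 1 / sqrt(1 + 0.5^2 * var(u1 * (u1 - mean(u1))))
  expect_equal(cor(u1, ct2$u3), cor(u1, u2c) * attenuation, tolerance = 0.02)
})

test_that("truncation selection takes the top GEBV parents", {
  g <- tiny_genome()
  pop <- simulate_founders(g, 80, seed = 49, burn_in = 1,
                           burn_in_size = 80, burn_in_parents = 10)
  gebv <- rnorm(80)
  scheme <- selection_scheme(n_sires = 3, n_dams = 8,
                             offspring_per_generation = 40, n_generations = 1)
  off <- select_and_mate(pop, gebv, scheme, generation = 1)
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  top_sires <- pop$ids[males[order(gebv[males], decreasing = TRUE)[1:3]]]
  top_dams <- pop$ids[females[order(gebv[females], decreasing = TRUE)[1:8]]]
  expect_setequal(off$selected$sires, top_sires)
  expect_setequal(off$selected$dams, top_dams)
  # equal dam family sizes
  expect_true(all(table(off$dam) == 5))
  expect_error(select_and_mate(pop, gebv,
                               selection_scheme(n_sires = 60, n_dams = 8,
                                                offspring_per_generation = 80,
                                                n_generations = 1), 1),
               "fewer candidates")
})

test_that("founder heritabilities match the configured variances", {
  sim <- run_generations(tiny_config(n_generations = 1), seed = 50)
  r0 <- sim$realized[sim$realized$generation == 0, ]
  # var(u) = 1 by construction, residuals 1.5 / 9 / 9
  expect_equal(r0$h2_1, 1 / 2.5, tolerance = 1e-6)
  expect_equal(r0$h2_2, 1 / 10, tolerance = 1e-6)
  expect_equal(r0$h2_3, 1 / 10, tolerance = 1e-6)
  # u is exactly the QTN dosage weighted by effects
  u <- sim$qtn_dosage %*% sim$effects
  expect_equal(sim$individuals$u1, unname(u[, 1]), tolerance = 1e-12)
  expect_equal(sim$individuals$u2, unname(u[, 2]), tolerance = 1e-12)
  # phenotypic variance ~ var(u) + residual variance
  d0 <- sim$individuals[sim$individuals$generation == 0, ]
  expect_equal(var(d0$y1), var(d0$u1) + 1.5, tolerance = 0.15)
  expect_equal(var(d0$y3), var(d0$u3) + 9, tolerance = 0.1)
})

test_that("selection raises the mean and erodes heritability of trait 1", {
  sim <- run_generations(tiny_config(n_generations = 4, offspring = 400,
                                     n_dams = 60), seed = 51)
  r <- sim$realized
  expect_true(all(diff(r$mean_u1) > 0))        # monotone genetic gain
  expect_lt(r$h2_1[5], r$h2_1[1])              # Bulmer + drift
  # parents recorded and taken from the previous generation
  ind <- sim$individuals
  g2 <- ind[ind$generation == 2, ]
  expect_true(all(g2$sire %in% ind$id[ind$generation == 1]))
})

test_that("without selection the realized parameters stay put", {
  # random parents at a comfortable effective size: heritability starts at
  # 0.4 exactly and only drifts; with beta = 0 the trait-1/trait-3
  # correlation keeps its founder value (which, with few QTN, need not be 0)
  sim <- run_generations(tiny_config(n_generations = 4, offspring = 500,
                                     n_sires = 25, n_dams = 100,
                                     selection = "random",
                                     beta = 0, qtn_per_chromosome = 40),
                         seed = 52)
  r <- sim$realized
  expect_equal(r$h2_1[1], 0.4, tolerance = 1e-6)
  expect_lt(max(abs(r$h2_1 - 0.4)), 0.08)
  expect_lt(max(abs(r$cor_u1_u3 - r$cor_u1_u3[1])), 0.15)
  expect_lt(abs(r$mean_u1[5] - r$mean_u1[1]), 0.6)
})

test_that("effective population size follows the hierarchical formula", {
  expect_equal(effective_population_size(13, 500), 50.68, tolerance = 1e-3)
  expect_true(abs(effective_population_size(13, 10000) - 50) < 2)
  expect_equal(effective_population_size(25, 25), 50)
})

test_that("beta calibration hits the target decline on held-out data", {
  cfg <- tiny_config(n_generations = 4, offspring = 400, n_dams = 60)
  cal <- calibrate_beta(cfg, target_decline = -0.08, seed = 53,
                        beta_grid = seq(0.02, 0.3, by = 0.04))
  expect_s3_class(cal, "beta_calibration")
  expect_equal(cal$decline, -0.08, tolerance = 1e-3)   # exact on pilot data
  expect_true(all(diff(cal$grid$decline) < 0))         # monotone in beta
  # held-out seed reproduces the decline at small-population tolerance
  cfg2 <- tiny_config(n_generations = 4, offspring = 400, n_dams = 60,
                      beta = cal$beta)
  sim <- run_generations(cfg2, seed = 54)
  dec <- (sim$realized$cor_u1_u3[5] - sim$realized$cor_u1_u3[1]) / 4
  # a small population drifts a lot; require the right sign and rough size
  expect_lt(dec, -0.03)
  expect_gt(dec, -0.2)
  # unreachable target fails loudly
  expect_error(calibrate_beta(cfg, target_decline = -5, seed = 55,
                              beta_grid = c(0.01, 0.02)), "not reachable")
})
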