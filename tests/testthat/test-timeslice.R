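# Window construction and the sliding-window estimation procedure.

test_that("windows slide by one generation with the right reference sets", {
  w <- make_windows(0:6, ref_len = 2, first_validation = 3)
  expect_length(w, 4)
  expect_equal(lapply(w, `[[`, "validation"), list(3L, 4L, 5L, 6L))
  expect_equal(w[[1]]$reference, 1:2)
  expect_equal(w[[4]]$reference, 4:5)
  w2 <- make_windows(0:2, ref_len = 2)
  expect_length(w2, 1)
  expect_equal(w2[[1]]$reference, 0:1)
  expect_equal(w2[[1]]$validation, 2L)
  expect_error(make_windows(0:1, ref_len = 2), "at least")
  expect_error(make_windows(0:6, ref_len = 2, first_validation = 1),
               "leave room")
})

sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_generations(tiny_config(n_generations = 3,
                                            offspring = 300, n_dams = 50,
                                            markers_per_chromosome = 80),
                                seed = 61)
    cache
  }
})

test_that("the slice result is internally consistent with the closed forms", {
  sim <- sim_small()
  w <- make_windows(0:3, ref_len = 2)[[2]]   # {1,2} -> 3
  res <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                         initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"))
  expect_false(res$failed)
  expect_equal(res$n_validation, 300)
  expect_equal(unname(res$n_reference), c(600, 600))
  tt <- res$traits
  # the reported heritability is exactly the formula applied to the reported
  # predictivity (the procedure adds nothing beyond the formula chain)
  for (i in 1:2) {
    expect_equal(tt$h2[i],
                 as.numeric(h2_from_predictivity(abs(tt$c[i]), 600, 400)),
                 tolerance = 1e-10)
    expect_equal(tt$acc[i],
                 as.numeric(acc_from_predictivity(abs(tt$c[i]), tt$h2[i])),
                 tolerance = 1e-10)
    expect_equal(tt$se_h2[i], se_h2(abs(tt$c[i]), 300, 400, 600),
                 tolerance = 1e-10)
    expect_equal(tt$se_acc[i], se_accuracy(tt$h2[i], 300), tolerance = 1e-10)
  }
  # both trait orders present, with estimator-consistent values and SEs
  pp <- res$pairs
  expect_setequal(paste(pp$trait_pheno, pp$trait_ebv),
                  c("y1 y3", "y3 y1"))
  for (i in seq_len(nrow(pp))) {
    hi <- tt$h2[tt$trait == pp$trait_pheno[i]]
    aj <- tt$acc[tt$trait == pp$trait_ebv[i]]
    expect_equal(pp$r_g_raw[i], pp$c[i] / (sqrt(hi) * aj), tolerance = 1e-10)
    expect_equal(pp$se[i], se_gencorr(hi, aj, 300), tolerance = 1e-10)
  }
})

test_that("a single-pass window equals the hand-run GBLUP pipeline", {
  sim <- sim_small()
  w <- make_windows(0:3, ref_len = 2)[[2]]
  res <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                         initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"),
                         max_iter = 1, tol = 1e-12)
  ind <- sim$individuals
  rid <- ind$id[ind$generation %in% 1:2]
  vid <- ind$id[ind$generation == 3]
  G <- build_grm(sim$genotypes[c(rid, vid), ])
  for (i in 1:2) {
    tr <- c("y1", "y3")[i]
    h2 <- c(0.4, 0.1)[i]
    y <- setNames(ind[[tr]], ind$id)
    fit <- solve_gblup(y[rid], NULL, G, h2, rid)
    ya <- adjusted_phenotype(y[vid], NULL, fit$fixed_effect_estimates)
    cc <- predictivity(ya, fit$gebv[vid], tr, tr, w$window_id)
    expect_equal(res$traits$c[res$traits$trait == tr], cc$c,
                 tolerance = 1e-10)
    expect_equal(res$traits$h2[res$traits$trait == tr],
                 as.numeric(h2_from_predictivity(abs(cc$c), length(rid), 400)),
                 tolerance = 1e-10)
  }
})

test_that("iteration refines and reports convergence honestly", {
  sim <- sim_small()
  w <- make_windows(0:3, ref_len = 2)[[2]]
  one <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                         initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"),
                         max_iter = 1, tol = 1e-9)
  expect_equal(one$iterations, 1L)
  expect_false(one$converged)
  many <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                          initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"),
                          max_iter = 10, tol = 0.001)
  expect_true(many$converged)
  expect_lte(many$iterations, 10L)
  # starting far away converges to nearly the same fixed point
  far <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                         initial_h2 = c(0.8, 0.05), traits = c("y1", "y3"),
                         max_iter = 20, tol = 0.001)
  expect_equal(far$traits$h2, many$traits$h2, tolerance = 0.05)
})

test_that("a supplied GRM must cover the window and then reproduces results", {
  sim <- sim_small()
  w <- make_windows(0:3, ref_len = 2)[[2]]
  ids <- sim$individuals$id[sim$individuals$generation %in% 1:3]
  G <- build_grm(sim$genotypes[ids, ])
  a <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                       initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"))
  b <- estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                       initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"),
                       grm = G)
  expect_equal(a$traits, b$traits, tolerance = 1e-10)
  G_bad <- build_grm(sim$genotypes[ids[-1], ])
  expect_error(estimate_window(sim$genotypes, sim$individuals, w, me = 400,
                               initial_h2 = c(0.4, 0.1),
                               traits = c("y1", "y3"), grm = G_bad),
               "cover")
})

test_that("a run over all windows matches per-window estimation", {
  sim <- sim_small()
  ws <- make_windows(0:3, ref_len = 2)
  fit <- run_timeslice(sim$genotypes, sim$individuals, ws, me = 400,
                       initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"))
  expect_s3_class(fit, "timeslice")
  expect_length(fit$results, 2)
  solo <- estimate_window(sim$genotypes, sim$individuals, ws[[1]], me = 400,
                          initial_h2 = c(0.4, 0.1), traits = c("y1", "y3"))
  expect_equal(fit$results[[1]]$traits, solo$traits, tolerance = 1e-12)
  # tidy table shape: per window, 2 h2 + 2 acc + 2 r_g rows
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 2 * 6)
  expect_setequal(unique(df$estimate_type), c("h2", "acc", "r_g"))
  cf <- coef(fit)
  expect_equal(dim(cf), c(2, 2))
  expect_equal(colnames(cf), c("y1", "y3"))
})

test_that("the formula interface builds windows from the phenotype table", {
  sim <- sim_small()
  fit <- timeslice(sim$genotypes, sim$individuals, traits = c("y1", "y3"),
                   me = me_from_ne_l(50, 2), initial_h2 = c(0.4, 0.1),
                   first_validation = 3)
  expect_length(fit$results, 1)
  expect_equal(fit$results[[1]]$validation, 3L)
  expect_equal(fit$me, 400)
})

test_that("degenerate windows are flagged, not fatal", {
  sim <- sim_small()
  ph <- sim$individuals
  ph$yflat <- ph$y1
  ph$yflat[ph$generation == 3] <- 5  # constant validation phenotype
  ws <- make_windows(0:3, ref_len = 2)
  expect_warning(
    fit <- run_timeslice(sim$genotypes, ph, ws[2], me = 400,
                         initial_h2 = c(0.4, 0.1),
                         traits = c("yflat", "y3")),
    "failed")
  expect_true(fit$results[[1]]$failed)
  df <- as.data.frame(fit)
  expect_equal(df$estimate_type, "failed")
})

test_that("null data yield genetic correlations within noise of zero", {
  # no selection, beta = 0: traits 1 and 3 genetically uncorrelated
  sim <- run_generations(tiny_config(n_generations = 2, offspring = 500,
                                     n_dams = 60, selection = "random",
                                     beta = 0, markers_per_chromosome = 80),
                         seed = 62)
  fit <- timeslice(sim$genotypes, sim$individuals, traits = c("y1", "y3"),
                   me = 400, initial_h2 = c(0.4, 0.1))
  pp <- fit$results[[1]]$pairs
  expect_true(all(abs(pp$r_g) < 3 * pp$se))
})
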