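# Forward-in-time genomic-selection simulator: founder genomes with LD built
# by a bottleneck burn-in, gamma-distributed QTN effects for two genetically
# independent traits, an engineered composite fitness trait whose genetic
# correlation with the selected trait drifts as selection moves the
# population, GBLUP-based truncation selection, and realized-parameter
# tracking.
#
# Internal population representation: two haplotype matrices H0 (paternal) and
# H1 (maternal), individuals x loci, integer 0/1; the locus map interleaves
# markers and QTN along each chromosome.

#' Genome specification
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_cm Length of each chromosome in centiMorgans.
#' @param markers_per_chromosome Biallelic SNP markers per chromosome.
#' @param qtn_per_chromosome Causal loci (QTN) per chromosome; QTN positions
#'   are drawn uniformly and are distinct from marker positions.
#' @param founder_maf_range Interval from which per-locus founder allele
#'   frequencies are drawn.
#' @param scale `"desk"` (default) or `"paper"`: presets for a desk-scale run
#'   (10 chromosomes x 100 cM, 500 markers + 30 QTN each) or the full-scale
#'   design (30 chromosomes x 100 cM, ~1667 markers + 100 QTN each).
#' @return A `"genome_spec"` list.
#' @export
genome_spec <- function(n_chromosomes = 10, chromosome_length_cm = 100,
                        markers_per_chromosome = 500, qtn_per_chromosome = 30,
                        founder_maf_range = c(0.1, 0.5), scale = "desk") {
  if (identical(scale, "paper")) {
    n_chromosomes <- 30; markers_per_chromosome <- 1667
    qtn_per_chromosome <- 100
  }
  stopifnot(n_chromosomes >= 1, chromosome_length_cm > 0,
            markers_per_chromosome >= 1, qtn_per_chromosome >= 1,
            length(founder_maf_range) == 2,
            founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
            founder_maf_range[1] <= founder_maf_range[2])
  structure(list(n_chromosomes = n_chromosomes,
                 chromosome_length_cm = chromosome_length_cm,
                 markers_per_chromosome = markers_per_chromosome,
                 qtn_per_chromosome = qtn_per_chromosome,
                 founder_maf_range = founder_maf_range),
            class = "genome_spec")
}

#' Trait architecture
#'
#' Two genetically independent base traits with founder additive variance
#' scaled to 1 (a production trait, residual variance 1.5, h2 = 0.4; and a
#' latent fitness-scaffold trait, residual variance 9, h2 = 0.1), plus the
#' composite third trait \eqn{u_3 = \alpha_j [u_2 - \beta u_1 (u_1 - \bar
#' u_{1,0})]} whose correlation with trait 1 declines under selection on
#' trait 1.  The phenotype of trait 3 uses the same residual variance as
#' trait 2.
#'
#' @param gamma_shape Shape of the gamma distribution of QTN effect
#'   magnitudes (signs random), default 0.4.
#' @param residual_variances Residual variances of the three observed traits,
#'   default `c(1.5, 9, 9)`.
#' @param beta Composite-trait coefficient; the default is the value
#'   calibrated with [calibrate_beta()] so the realized correlation between
#'   traits 1 and 3 declines by about 0.1 per generation under the default
#'   selection scheme.
#' @return A `"trait_architecture"` list.
#' @export
trait_architecture <- function(gamma_shape = 0.4,
                               residual_variances = c(1.5, 9, 9),
                               beta = 0.0794) {
  stopifnot(gamma_shape > 0, length(residual_variances) == 3,
            all(residual_variances > 0))
  structure(list(gamma_shape = gamma_shape,
                 residual_variances = residual_variances, beta = beta),
            class = "trait_architecture")
}

#' Selection scheme
#'
#' Truncation selection on trait-1 GEBV within each sex; selected dams
#' contribute equal family sizes and sires are assigned to matings uniformly
#' at random.  The default desk scale (13 sires, 500 dams, 2000 offspring per
#' generation) keeps the effective population size
#' \eqn{N_e = 4 N_m N_f / (N_m + N_f) \approx 50} and the dam-selection
#' fraction (~50%) of the full-scale design (13 sires, 10,000 dams, 40,000
#' offspring).
#'
#' @param n_sires,n_dams Numbers of male and female parents per generation.
#' @param offspring_per_generation Offspring produced each generation.
#' @param n_generations Number of selected generations after generation 0.
#' @param selection_h2 Heritability used in the selection-stage GBLUP every
#'   generation (the "initial parameters"), default 0.4.
#' @param selection_criterion `"gebv"` for truncation selection on trait-1
#'   GEBV, `"random"` for a no-selection control with randomly chosen parents.
#' @param scale `"desk"` (default) or `"paper"` preset.
#' @return A `"selection_scheme"` list.
#' @export
selection_scheme <- function(n_sires = 13, n_dams = 500,
                             offspring_per_generation = 2000,
                             n_generations = 6, selection_h2 = 0.4,
                             selection_criterion = c("gebv", "random"),
                             scale = "desk") {
  if (identical(scale, "paper")) {
    n_dams <- 10000; offspring_per_generation <- 40000
  }
  selection_criterion <- match.arg(selection_criterion)
  stopifnot(n_sires >= 1, n_dams >= 1,
            offspring_per_generation >= n_sires + n_dams,
            n_generations >= 1, selection_h2 > 0, selection_h2 < 1)
  structure(list(n_sires = n_sires, n_dams = n_dams,
                 offspring_per_generation = offspring_per_generation,
                 n_generations = n_generations, selection_h2 = selection_h2,
                 selection_trait = 1,
                 selection_criterion = selection_criterion),
            class = "selection_scheme")
}

#' Effective population size of a hierarchical mating scheme
#'
#' \eqn{N_e = 4 N_m N_f / (N_m + N_f)}.
#'
#' @param n_sires,n_dams Numbers of male and female parents.
#' @return Effective population size.
#' @examples
#' effective_population_size(13, 500)  # ~ 50
#' @export
effective_population_size <- function(n_sires, n_dams) {
  4 * n_sires * n_dams / (n_sires + n_dams)
}

#' Simulation run configuration
#'
#' Bundles genome, trait architecture, selection scheme and founder/burn-in
#' settings.
#'
#' @param genome A [genome_spec()].
#' @param traits A [trait_architecture()].
#' @param scheme A [selection_scheme()].
#' @param burn_in Number of bottleneck burn-in generations used to build
#'   linkage disequilibrium before generation 0 (default 10, chosen so the
#'   realized GEBV accuracy structure of the simulated population is
#'   consistent with the independent-segments model at Me = 4 Ne L).
#' @param burn_in_size Census size of the burn-in population (default 200).
#' @param burn_in_parents Sires (= dams) drawn at random each burn-in
#'   generation (default 25 + 25, i.e. Ne = 50, matching the selection
#'   scheme's effective size).
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(genome = genome_spec(), traits = trait_architecture(),
                       scheme = selection_scheme(), burn_in = 10,
                       burn_in_size = 200, burn_in_parents = 25) {
  stopifnot(inherits(genome, "genome_spec"),
            inherits(traits, "trait_architecture"),
            inherits(scheme, "selection_scheme"),
            burn_in >= 0, burn_in_size >= 4,
            2 * burn_in_parents <= burn_in_size)
  structure(list(genome = genome, traits = traits, scheme = scheme,
                 burn_in = burn_in, burn_in_size = burn_in_size,
                 burn_in_parents = burn_in_parents),
            class = "sim_config")
}

# ---- locus map ------------------------------------------------------------

# markers evenly spaced, QTN at uniform random positions (distinct from
# markers with probability 1); positions in Morgans
.make_map <- function(genome) {
  L <- genome$chromosome_length_cm / 100
  nm <- genome$markers_per_chromosome
  nq <- genome$qtn_per_chromosome
  chrs <- vector("list", genome$n_chromosomes)
  idx0 <- 0L
  marker_idx <- integer(0); qtn_idx <- integer(0)
  for (k in seq_len(genome$n_chromosomes)) {
    pos_m <- (seq_len(nm) - 0.5) / nm * L
    pos_q <- sort(stats::runif(nq, 0, L))
    pos <- c(pos_m, pos_q)
    type <- rep(c("marker", "qtn"), c(nm, nq))
    o <- order(pos)
    pos <- pos[o]; type <- type[o]
    gidx <- idx0 + seq_along(pos)
    marker_idx <- c(marker_idx, gidx[type == "marker"])
    qtn_idx <- c(qtn_idx, gidx[type == "qtn"])
    chrs[[k]] <- list(pos = pos, idx = gidx, length_m = L)
    idx0 <- idx0 + length(pos)
  }
  list(chromosomes = chrs, n_loci = idx0,
       marker_idx = marker_idx, qtn_idx = qtn_idx)
}

# ---- meiosis --------------------------------------------------------------

# one gamete per row of `parent_rows`, recombining H0/H1 of those parents.
# Haldane model: crossover count ~ Poisson(chromosome length in Morgans),
# positions uniform, no interference; starting strand random per chromosome.
.meiosis <- function(H0, H1, parent_rows, map) {
  n <- length(parent_rows)
  gam <- matrix(0L, n, map$n_loci)
  for (ch in map$chromosomes) {
    pos <- ch$pos; cols <- ch$idx; m <- length(cols)
    k <- stats::rpois(n, ch$length_m)
    start <- sample.int(2L, n, replace = TRUE) - 1L
    SW <- matrix(0L, n, m)
    for (i in which(k > 0L))
      SW[i, ] <- findInterval(pos, sort(stats::runif(k[i], 0, ch$length_m)))
    pick <- (SW + start) %% 2L == 1L
    A <- H0[parent_rows, cols, drop = FALSE]
    B <- H1[parent_rows, cols, drop = FALSE]
    A[pick] <- B[pick]
    gam[, cols] <- A
  }
  gam
}

# ---- founders -------------------------------------------------------------

#' Simulate founder population with burn-in linkage disequilibrium
#'
#' Draws a base population with per-locus allele frequencies uniform in the
#' configured range (loci initially in linkage equilibrium), then runs a
#' random-mating burn-in at a bottleneck census size with a fixed number of
#' randomly chosen parents per sex (default 25 + 25, Ne = 50) so that
#' drift-recombination linkage disequilibrium accumulates, and finally expands
#' to `n` individuals forming generation 0.
#'
#' @param genome A [genome_spec()].
#' @param n Number of generation-0 individuals.
#' @param seed Optional integer seed (full determinism under a fixed seed).
#' @param burn_in Burn-in generations (default 10).
#' @param burn_in_size Census size during burn-in (default 200).
#' @param burn_in_parents Parents per sex during burn-in (default 25).
#' @return An internal population list: haplotype matrices `H0`/`H1`, `ids`,
#'   `sex`, `sire`, `dam`, `generation`, and the locus `map`.
#' @export
simulate_founders <- function(genome, n, seed = NULL, burn_in = 10,
                              burn_in_size = 200, burn_in_parents = 25) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  map <- .make_map(genome)
  nl <- map$n_loci
  freq <- stats::runif(nl, genome$founder_maf_range[1],
                       genome$founder_maf_range[2])
  nb <- burn_in_size
  H0 <- matrix(stats::rbinom(nb * nl, 1L, rep(freq, each = nb)), nb, nl)
  H1 <- matrix(stats::rbinom(nb * nl, 1L, rep(freq, each = nb)), nb, nl)
  sex <- sample(rep_len(c("M", "F"), nb))
  for (g in seq_len(burn_in)) {
    last <- g == burn_in
    n_off <- if (last) n else nb
    sires <- sample(which(sex == "M"), burn_in_parents)
    dams <- sample(which(sex == "F"), burn_in_parents)
    sire_of <- sample(sires, n_off, replace = TRUE)
    dam_of <- sample(dams, n_off, replace = TRUE)
    H0n <- .meiosis(H0, H1, sire_of, map)
    H1n <- .meiosis(H0, H1, dam_of, map)
    H0 <- H0n; H1 <- H1n
    sex <- sample(rep_len(c("M", "F"), n_off))
  }
  if (burn_in == 0 && nb != n)
    stop("with burn_in = 0, `burn_in_size` must equal `n`", call. = FALSE)
  ids <- sprintf("G0_%05d", seq_len(n))
  list(H0 = H0, H1 = H1, ids = ids, sex = sex,
       sire = rep(NA_character_, n), dam = rep(NA_character_, n),
       generation = rep(0L, n), map = map, founder_freq = freq)
}

# ---- QTN effects ----------------------------------------------------------

#' Sample QTN effects
#'
#' Effect magnitudes are gamma-distributed (shape `gamma_shape`, unit rate)
#' with random signs, drawn independently for each trait, producing a
#' leptokurtic effect-size distribution (few large, many small effects).  When
#' founder QTN dosages are supplied, each trait's effects are rescaled so the
#' founder additive variance is exactly 1, which also makes the two base
#' traits genetically independent up to sampling error.
#'
#' @param n_qtn Number of causal loci.
#' @param gamma_shape Gamma shape parameter, default 0.4.
#' @param n_traits Number of base traits, default 2.
#' @param qtn_dosage Optional founder QTN dosage matrix (individuals x QTN)
#'   used for the variance-1 rescale.
#' @param seed Optional seed.
#' @return Matrix of effects, `n_qtn` x `n_traits`.
#' @export
sample_qtn_effects <- function(n_qtn, gamma_shape = 0.4, n_traits = 2,
                               qtn_dosage = NULL, seed = NULL) {
  stopifnot(gamma_shape > 0, n_qtn >= 1)
  if (!is.null(seed)) set.seed(seed)
  eff <- matrix(stats::rgamma(n_qtn * n_traits, shape = gamma_shape) *
                  sample(c(-1, 1), n_qtn * n_traits, replace = TRUE),
                n_qtn, n_traits)
  if (!is.null(qtn_dosage)) {
    stopifnot(ncol(qtn_dosage) == n_qtn)
    u <- qtn_dosage %*% eff
    s <- apply(u, 2, stats::sd)
    if (any(s == 0))
      stop("founder additive variance is zero for some trait", call. = FALSE)
    eff <- sweep(eff, 2, s, "/")
  }
  eff
}

#' Composite (fitness) trait
#'
#' \eqn{u_3 = \alpha [u_2 - \beta u_1 (u_1 - \bar u_{1,0})]}, with \eqn{\alpha}
#' chosen so that `var(u3)` is exactly 1 on the supplied vector.  With the
#' centering constant frozen at the generation-0 mean of trait 1, directional
#' selection on trait 1 shifts its distribution away from the centering point
#' and the correlation between traits 1 and 3 drifts, emulating a trait whose
#' definition changes over time.
#'
#' @param u1,u2 Breeding-value vectors of the two base traits, same length.
#' @param beta Composite coefficient.
#' @param ref_mean_u1 Centering constant (founder mean of trait 1).
#' @return List with `u3` (variance exactly 1) and `alpha`.
#' @export
composite_trait <- function(u1, u2, beta, ref_mean_u1) {
  stopifnot(length(u1) == length(u2), length(u1) >= 2)
  raw <- u2 - beta * u1 * (u1 - ref_mean_u1)
  s <- stats::sd(raw)
  if (s == 0) stop("composite trait has zero variance", call. = FALSE)
  alpha <- 1 / s
  list(u3 = alpha * raw, alpha = alpha)
}

# ---- selection and mating -------------------------------------------------

#' Select parents and produce the next generation
#'
#' Truncation selection on the supplied selection criterion (trait-1 GEBVs)
#' within each sex, or random parent choice for the control scheme; equal dam
#' family sizes; sires assigned to matings uniformly at random; gametes by
#' Haldane (Poisson-recombination) meiosis; offspring sexes balanced.
#'
#' @param pop Internal population list for the current generation (as produced
#'   by [simulate_founders()] or a previous call).
#' @param gebv Numeric vector of selection criteria for all candidates (same
#'   order as `pop$ids`); ignored when the scheme's criterion is `"random"`.
#' @param scheme A [selection_scheme()].
#' @param generation Integer label of the offspring generation.
#' @return Internal population list for the next generation.
#' @export
select_and_mate <- function(pop, gebv, scheme, generation) {
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  if (length(males) < scheme$n_sires || length(females) < scheme$n_dams)
    stop("fewer candidates than required parents (",
         length(males), " males, ", length(females), " females)",
         call. = FALSE)
  if (scheme$selection_criterion == "gebv") {
    stopifnot(length(gebv) == length(pop$ids))
    sires <- males[order(gebv[males], decreasing = TRUE)[seq_len(scheme$n_sires)]]
    dams <- females[order(gebv[females], decreasing = TRUE)[seq_len(scheme$n_dams)]]
  } else {
    sires <- sample(males, scheme$n_sires)
    dams <- sample(females, scheme$n_dams)
  }
  n_off <- scheme$offspring_per_generation
  fam <- n_off %/% scheme$n_dams
  extra <- n_off %% scheme$n_dams
  dam_of <- rep(dams, times = fam + (seq_along(dams) <= extra))
  sire_of <- sample(sires, n_off, replace = TRUE)
  H0 <- .meiosis(pop$H0, pop$H1, sire_of, pop$map)
  H1 <- .meiosis(pop$H0, pop$H1, dam_of, pop$map)
  list(H0 = H0, H1 = H1,
       ids = sprintf("G%d_%05d", generation, seq_len(n_off)),
       sex = sample(rep_len(c("M", "F"), n_off)),
       sire = pop$ids[sire_of], dam = pop$ids[dam_of],
       generation = rep(as.integer(generation), n_off),
       map = pop$map, founder_freq = pop$founder_freq,
       selected = list(sires = pop$ids[sires], dams = pop$ids[dams]))
}

# ---- full run -------------------------------------------------------------

#' Run the multi-generation genomic-selection simulation
#'
#' Simulates generation 0 founders (with burn-in LD), draws QTN effects for
#' the two base traits (founder additive variance 1), builds the composite
#' fitness trait, and then for each generation: phenotypes all individuals
#' (\eqn{y = u + e}), runs a single-trait GBLUP on trait 1 within the current
#' generation using the scheme's fixed selection heritability, selects parents
#' by truncation on GEBV (or at random for the control), and mates them to
#' produce the next generation.  True breeding values are always recomputed
#' from QTN genotypes.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   population.
#' @return A `"sim_population"` object: `individuals` (data frame with id,
#'   generation, sex, sire, dam, u1..u3, y1..y3), `genotypes` (marker dosage
#'   matrix for all individuals), `qtn_dosage`, `effects`, `alpha` (composite
#'   scaling per generation), `ref_mean_u1`, `beta`, `realized` (per-generation
#'   realized parameters), `config`, `seed`.
#' @export
run_generations <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  genome <- config$genome; traits <- config$traits; scheme <- config$scheme
  n_off <- scheme$offspring_per_generation
  J <- scheme$n_generations
  pop <- simulate_founders(genome, n_off, seed = NULL,
                           burn_in = config$burn_in,
                           burn_in_size = config$burn_in_size,
                           burn_in_parents = config$burn_in_parents)
  map <- pop$map
  n_qtn <- length(map$qtn_idx)
  Q <- (pop$H0 + pop$H1)[, map$qtn_idx, drop = FALSE]
  effects <- sample_qtn_effects(n_qtn, traits$gamma_shape, 2, qtn_dosage = Q)
  u12 <- Q %*% effects
  ref_mean_u1 <- mean(u12[, 1])

  n_total <- n_off * (J + 1)
  geno <- matrix(0L, n_total, length(map$marker_idx))
  qtn_all <- matrix(0L, n_total, n_qtn)
  ind <- vector("list", J + 1)
  alpha <- numeric(J + 1)
  sv <- traits$residual_variances

  for (j in 0:J) {
    rows <- j * n_off + seq_len(n_off)
    if (j > 0) {
      Q <- (pop$H0 + pop$H1)[, map$qtn_idx, drop = FALSE]
      u12 <- Q %*% effects
    }
    comp <- composite_trait(u12[, 1], u12[, 2], traits$beta, ref_mean_u1)
    alpha[j + 1] <- comp$alpha
    y1 <- u12[, 1] + stats::rnorm(n_off, 0, sqrt(sv[1]))
    y2 <- u12[, 2] + stats::rnorm(n_off, 0, sqrt(sv[2]))
    y3 <- comp$u3 + stats::rnorm(n_off, 0, sqrt(sv[3]))
    M <- (pop$H0 + pop$H1)[, map$marker_idx, drop = FALSE]
    rownames(M) <- pop$ids
    geno[rows, ] <- M
    qtn_all[rows, ] <- Q
    ind[[j + 1]] <- data.frame(id = pop$ids, generation = pop$generation,
                               sex = pop$sex, sire = pop$sire, dam = pop$dam,
                               u1 = u12[, 1], u2 = u12[, 2], u3 = comp$u3,
                               y1 = y1, y2 = y2, y3 = y3,
                               stringsAsFactors = FALSE)
    if (j < J) {
      if (scheme$selection_criterion == "gebv") {
        G <- build_grm(M)
        fit <- solve_gblup(stats::setNames(y1, pop$ids), NULL, G,
                           scheme$selection_h2, pop$ids)
        crit <- fit$gebv[pop$ids]
      } else crit <- NULL
      pop <- select_and_mate(pop, crit, scheme, j + 1L)
    }
  }
  individuals <- do.call(rbind, ind)
  rownames(geno) <- individuals$id
  rownames(qtn_all) <- individuals$id
  out <- structure(list(individuals = individuals, genotypes = geno,
                        qtn_dosage = qtn_all, effects = effects,
                        alpha = alpha, ref_mean_u1 = ref_mean_u1,
                        beta = traits$beta, config = config, seed = seed),
                   class = "sim_population")
  out$realized <- realized_parameters(out, sv)
  out
}

#' Realized genetic parameters per generation
#'
#' Within-generation realized heritabilities
#' \eqn{h^2_t = var(u_t)/(var(u_t) + \sigma^2_{e,t})} and the realized genetic
#' correlation between traits 1 and 3, computed directly from true breeding
#' values.
#'
#' @param pop A `"sim_population"` object, or a data frame with columns
#'   `generation`, `u1`, `u2`, `u3`.
#' @param residual_variances Residual variances of the three traits; defaults
#'   to the population's configured values when `pop` is a
#'   `"sim_population"`.
#' @return Data frame with one row per generation: realized h2 of each trait,
#'   `cor_u1_u3`, and mean breeding values of traits 1 and 3.
#' @export
realized_parameters <- function(pop, residual_variances = NULL) {
  if (inherits(pop, "sim_population")) {
    if (is.null(residual_variances))
      residual_variances <- pop$config$traits$residual_variances
    df <- pop$individuals
  } else df <- pop
  stopifnot(!is.null(residual_variances), length(residual_variances) == 3)
  gens <- sort(unique(df$generation))
  res <- lapply(gens, function(g) {
    d <- df[df$generation == g, , drop = FALSE]
    if (nrow(d) < 2)
      stop("generation ", g, " has fewer than 2 individuals", call. = FALSE)
    vu <- c(stats::var(d$u1), stats::var(d$u2), stats::var(d$u3))
    data.frame(generation = g,
               h2_1 = vu[1] / (vu[1] + residual_variances[1]),
               h2_2 = vu[2] / (vu[2] + residual_variances[2]),
               h2_3 = vu[3] / (vu[3] + residual_variances[3]),
               cor_u1_u3 = if (vu[1] > 0 && vu[3] > 0)
                 stats::cor(d$u1, d$u3) else 0,
               mean_u1 = mean(d$u1), mean_u3 = mean(d$u3))
  })
  do.call(rbind, res)
}

#' Calibrate the composite-trait coefficient
#'
#' Finds the \eqn{\beta} for which the realized correlation between traits 1
#' and 3 declines by a target amount per generation (default -0.1) under the
#' configured selection scheme.  Because trait 3 never feeds back into
#' selection, a single pilot run fixes the trajectories of \eqn{u_1} and
#' \eqn{u_2}, and the decline implied by any \eqn{\beta} can then be evaluated
#' exactly on the pilot data: the procedure evaluates a grid, checks that the
#' decline is monotone in \eqn{\beta}, and refines the bracketing interval by
#' bisection.
#'
#' @param config A [sim_config()]; its `beta` is irrelevant to the pilot.
#' @param target_decline Target mean per-generation change of the realized
#'   correlation, negative; default -0.1.
#' @param seed Seed for the pilot simulation.
#' @param beta_grid Grid of candidate coefficients, default
#'   `seq(0.01, 0.2, by = 0.01)`.
#' @return A `"beta_calibration"` list: `beta`, `decline` (achieved on the
#'   pilot), `grid` (data frame of candidate betas and their declines),
#'   `target_decline`, `seed`.
#' @export
calibrate_beta <- function(config, target_decline = -0.1, seed = NULL,
                           beta_grid = seq(0.01, 0.2, by = 0.01)) {
  stopifnot(target_decline < 0, length(beta_grid) >= 2)
  pilot <- run_generations(config, seed = seed)
  df <- pilot$individuals
  gens <- sort(unique(df$generation))
  J <- max(gens)
  m0 <- pilot$ref_mean_u1
  decline_of <- function(beta) {
    cors <- vapply(gens, function(g) {
      d <- df[df$generation == g, ]
      u3 <- composite_trait(d$u1, d$u2, beta, m0)$u3
      stats::cor(d$u1, u3)
    }, numeric(1))
    (cors[length(cors)] - cors[1]) / J
  }
  grid <- data.frame(beta = beta_grid,
                     decline = vapply(beta_grid, decline_of, numeric(1)))
  if (is.unsorted(rev(grid$decline)) && is.unsorted(grid$decline))
    warning("decline is not monotone in beta over the grid", call. = FALSE)
  if (target_decline < min(grid$decline) || target_decline > max(grid$decline))
    stop("target decline ", target_decline, " not reachable on the grid [",
         min(grid$decline), ", ", max(grid$decline), "]; widen `beta_grid`",
         call. = FALSE)
  i <- which(grid$decline <= target_decline)[1]
  lo <- grid$beta[i - 1]; hi <- grid$beta[i]
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (decline_of(mid) > target_decline) lo <- mid else hi <- mid
  }
  beta <- (lo + hi) / 2
  structure(list(beta = beta, decline = decline_of(beta), grid = grid,
                 target_decline = target_decline, seed = seed),
            class = "beta_calibration")
}

#' @export
print.beta_calibration <- function(x, ...) {
  cat(sprintf("Composite-trait calibration: beta = %.4f\n", x$beta))
  cat(sprintf("  mean per-generation decline of cor(u1, u3): %.4f (target %.2f)\n",
              x$decline, x$target_decline))
  invisible(x)
}

#' @export
print.sim_population <- function(x, ...) {
  g <- range(x$individuals$generation)
  cat("Simulated breeding population\n")
  cat("  ", nrow(x$individuals), " individuals, generations ", g[1], "-", g[2],
      ", ", ncol(x$genotypes), " markers, ", ncol(x$qtn_dosage), " QTN\n",
      sep = "")
  cat("  selection:", x$config$scheme$selection_criterion,
      "| beta =", x$beta, "\n")
  invisible(x)
}

#' @export
summary.sim_population <- function(object, ...) {
  cat("Realized parameters by generation:\n")
  print(object$realized, digits = 3, row.names = FALSE)
  invisible(object$realized)
}
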