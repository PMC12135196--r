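# Sliding-window ("time slice") estimation of heritabilities and genetic
# correlations: per window, single-trait GBLUP with reference phenotypes only,
# predictivities on the validation generation within and across traits,
# closed-form parameter re-estimation, and optional iteration with the updated
# heritabilities.

#' Construct sliding generation windows
#'
#' One window per feasible validation generation, sliding by one generation:
#' the reference is the `ref_len` generations immediately preceding the
#' validation generation.
#'
#' @param generations Ordered vector of generation labels.
#' @param ref_len Number of reference generations per window, default 2.
#' @param first_validation Optional label of the first validation generation
#'   (defaults to the earliest feasible one).
#' @return List of window specifications: each a list with `reference`
#'   (ordered labels), `validation` (single label), and `window_id`.
#' @examples
#' make_windows(0:6, ref_len = 2, first_validation = 3)
#' @export
make_windows <- function(generations, ref_len = 2, first_validation = NULL) {
  generations <- unique(generations)
  if (length(generations) < ref_len + 1)
    stop("need at least ref_len + 1 = ", ref_len + 1, " generations",
         call. = FALSE)
  first_feasible <- ref_len + 1
  start <- if (is.null(first_validation)) first_feasible else {
    w <- match(first_validation, generations)
    if (is.na(w) || w < first_feasible)
      stop("`first_validation` must leave room for ", ref_len,
           " reference generations", call. = FALSE)
    w
  }
  lapply(start:length(generations), function(v) {
    list(reference = generations[(v - ref_len):(v - 1)],
         validation = generations[v],
         window_id = paste0("val", generations[v]))
  })
}

# per-trait reference sets: individuals in the reference generations with both
# genotype and a non-missing phenotype for that trait
.window_sets <- function(genotypes, phenotypes, window, traits) {
  geno_ids <- rownames(genotypes)
  ph <- phenotypes[phenotypes$id %in% geno_ids, , drop = FALSE]
  ref <- ph[ph$generation %in% window$reference, , drop = FALSE]
  val <- ph[ph$generation %in% window$validation, , drop = FALSE]
  if (nrow(val) < 4)
    stop("window ", window$window_id, ": fewer than 4 genotyped validation ",
         "individuals", call. = FALSE)
  ref_ids <- lapply(traits, function(tr) ref$id[!is.na(ref[[tr]])])
  names(ref_ids) <- traits
  if (any(lengths(ref_ids) < 2))
    stop("window ", window$window_id, ": no phenotyped reference individuals ",
         "for some trait", call. = FALSE)
  list(ref = ref, val = val, ref_ids = ref_ids)
}

#' Estimate parameters in one generation window
#'
#' Executes the per-window estimation procedure: (i) univariate GBLUP per
#' trait using reference-generation phenotypes only, with validation-animal
#' genotypes included in the relationship matrix; (ii) predictivities for all
#' ordered trait pairs on the validation animals; (iii) heritability per trait
#' from the within-trait predictivity with N = number of reference individuals
#' having both genotype and phenotype for that trait; (iv) accuracies from the
#' updated heritabilities; (v) genetic correlations for both trait orders;
#' (vi) iteration of the GBLUP with the updated heritabilities until the
#' largest per-trait change is below `tol` or `max_iter` is reached.
#'
#' A window whose predictivity degenerates (constant GEBVs) is flagged failed
#' rather than raising an error, so a multi-window run can continue.
#'
#' @param genotypes Dosage matrix (individuals x markers) with row names.
#' @param phenotypes Data frame with columns `id`, `generation`, and one
#'   column per trait.
#' @param window A window specification from [make_windows()].
#' @param me Number of independent chromosome segments.
#' @param initial_h2 Named (by trait) or positional vector of starting
#'   heritabilities.
#' @param traits Character vector of trait column names.
#' @param max_iter Maximum GBLUP refits, default 10.
#' @param tol Convergence tolerance on the largest per-trait heritability
#'   change, default 0.01.
#' @param blend_alpha GRM identity-blend weight, default 0.05.
#' @param grm Optional precomputed `"grm"` over exactly the window's
#'   reference-plus-validation individuals (e.g. to re-estimate with different
#'   starting values without rebuilding it).
#' @param fixed_design Optional named factor for a single categorical fixed
#'   effect; default `NULL` fits an overall mean only (the validation set is a
#'   single generation, so mean adjustment suffices).
#' @return A `"slice_result"` list: `window_id`, `reference`, `validation`,
#'   `n_reference` (per trait), `n_validation`, `traits` (data frame with c,
#'   h2, se_h2, acc, se_acc per trait), `pairs` (data frame with c, r_g,
#'   r_g_raw, se per ordered trait pair), `iterations`, `converged`, `failed`.
#' @export
estimate_window <- function(genotypes, phenotypes, window, me, initial_h2,
                            traits, max_iter = 10, tol = 0.01,
                            blend_alpha = 0.05, grm = NULL,
                            fixed_design = NULL) {
  stopifnot(length(traits) >= 1, me > 0)
  h2 <- rep_len(as.numeric(initial_h2), length(traits))
  names(h2) <- traits
  sets <- .window_sets(genotypes, phenotypes, window, traits)
  all_ids <- c(unique(unlist(sets$ref_ids)), sets$val$id)
  all_ids <- unique(all_ids)
  if (is.null(grm)) {
    grm <- build_grm(genotypes[all_ids, , drop = FALSE], blend_alpha)
  } else if (!all(all_ids %in% rownames(grm)))
    stop("supplied `grm` does not cover the window's individuals",
         call. = FALSE)
  n_val <- nrow(sets$val)
  n_ref <- lengths(sets$ref_ids)

  failed_result <- function(msg) {
    warning("window ", window$window_id, " failed: ", msg, call. = FALSE)
    structure(list(window_id = window$window_id,
                   reference = window$reference,
                   validation = window$validation,
                   n_reference = n_ref, n_validation = n_val,
                   traits = NULL, pairs = NULL, iterations = 0L,
                   converged = FALSE, failed = TRUE, message = msg),
              class = "slice_result")
  }

  # cache the relationship-matrix subsets per unique reference set (the
  # traits usually share one); refits across iterations and repeated calls
  # with a supplied GRM then cost one Cholesky each, no re-subsetting
  ids <- rownames(grm)
  Gm <- unclass(grm)
  uniq_sets <- unique(sets$ref_ids)
  caches <- lapply(uniq_sets, function(rid) {
    ridx <- match(rid, ids)
    X <- .design_matrix(fixed_design, rid)
    if (qr(X)$rank < ncol(X))
      stop("fixed-effect design is rank deficient", call. = FALSE)
    list(ref_ids = rid, Grr = Gm[ridx, ridx, drop = FALSE],
         Gxr = Gm[, ridx, drop = FALSE], X = X,
         levels = if (is.null(fixed_design)) NULL else
           sort(unique(as.character(fixed_design[rid]))))
  })
  cache_of <- vapply(traits, function(tr)
    which(vapply(uniq_sets, identical, logical(1), sets$ref_ids[[tr]]))[1],
    integer(1))
  y_ref <- lapply(traits, function(tr)
    stats::setNames(sets$ref[[tr]], sets$ref$id)[sets$ref_ids[[tr]]])
  names(y_ref) <- traits

  it <- 0L; converged <- FALSE
  c_within <- stats::setNames(rep(NA_real_, length(traits)), traits)
  fits <- stats::setNames(vector("list", length(traits)), traits)
  stale <- stats::setNames(rep(TRUE, length(traits)), traits)
  repeat {
    it <- it + 1L
    for (tr in traits[stale]) {
      ca <- caches[[cache_of[[tr]]]]
      core <- .gblup_direct(ca$Grr, ca$Gxr, ca$X, y_ref[[tr]], h2[[tr]])
      est <- stats::setNames(drop(core$b), colnames(ca$X))
      attr(est, "levels") <- ca$levels
      fits[[tr]] <- list(gebv = stats::setNames(core$u, ids),
                         fixed_effect_estimates = est)
      yv <- stats::setNames(sets$val[[tr]], sets$val$id)
      keep <- names(yv)[!is.na(yv)]
      ya <- adjusted_phenotype(yv, fixed_design, est, keep)
      gv <- fits[[tr]]$gebv[keep]
      c_within[[tr]] <- if (stats::sd(gv) == 0 || stats::sd(ya) == 0)
        NA_real_ else stats::cor(ya, gv)
    }
    if (anyNA(c_within)) return(failed_result("degenerate predictivity"))
    h2_new <- vapply(traits, function(tr)
      as.numeric(h2_from_predictivity(abs(c_within[[tr]]), n_ref[[tr]], me)),
      numeric(1))
    delta <- abs(h2_new - h2)
    stale <- delta >= tol   # a trait within tolerance keeps its solution
    h2 <- stats::setNames(pmin(pmax(h2_new, 1e-6), 1 - 1e-6), traits)
    if (max(delta) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }

  acc <- vapply(traits, function(tr)
    as.numeric(acc_from_predictivity(abs(c_within[[tr]]), h2[[tr]])),
    numeric(1))
  tr_tab <- data.frame(trait = traits, c = unname(c_within),
                       h2 = unname(h2),
                       se_h2 = vapply(traits, function(tr)
                         suppressWarnings(se_h2(abs(c_within[[tr]]), n_val, me,
                                                n_ref[[tr]])), numeric(1)),
                       acc = unname(acc),
                       se_acc = se_accuracy(unname(h2), n_val),
                       n_reference = unname(n_ref),
                       stringsAsFactors = FALSE)

  pairs <- NULL
  if (length(traits) >= 2) {
    combos <- expand.grid(trait_pheno = traits, trait_ebv = traits,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$trait_pheno != combos$trait_ebv, , drop = FALSE]
    pairs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
      i <- combos$trait_pheno[r]; j <- combos$trait_ebv[r]
      yv <- stats::setNames(sets$val[[i]], sets$val$id)
      keep <- names(yv)[!is.na(yv)]
      ya <- adjusted_phenotype(yv, fixed_design,
                               fits[[i]]$fixed_effect_estimates, keep)
      gv <- fits[[j]]$gebv[keep]
      cc <- stats::cor(ya, gv)
      rg <- suppressWarnings(
        gencorr_from_predictivity(cc, h2[[i]], acc[[j]]))
      data.frame(trait_pheno = i, trait_ebv = j, c = cc,
                 r_g = as.numeric(rg), r_g_raw = attr(rg, "raw"),
                 se = se_gencorr(h2[[i]], acc[[j]], length(keep)),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(window_id = window$window_id, reference = window$reference,
                 validation = window$validation, n_reference = n_ref,
                 n_validation = n_val, traits = tr_tab, pairs = pairs,
                 iterations = it, converged = converged, failed = FALSE),
            class = "slice_result")
}

#' @export
print.slice_result <- function(x, ...) {
  cat("Window ", x$window_id, ": reference {",
      paste(x$reference, collapse = ", "), "} -> validation ", x$validation,
      "\n", sep = "")
  if (x$failed) {
    cat("  FAILED:", x$message, "\n"); return(invisible(x))
  }
  cat("  n_val =", x$n_validation, "; iterations =", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$traits, digits = 3, row.names = FALSE)
  if (!is.null(x$pairs)) print(x$pairs, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Run the time-slice estimation over multiple windows
#'
#' Applies [estimate_window()] independently to each window; failures are
#' propagated as flagged rows rather than aborting the run.
#'
#' @inheritParams estimate_window
#' @param windows List of window specifications from [make_windows()].
#' @param ... Passed on to [estimate_window()] (`max_iter`, `tol`,
#'   `blend_alpha`, `fixed_design`).
#' @return A `"timeslice"` object; see [timeslice()].
#' @export
run_timeslice <- function(genotypes, phenotypes, windows, me, initial_h2,
                          traits, ...) {
  results <- lapply(windows, function(w)
    tryCatch(estimate_window(genotypes, phenotypes, w, me, initial_h2,
                             traits, ...),
             error = function(e) {
               warning("window ", w$window_id, " failed: ",
                       conditionMessage(e), call. = FALSE)
               structure(list(window_id = w$window_id,
                              reference = w$reference,
                              validation = w$validation,
                              n_reference = NULL, n_validation = NA_integer_,
                              traits = NULL, pairs = NULL, iterations = 0L,
                              converged = FALSE, failed = TRUE,
                              message = conditionMessage(e)),
                         class = "slice_result")
             }))
  ord <- order(vapply(results, function(r) as.numeric(r$validation),
                      numeric(1)))
  results <- results[ord]
  structure(list(results = results, me = me, traits = traits,
                 initial_h2 = initial_h2, call = sys.call(-1)),
            class = "timeslice")
}

#' Fit the time-slice predictivity model
#'
#' The main fitting interface: builds sliding generation windows from the
#' phenotype table and estimates heritabilities, accuracies and genetic
#' correlations (both trait orders, with standard errors) in every window.
#'
#' @inheritParams estimate_window
#' @param ref_len Reference generations per window, default 2.
#' @param first_validation Optional first validation generation.
#' @param ... Passed on to [estimate_window()].
#' @return A `"timeslice"` object with `print`, `summary`, `coef`, `plot` and
#'   `as.data.frame` methods.  `coef()` returns the matrix of heritability
#'   estimates (windows x traits); `as.data.frame()` returns the tidy
#'   estimate table with one row per window and trait (or ordered trait
#'   pair).
#' @examples
#' \donttest{
#' cfg <- sim_config(
#'   genome = genome_spec(n_chromosomes = 2, markers_per_chromosome = 100,
#'                        qtn_per_chromosome = 20),
#'   scheme = selection_scheme(n_sires = 5, n_dams = 50,
#'                             offspring_per_generation = 200,
#'                             n_generations = 3),
#'   burn_in = 5)
#' sim <- run_generations(cfg, seed = 1)
#' fit <- timeslice(sim$genotypes, sim$individuals, traits = c("y1", "y3"),
#'                  me = me_from_ne_l(50, 2)$me, initial_h2 = c(0.4, 0.1))
#' fit
#' }
#' @export
timeslice <- function(genotypes, phenotypes, traits, me, initial_h2,
                      ref_len = 2, first_validation = NULL, ...) {
  if (inherits(me, "segments_estimate")) me <- me$me
  windows <- make_windows(sort(unique(phenotypes$generation)), ref_len,
                          first_validation)
  out <- run_timeslice(genotypes, phenotypes, windows, me, initial_h2,
                       traits, ...)
  out$call <- match.call()
  out
}

#' @export
as.data.frame.timeslice <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    if (r$failed)
      return(data.frame(window_id = r$window_id,
                        val_generation = r$validation,
                        trait = NA_character_, trait_ebv = NA_character_,
                        estimate_type = "failed", estimate = NA_real_,
                        se = NA_real_, n_ref = NA_integer_,
                        n_val = r$n_validation, iterations = r$iterations,
                        converged = r$converged, stringsAsFactors = FALSE))
    h <- data.frame(window_id = r$window_id, val_generation = r$validation,
                    trait = r$traits$trait, trait_ebv = r$traits$trait,
                    estimate_type = "h2", estimate = r$traits$h2,
                    se = r$traits$se_h2, n_ref = r$traits$n_reference,
                    n_val = r$n_validation, iterations = r$iterations,
                    converged = r$converged, stringsAsFactors = FALSE)
    a <- h; a$estimate_type <- "acc"; a$estimate <- r$traits$acc
    a$se <- r$traits$se_acc
    out <- rbind(h, a)
    if (!is.null(r$pairs)) {
      g <- data.frame(window_id = r$window_id, val_generation = r$validation,
                      trait = r$pairs$trait_pheno,
                      trait_ebv = r$pairs$trait_ebv,
                      estimate_type = "r_g", estimate = r$pairs$r_g,
                      se = r$pairs$se, n_ref = NA_integer_,
                      n_val = r$n_validation, iterations = r$iterations,
                      converged = r$converged, stringsAsFactors = FALSE)
      out <- rbind(out, g)
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
coef.timeslice <- function(object, ...) {
  ok <- !vapply(object$results, `[[`, logical(1), "failed")
  m <- t(vapply(object$results[ok], function(r)
    stats::setNames(r$traits$h2, r$traits$trait),
    numeric(length(object$traits))))
  rownames(m) <- vapply(object$results[ok], `[[`, character(1), "window_id")
  m
}

#' @export
print.timeslice <- function(x, ...) {
  cat("Time-slice predictivity estimates (Me =", x$me, ")\n")
  cat(length(x$results), "window(s); traits:",
      paste(x$traits, collapse = ", "), "\n\n")
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
summary.timeslice <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Time-slice predictivity estimates (Me =", object$me, ")\n")
  print(df, digits = 3, row.names = FALSE)
  invisible(df)
}

#' Plot parameter trajectories over validation generations
#'
#' Heritability trajectories per trait and, when at least two traits were
#' analysed, genetic-correlation trajectories for both trait orders, with
#' approximate 95% bands from the closed-form standard errors.
#'
#' @param x A `"timeslice"` object.
#' @param which `"h2"`, `"r_g"`, or both (default).
#' @param ... Further graphical arguments (ignored).
#' @export
plot.timeslice <- function(x, which = c("h2", "r_g"), ...) {
  df <- as.data.frame(x)
  df <- df[df$estimate_type %in% which & !is.na(df$estimate), , drop = FALSE]
  if (nrow(df) == 0) stop("nothing to plot", call. = FALSE)
  panels <- intersect(which, unique(df$estimate_type))
  old <- graphics::par(mfrow = c(1, length(panels)))
  on.exit(graphics::par(old))
  for (p in panels) {
    d <- df[df$estimate_type == p, ]
    key <- if (p == "r_g") paste0(d$trait, "|", d$trait_ebv) else d$trait
    groups <- unique(key)
    xs <- as.numeric(d$val_generation)
    ylim <- range(d$estimate - 2 * d$se, d$estimate + 2 * d$se, na.rm = TRUE)
    graphics::plot(NA, xlim = range(xs), ylim = ylim,
                   xlab = "validation generation",
                   ylab = if (p == "h2") "heritability" else
                     "genetic correlation",
                   main = if (p == "h2") "Heritability" else
                     "Genetic correlation (pheno|GEBV)")
    for (gi in seq_along(groups)) {
      dd <- d[key == groups[gi], ]
      o <- order(as.numeric(dd$val_generation))
      graphics::lines(as.numeric(dd$val_generation)[o], dd$estimate[o],
                      col = gi, type = "b", pch = 19)
      graphics::arrows(as.numeric(dd$val_generation)[o],
                       dd$estimate[o] - 2 * dd$se[o],
                       as.numeric(dd$val_generation)[o],
                       dd$estimate[o] + 2 * dd$se[o],
                       angle = 90, code = 3, length = 0.03, col = gi)
    }
    graphics::legend("topright", legend = groups, col = seq_along(groups),
                     lty = 1, pch = 19, bty = "n", cex = 0.8)
  }
  invisible(x)
}
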