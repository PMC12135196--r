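# Genomic relationship matrix, single-trait GBLUP, fixed-effect adjustment and
# predictivity.  The GRM is VanRaden method 1 with allele frequencies taken
# from the full supplied genotype set (reference + validation), blended with
# the identity for invertibility.

#' Build a genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = Z Z' / (2 \sum_k p_k (1 - p_k))}, where Z is the allele-dosage
#' matrix centered by twice the allele frequency, followed by identity
#' blending \eqn{G \leftarrow (1-\alpha) G + \alpha I}.  Frequencies are
#' computed from all supplied individuals; monomorphic markers contribute
#' nothing and are tolerated as long as at least one marker segregates.
#'
#' @param genotypes Individuals-by-markers matrix of allele dosages in
#'   \{0, 1, 2\}, with unique row names identifying individuals.  No missing
#'   values are allowed; pre-impute or drop incomplete markers beforehand.
#' @param blend_alpha Weight of the identity in the blend, default 0.05.
#' @return A `"grm"` object: the blended relationship matrix with attributes
#'   `blend_alpha`, `allele_freqs`, and `scale_k` (the VanRaden denominator).
#' @examples
#' M <- matrix(rbinom(40, 2, 0.4), nrow = 4,
#'             dimnames = list(paste0("id", 1:4), NULL))
#' G <- build_grm(M)
#' @export
build_grm <- function(genotypes, blend_alpha = 0.05) {
  if (!is.matrix(genotypes) || nrow(genotypes) < 2)
    stop("`genotypes` must be a matrix with >= 2 individuals", call. = FALSE)
  if (anyNA(genotypes))
    stop("missing genotypes are not supported; impute or drop markers",
         call. = FALSE)
  rng <- range(genotypes)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must be in {0, 1, 2}", call. = FALSE)
  if (is.null(rownames(genotypes)) || anyDuplicated(rownames(genotypes)))
    stop("`genotypes` must have unique row names (individual ids)",
         call. = FALSE)
  if (blend_alpha < 0 || blend_alpha >= 1)
    stop("`blend_alpha` must be in [0, 1)", call. = FALSE)
  p <- colMeans(genotypes) / 2
  k <- 2 * sum(p * (1 - p))
  if (k <= 0)
    stop("all markers are monomorphic; cannot build a relationship matrix",
         call. = FALSE)
  Z <- genotypes - rep(2 * p, each = nrow(genotypes))
  G <- tcrossprod(Z) / k
  if (blend_alpha > 0) {
    G <- (1 - blend_alpha) * G
    diag(G) <- diag(G) + blend_alpha
  }
  structure(G, class = c("grm", "matrix", "array"),
            blend_alpha = blend_alpha, allele_freqs = p, scale_k = k)
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix (VanRaden method 1)\n")
  cat("  individuals:", nrow(x),
      " blend_alpha:", attr(x, "blend_alpha"),
      " mean diagonal:", round(mean(diag(x)), 3), "\n")
  invisible(x)
}

# remove the identity blend, recovering the raw VanRaden G
unblend_grm <- function(grm) {
  a <- attr(grm, "blend_alpha")
  if (is.null(a) || a == 0) return(unclass(grm))
  G <- unclass(grm)
  diag(G) <- diag(G) - a
  G / (1 - a)
}

# direct mixed-model solve through the reference-block covariance
# V = h2 Grr + (1-h2) I: GLS for b, then u = h2 Gxr' ... (Gxr is all x ref).
# Triangular solves use backsolve(transpose=) to avoid materialising t(R).
.gblup_direct <- function(Grr, Gxr, X, y, h2) {
  V <- h2 * Grr
  diag(V) <- diag(V) + (1 - h2)
  R <- chol(V)
  ViX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  b <- solve(crossprod(X, ViX), crossprod(ViX, y))
  e <- y - drop(X %*% b)
  w <- backsolve(R, backsolve(R, e, transpose = TRUE))
  list(b = b, u = h2 * drop(Gxr %*% w))
}

# build the fixed-effect design matrix for a set of ids.
# fixed_design: NULL (overall mean only) or a named factor/character vector
# giving one categorical level per individual; the model is ~ factor (mean
# absorbed in the first level's estimate via treatment contrasts).
.design_matrix <- function(fixed_design, ids, levels = NULL) {
  if (is.null(fixed_design)) {
    X <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
    return(X)
  }
  f <- fixed_design[ids]
  if (anyNA(f))
    stop("fixed-effect level missing for some individuals", call. = FALSE)
  f <- factor(f, levels = if (is.null(levels)) sort(unique(f)) else levels)
  if (anyNA(f))
    stop("fixed-effect level present in validation but absent from the fit",
         call. = FALSE)
  if (nlevels(f) < 2)
    stop("the fixed factor needs at least 2 observed levels; ",
         "use NULL for a mean-only model", call. = FALSE)
  X <- stats::model.matrix(~f)
  rownames(X) <- ids
  colnames(X) <- c("(Intercept)", paste0("level:", base::levels(f)[-1]))
  X
}

#' Solve single-trait GBLUP
#'
#' Solves the single-trait mixed model \eqn{y = X b + u + e} with
#' \eqn{u \sim (0, G\sigma_u^2)}, using the variance ratio
#' \eqn{\lambda = \sigma_e^2/\sigma_u^2 = (1 - h^2)/h^2}.  Phenotypes of
#' reference individuals enter the right-hand side; all individuals covered by
#' the relationship matrix (including validation animals without phenotypes in
#' the solve) receive GEBVs.  The phenotypic variance need not be known:
#' GEBVs are invariant up to scale, and the predictivities computed from them
#' are scale-free correlations.
#'
#' @param phenotypes Named numeric vector of phenotypes (names are individual
#'   ids); must cover all `reference_ids`.
#' @param fixed_design `NULL` for an overall-mean-only model, or a named
#'   factor/character vector giving one categorical level per individual
#'   (a single fixed factor in addition to the mean).
#' @param grm A `"grm"` object (or symmetric matrix with dimnames) covering
#'   reference and validation individuals.
#' @param h2 Heritability used for shrinkage, in (0, 1).
#' @param reference_ids Ids of the individuals whose phenotypes enter the
#'   solve.
#' @param method `"direct"` (default) solves via the phenotypic covariance
#'   \eqn{V = h^2 G_{rr} + (1-h^2) I}: GLS for \eqn{\hat b}, then
#'   \eqn{\hat u = h^2 G_{\cdot r} V^{-1}(y - X\hat b)}.  `"mme"` builds and
#'   factorises the full mixed-model equations with \eqn{G^{-1}}; both routes
#'   are algebraically identical for an invertible G.
#' @return A `"gblup"` object: list with `gebv` (named vector over all
#'   individuals in the GRM), `fixed_effect_estimates`, `lambda_used`,
#'   `reference_ids`, `h2`, and `method`.
#' @export
solve_gblup <- function(phenotypes, fixed_design, grm, h2, reference_ids,
                        method = c("direct", "mme")) {
  method <- match.arg(method)
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0 || h2 >= 1)
    stop("`h2` must be a single value in (0, 1)", call. = FALSE)
  ids <- rownames(grm)
  if (is.null(ids)) stop("`grm` must have dimnames", call. = FALSE)
  if (!all(reference_ids %in% ids))
    stop("`grm` must cover all reference individuals", call. = FALSE)
  y <- phenotypes[reference_ids]
  if (anyNA(y))
    stop("phenotypes missing for some reference individuals", call. = FALSE)
  ridx <- match(reference_ids, ids)
  X <- .design_matrix(fixed_design, reference_ids)
  fit_levels <- if (is.null(fixed_design)) NULL else
    sort(unique(as.character(fixed_design[reference_ids])))
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient", call. = FALSE)
  G <- unclass(grm)
  nr <- length(ridx)
  lambda <- (1 - h2) / h2

  if (method == "direct") {
    core <- .gblup_direct(G[ridx, ridx, drop = FALSE],
                          G[, ridx, drop = FALSE], X, y, h2)
    b <- core$b; u <- core$u
  } else {
    # full Henderson mixed-model equations with G^{-1}
    Ginv <- solve(G)
    n <- nrow(G)
    W <- matrix(0, nr, n)
    W[cbind(seq_len(nr), ridx)] <- 1
    p <- ncol(X)
    LHS <- rbind(
      cbind(crossprod(X), crossprod(X, W)),
      cbind(crossprod(W, X), crossprod(W) + lambda * Ginv))
    RHS <- c(crossprod(X, y), crossprod(W, y))
    sol <- solve(LHS, RHS)
    b <- matrix(sol[seq_len(p)], ncol = 1, dimnames = list(colnames(X), NULL))
    u <- sol[-seq_len(p)]
  }
  names(u) <- ids
  est <- stats::setNames(drop(b), colnames(X))
  attr(est, "levels") <- fit_levels
  structure(list(gebv = u,
                 fixed_effect_estimates = est,
                 lambda_used = lambda, reference_ids = reference_ids,
                 h2 = h2, method = method,
                 fixed_design = fixed_design),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("Single-trait GBLUP solution\n")
  cat("  reference:", length(x$reference_ids), "individuals;  GEBVs for",
      length(x$gebv), "individuals\n")
  cat("  h2 =", x$h2, " (lambda =", format(x$lambda_used, digits = 4), ")\n")
  cat("  fixed effects:",
      paste(names(x$fixed_effect_estimates),
            format(x$fixed_effect_estimates, digits = 4),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Adjust phenotypes for estimated fixed effects
#'
#' Returns \eqn{y - X\hat b} for the given individuals, using fixed-effect
#' estimates from a GBLUP solve (the true fixed effects being unknown).
#'
#' @param phenotypes Named numeric vector of phenotypes.
#' @param fixed_design As in [solve_gblup()]; must provide a level for every
#'   individual being adjusted, and every such level must have an estimate.
#' @param fixed_estimates Named vector of fixed-effect estimates as returned in
#'   `fixed_effect_estimates` of a `"gblup"` object.
#' @param ids Individuals to adjust; defaults to all names of `phenotypes`.
#' @return Named vector of adjusted phenotypes.
#' @export
adjusted_phenotype <- function(phenotypes, fixed_design, fixed_estimates,
                               ids = names(phenotypes)) {
  y <- phenotypes[ids]
  if (anyNA(y)) stop("phenotypes missing for some ids", call. = FALSE)
  adj <- y - fixed_estimates[["(Intercept)"]]
  if (!is.null(fixed_design)) {
    f <- as.character(fixed_design[ids])
    if (anyNA(f)) stop("fixed-effect level missing for some ids", call. = FALSE)
    fit_levels <- attr(fixed_estimates, "levels")
    if (!is.null(fit_levels)) {
      unknown <- setdiff(unique(f), fit_levels)
      if (length(unknown))
        stop("no fixed-effect estimate for level(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    coefs <- fixed_estimates[-1]
    lv <- sub("^level:", "", names(coefs))
    m <- match(f, lv)  # levels without a coefficient are the baseline
    adj <- adj - ifelse(is.na(m), 0, coefs[m])
  }
  stats::setNames(as.numeric(adj), ids)
}

#' Predictivity: correlation of adjusted phenotypes with GEBVs
#'
#' The Pearson correlation between validation individuals' phenotypes adjusted
#' for fixed effects (trait i) and their GEBVs (trait j), the central quantity
#' of the predictivity-based estimators.
#'
#' @param adjusted_phenotypes,gebv Numeric vectors over the same validation
#'   individuals, length at least 4.
#' @param trait_pheno,trait_ebv Trait identifiers (defaults `"trait"`).
#' @param window_id Optional label of the time slice.
#' @return A `"predictivity_record"`: list with `c`, `trait_pheno`,
#'   `trait_ebv`, `n_validation`, `window_id`.
#' @export
predictivity <- function(adjusted_phenotypes, gebv, trait_pheno = "trait",
                         trait_ebv = trait_pheno, window_id = NA_character_) {
  if (length(adjusted_phenotypes) != length(gebv))
    stop("vectors must cover the same validation individuals", call. = FALSE)
  if (length(gebv) < 4)
    stop("need at least 4 validation individuals", call. = FALSE)
  if (stats::sd(adjusted_phenotypes) == 0 || stats::sd(gebv) == 0)
    stop("zero variance in adjusted phenotypes or GEBVs ",
         "(constant predictions are uninformative)", call. = FALSE)
  structure(list(c = stats::cor(adjusted_phenotypes, gebv),
                 trait_pheno = trait_pheno, trait_ebv = trait_ebv,
                 n_validation = length(gebv), window_id = window_id),
            class = "predictivity_record")
}

#' @export
print.predictivity_record <- function(x, ...) {
  cat(sprintf("Predictivity c = %.4f  (phenotype: %s, GEBV: %s, n = %d%s)\n",
              x$c, x$trait_pheno, x$trait_ebv, x$n_validation,
              if (is.na(x$window_id)) "" else paste0(", window ", x$window_id)))
  invisible(x)
}
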