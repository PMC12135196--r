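# Number of independent chromosome segments (Me), either from population
# parameters or from the eigenvalue spectrum of the genomic relationship
# matrix.

#' Independent chromosome segments from Ne and genome length
#'
#' \eqn{M_e \approx 4 N_e L}, with \eqn{N_e} the effective population size and
#' \eqn{L} the genome length in Morgans.
#'
#' @param ne Effective population size, positive.
#' @param genome_length Genome length in Morgans, positive.
#' @return A `"segments_estimate"`: list with `me`, `method = "ne_l"` and the
#'   inputs in `detail`.
#' @examples
#' me_from_ne_l(50, 30)  # cattle-like genome at Ne = 50
#' @export
me_from_ne_l <- function(ne, genome_length) {
  if (!is.numeric(ne) || any(ne <= 0))
    stop("`ne` must be > 0", call. = FALSE)
  if (!is.numeric(genome_length) || any(genome_length <= 0))
    stop("`genome_length` must be > 0 (Morgans)", call. = FALSE)
  me <- round(4 * ne * genome_length)
  structure(list(me = me, method = "ne_l",
                 detail = list(ne = ne, genome_length = genome_length)),
            class = "segments_estimate")
}

#' Independent chromosome segments from GRM eigenvalues
#'
#' The smallest number of leading eigenvalues of the (unblended) genomic
#' relationship matrix whose sum explains a given fraction (default 98%) of the
#' total variation.  Negative numerical eigenvalues are truncated at zero
#' before summation.  For large matrices a random subset of individuals is
#' analysed.
#'
#' @param grm A `"grm"` object or symmetric matrix.  If the object carries a
#'   `blend_alpha` attribute the identity blend is removed first: the rule
#'   refers to genomic variation, and blending inflates the spectrum's tail.
#' @param fraction Fraction of variation to explain, in (0, 1); default 0.98.
#' @param max_individuals Subsample size for large matrices, default 5000.
#' @param seed Optional seed for the subsample draw.
#' @return A `"segments_estimate"`: list with `me`, `method = "eigenvalue"`,
#'   and `detail` (fraction, individuals used, eigenvalue sum).
#' @export
me_from_grm_eigenvalues <- function(grm, fraction = 0.98,
                                    max_individuals = 5000, seed = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  G <- unblend_grm(grm)
  if (!isSymmetric(unname(G), tol = 1e-8))
    stop("`grm` must be symmetric", call. = FALSE)
  n <- nrow(G)
  if (n > max_individuals) {
    if (!is.null(seed)) set.seed(seed)
    keep <- sort(sample.int(n, max_individuals))
    G <- G[keep, keep]
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 0) stop("relationship matrix has no variation", call. = FALSE)
  k <- which(cumsum(ev) / tot >= fraction)[1]
  structure(list(me = k, method = "eigenvalue",
                 detail = list(fraction = fraction, n_used = nrow(G),
                               total_variance = tot)),
            class = "segments_estimate")
}

#' @export
print.segments_estimate <- function(x, ...) {
  cat("Independent chromosome segments (Me):", x$me, "\n")
  if (x$method == "ne_l")
    cat(sprintf("  method: 4*Ne*L with Ne = %g, L = %g Morgans\n",
                x$detail$ne, x$detail$genome_length))
  else
    cat(sprintf("  method: eigenvalues explaining %.0f%% of variation (n = %d)\n",
                100 * x$detail$fraction, x$detail$n_used))
  invisible(x)
}
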