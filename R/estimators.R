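# Closed-form estimators of heritability, accuracy, genetic correlation and
# their standard errors from predictivity.  All functions are pure, vectorised
# over their numeric arguments (recycled elementwise), and clamp estimates to
# their natural ranges with a warning, preserving the raw value as an
# attribute.

.recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`", name, "` must be finite numeric", call. = FALSE)
  x
}

# clamp with warning; raw values kept in attr "raw" only when clamping
# occurred (overshoot within floating-point noise is clamped silently)
.clamp <- function(x, lo, hi, what, tol = 1e-9) {
  out <- pmin(pmax(x, lo), hi)
  if (any(bad <- (x < lo - tol | x > hi + tol))) {
    warning(sum(bad), " ", what, " estimate(s) outside [", lo, ", ", hi,
            "] clamped; raw value(s) kept in attr(, \"raw\")", call. = FALSE)
    attr(out, "raw") <- x
  }
  out
}

#' Heritability from predictivity
#'
#' Estimates narrow-sense heritability by equating two expressions for the
#' accuracy of genomic breeding values: one based on predictivity
#' \eqn{c = \mathrm{Corr}(y - Xb, \hat u)} (the correlation between validation
#' animals' adjusted phenotypes and their GEBVs), and one based on the size of
#' the reference population \eqn{N} and the number of independent chromosome
#' segments \eqn{M_e}.  The closed-form solution is
#' \deqn{\hat h^2 = \frac{c^2 + \sqrt{c^4 + 4 c^2 M_e / N}}{2}.}
#'
#' @param c Predictivity: Pearson correlation between adjusted phenotypes and
#'   GEBVs of the validation individuals, in \[-1, 1\].
#' @param n_reference Number of individuals with both genotypes and phenotypes
#'   in the reference population (\eqn{N}).
#' @param me Number of independent chromosome segments (\eqn{M_e}), positive.
#' @param n_validation Optional validation-set size; when supplied, the
#'   standard error from [se_h2()] is attached as `attr(, "se")`.
#' @return Numeric vector of heritability estimates in \[0, 1\] (values outside
#'   the range are clamped with a warning and the raw value kept in
#'   `attr(, "raw")`).  Always satisfies \eqn{\hat h^2 \ge c^2}.
#' @seealso [se_h2()], [expected_accuracy()], [acc_from_predictivity()]
#' @examples
#' h2_from_predictivity(0.55, 580000, 15000)  # dairy-cattle-scale example
#' @export
h2_from_predictivity <- function(c, n_reference, me, n_validation = NULL) {
  .check_finite(c, "c"); .check_finite(n_reference, "n_reference")
  .check_finite(me, "me")
  if (any(abs(c) > 1)) stop("|c| must be <= 1", call. = FALSE)
  if (any(me <= 0)) stop("`me` must be > 0", call. = FALSE)
  if (any(n_reference < 1)) stop("`n_reference` must be >= 1", call. = FALSE)
  r <- .recycle(c = c, N = n_reference, me = me)
  h2 <- (r$c^2 + sqrt(r$c^4 + 4 * r$c^2 * r$me / r$N)) / 2
  h2 <- .clamp(h2, 0, 1, "heritability")
  if (!is.null(n_validation))
    attr(h2, "se") <- se_h2(r$c, n_validation, r$me, r$N)
  h2
}

#' Accuracy of breeding values from predictivity
#'
#' Converts predictivity into the accuracy of GEBVs,
#' \eqn{acc = \mathrm{Corr}(y - Xb, \hat u) / h}, where \eqn{h} is the square
#' root of the heritability of the trait whose phenotypes were predicted.
#'
#' @param c Predictivity in \[-1, 1\].
#' @param h2 Heritability of the trait, in (0, 1\].
#' @return Accuracy in \[0, 1\].  Values above 1 indicate an inflated accuracy
#'   (e.g. an overstated heritability); they are flagged with a warning and
#'   clamped, the raw value kept in `attr(, "raw")`.
#' @examples
#' acc_from_predictivity(0.09, 0.05)  # low-heritability fitness trait
#' @export
acc_from_predictivity <- function(c, h2) {
  .check_finite(c, "c"); .check_finite(h2, "h2")
  if (any(abs(c) > 1)) stop("|c| must be <= 1", call. = FALSE)
  if (any(h2 <= 0 | h2 > 1)) stop("`h2` must be in (0, 1]", call. = FALSE)
  r <- .recycle(c = c, h2 = h2)
  acc <- r$c / sqrt(r$h2)
  if (any(acc > 1))
    warning("accuracy exceeds 1 (inflated-accuracy diagnostic); clamped",
            call. = FALSE)
  out <- pmin(pmax(acc, 0), 1)
  if (any(acc > 1 | acc < 0)) attr(out, "raw") <- acc
  attr(out, "source") <- "from_predictivity"
  out
}

#' Expected accuracy from reference size and independent chromosome segments
#'
#' The expected accuracy of GEBVs in a population with \eqn{N} genotyped and
#' phenotyped reference individuals, heritability \eqn{h^2}, and \eqn{M_e}
#' independent chromosome segments:
#' \deqn{acc = \sqrt{N h^2 / (N h^2 + M_e)}.}
#'
#' @param n_reference Reference-population size, non-negative.
#' @param h2 Heritability in \[0, 1\].
#' @param me Number of independent chromosome segments, positive.
#' @return Expected accuracy in \[0, 1\].
#' @examples
#' expected_accuracy(12000, 0.05, 5000)
#' @export
expected_accuracy <- function(n_reference, h2, me) {
  .check_finite(n_reference, "n_reference"); .check_finite(h2, "h2")
  .check_finite(me, "me")
  if (any(me <= 0)) stop("`me` must be > 0", call. = FALSE)
  if (any(n_reference < 0)) stop("`n_reference` must be >= 0", call. = FALSE)
  if (any(h2 < 0 | h2 > 1)) stop("`h2` must be in [0, 1]", call. = FALSE)
  r <- .recycle(N = n_reference, h2 = h2, me = me)
  acc <- sqrt(r$N * r$h2 / (r$N * r$h2 + r$me))
  attr(acc, "source") <- "expected"
  acc
}

#' Genetic correlation from cross-trait predictivity
#'
#' Estimates the genetic correlation between traits i and j from the
#' cross-trait predictivity \eqn{c_{ij} = \mathrm{Corr}(y_i - X b_i, \hat u_j)}
#' (adjusted phenotype of trait i, GEBV of trait j):
#' \deqn{\mathrm{Corr}(u_i, u_j) = c_{ij} / (h_i \cdot acc_j).}
#' The two trait orders are asymptotically equal but differ in finite samples
#' and have different standard errors; both should be examined.
#'
#' @param c_cross Cross-trait predictivity in \[-1, 1\].
#' @param h2_i Heritability of the trait whose phenotype is used, in (0, 1\].
#' @param acc_j Accuracy of the GEBV of the other trait, in (0, 1\].
#' @param n_validation Optional validation-set size; when supplied the standard
#'   error from [se_gencorr()] is attached as `attr(, "se")`.
#' @return Genetic-correlation estimate clamped to \[-1, 1\]; the raw
#'   (pre-clamp) value is always retained in `attr(, "raw")` for diagnostics.
#' @examples
#' gencorr_from_predictivity(-0.1, 0.4, 0.6, 2000)
#' @export
gencorr_from_predictivity <- function(c_cross, h2_i, acc_j,
                                      n_validation = NULL) {
  .check_finite(c_cross, "c_cross"); .check_finite(h2_i, "h2_i")
  .check_finite(acc_j, "acc_j")
  if (any(abs(c_cross) > 1)) stop("|c_cross| must be <= 1", call. = FALSE)
  if (any(h2_i <= 0)) stop("`h2_i` must be > 0", call. = FALSE)
  if (any(acc_j <= 0)) stop("`acc_j` must be > 0", call. = FALSE)
  r <- .recycle(c = c_cross, h2 = h2_i, acc = acc_j)
  raw <- r$c / (sqrt(r$h2) * r$acc)
  out <- pmin(pmax(raw, -1), 1)
  if (any(abs(raw) > 1))
    warning("genetic correlation outside [-1, 1]; clamped (raw kept)",
            call. = FALSE)
  attr(out, "raw") <- raw
  if (!is.null(n_validation))
    attr(out, "se") <- se_gencorr(r$h2, r$acc, n_validation)
  out
}

#' Standard error of accuracy estimated from predictivity
#'
#' Upper bound on the sampling standard error of an accuracy obtained from
#' predictivity, treating \eqn{h_i} as a constant:
#' \eqn{SE(acc) < 1 / (h_i \sqrt{n})}.
#'
#' @param h2_i Heritability of the trait, in (0, 1\].
#' @param n_validation Validation-population size, at least 4.
#' @return Standard-error bound.
#' @examples
#' se_accuracy(0.25, 1600)  # 0.05
#' @export
se_accuracy <- function(h2_i, n_validation) {
  .check_finite(h2_i, "h2_i"); .check_finite(n_validation, "n_validation")
  if (any(h2_i <= 0)) stop("`h2_i` must be > 0", call. = FALSE)
  if (any(n_validation < 4)) stop("`n_validation` must be >= 4", call. = FALSE)
  r <- .recycle(h2 = h2_i, n = n_validation)
  1 / (sqrt(r$h2) * sqrt(r$n))
}

#' Standard error of a genetic correlation estimated from predictivity
#'
#' Upper bound obtained by treating \eqn{h_i} and \eqn{acc_j} as constants:
#' \eqn{SE < 1 / (h_i \cdot acc_j \cdot \sqrt{n})}.  Swapping the roles of the
#' two traits generally changes the value; the order with the larger
#' denominator has the smaller standard error.
#'
#' @param h2_i Heritability of the trait whose phenotype is used, in (0, 1\].
#' @param acc_j Accuracy of the GEBV of the other trait, in (0, 1\].
#' @param n_validation Validation-population size, at least 4.
#' @return Standard-error bound.
#' @examples
#' se_gencorr(0.25, 0.5, 1600)  # 0.10
#' @export
se_gencorr <- function(h2_i, acc_j, n_validation) {
  .check_finite(h2_i, "h2_i"); .check_finite(acc_j, "acc_j")
  .check_finite(n_validation, "n_validation")
  if (any(h2_i <= 0)) stop("`h2_i` must be > 0", call. = FALSE)
  if (any(acc_j <= 0)) stop("`acc_j` must be > 0", call. = FALSE)
  if (any(n_validation < 4)) stop("`n_validation` must be >= 4", call. = FALSE)
  r <- .recycle(h2 = h2_i, acc = acc_j, n = n_validation)
  1 / (sqrt(r$h2) * r$acc * sqrt(r$n))
}

#' Approximate standard error of the heritability estimate
#'
#' Linear (delta-method) approximation
#' \eqn{SE(\hat h^2) \approx (d\hat h^2/dc)\, SD(c)} evaluated with
#' \eqn{SD(c) < 1/\sqrt{n}}, in the closed form
#' \deqn{SE(\hat h^2) \approx \frac{1}{2\sqrt{n}}\left[c +
#'   \frac{2c^2 + 4 M_e/N}{\sqrt{c^2 + 4 M_e/N}}\right],}
#' which for very large reference populations (\eqn{N \gg M_e}) simplifies to
#' \eqn{1.5\, c/\sqrt{n}}.
#'
#' At \eqn{c = 0} the linearisation degenerates; `NA` is returned there (with a
#' warning) rather than 0.
#'
#' @param c Predictivity, strictly positive for a defined SE.
#' @param n_validation Validation-population size, at least 4.
#' @param me Number of independent chromosome segments, positive.
#' @param n_reference Reference-population size, at least 1.
#' @return Standard-error values; `NA` where `c` is 0.
#' @examples
#' se_h2(0.55, 381000, 15000, 580000)
#' @export
se_h2 <- function(c, n_validation, me, n_reference) {
  .check_finite(c, "c"); .check_finite(n_validation, "n_validation")
  .check_finite(me, "me"); .check_finite(n_reference, "n_reference")
  if (any(c < 0) || any(c > 1)) stop("`c` must be in [0, 1]", call. = FALSE)
  if (any(n_validation < 4)) stop("`n_validation` must be >= 4", call. = FALSE)
  if (any(me <= 0)) stop("`me` must be > 0", call. = FALSE)
  if (any(n_reference < 1)) stop("`n_reference` must be >= 1", call. = FALSE)
  r <- .recycle(c = c, n = n_validation, me = me, N = n_reference)
  k <- r$me / r$N
  out <- (r$c + (2 * r$c^2 + 4 * k) / sqrt(r$c^2 + 4 * k)) / (2 * sqrt(r$n))
  if (any(zero <- r$c == 0)) {
    warning("SE(h2) undefined at c = 0; returning NA", call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Minimum reference-population size for reliable heritability estimation
#'
#' The expected-accuracy formula is least sensitive to the assumed number of
#' independent chromosome segments when the accuracy is high (> ~0.7), i.e.
#' when \eqn{N h^2 > M_e / 3}.  This returns the corresponding minimum
#' reference size \eqn{N > M_e / (3 h^2)}, rounded up to a whole count.
#'
#' @param me Number of independent chromosome segments, positive.
#' @param h2 Heritability, in (0, 1\].
#' @return Integer-valued minimum reference-population size.
#' @examples
#' min_reference_size(15000, 0.05)  # 100000
#' @export
min_reference_size <- function(me, h2) {
  .check_finite(me, "me"); .check_finite(h2, "h2")
  if (any(h2 <= 0)) stop("`h2` must be > 0", call. = FALSE)
  if (any(me <= 0)) stop("`me` must be > 0", call. = FALSE)
  r <- .recycle(me = me, h2 = h2)
  ceiling(r$me / (3 * r$h2))
}
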