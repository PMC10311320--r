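#' Cochran-Mantel-Haenszel association test for a pattern
#'
#' Tests association between a binary pattern indicator and a binary phenotype
#' across `C` covariate strata. For per-stratum margins `n_j` (stratum size),
#' `n1_j` (cases), `x_j` (pattern carriers) and counts `a_j` (case carriers),
#' the statistic is
#' \deqn{T = \frac{\left[\sum_j (a_j - x_j n_{1j}/n_j)\right]^2}{
#'   \sum_j x_j (n_j - x_j) n_{1j} (n_j - n_{1j}) / (n_j^2 (n_j - 1))},}
#' which is chi-squared with 1 df under the null; no continuity correction is
#' applied, matching the convention of discrete significant-pattern mining.
#' Degenerate strata (`x_j` in \{0, n_j\}, `n1_j` in \{0, n_j\}, or
#' `n_j <= 1`) contribute zero to numerator and denominator; when the whole
#' denominator vanishes, `T = 0` and `p = 1`.
#'
#' @param counts an `mm_counts` object from [stratified_counts()], or a list
#'   with integer fields `x`, `a`, `n`, `n1` of equal length.
#' @return a list with elements `T` (statistic) and `p` (p-value).
#' @examples
#' cmh_pvalue(list(x = 2L, a = 2L, n = 4L, n1 = 2L))
#' @export
cmh_pvalue <- function(counts) {
  st <- cmh_stat_vec(matrix(counts$x, ncol = 1), matrix(counts$a, ncol = 1),
                     counts$n, counts$n1)
  list(T = st$T[1], p = st$p[1])
}

# Vectorized CMH over patterns: x, a are C x P matrices; n, n1 length C.
# Returns T, p, esum (sum of expectations) and den per pattern.
cmh_stat_vec <- function(x, a, n, n1) {
  e <- x * (n1 / n)
  v <- x * (n - x) * as.numeric(n1) * (n - n1) / (as.numeric(n)^2 * pmax(n - 1, 1))
  v[n <= 1, ] <- 0
  esum <- colSums(e)
  den <- colSums(v)
  num <- (colSums(a) - esum)^2
  T <- ifelse(den > 0, num / den, 0)
  list(T = T, p = stats::pchisq(T, 1, lower.tail = FALSE),
       esum = esum, den = den)
}

#' Minimum attainable p-value of a pattern
#'
#' For fixed margins the CMH statistic depends on the case split only through
#' the total `sum(a_j)`, so its most extreme achievable values sit at the
#' per-stratum corners `a^U_j = min(x_j, n1_j)` and
#' `a^L_j = max(0, x_j - (n_j - n1_j))`. The minimum attainable p-value is the
#' chi-squared survival function at the larger of the two corner statistics;
#' it depends only on the pattern's support, never on the observed labels of
#' its carriers, which is what makes Tarone's testability argument valid.
#'
#' @inheritParams cmh_pvalue
#' @return the minimum attainable p-value (1 for fully degenerate margins).
#' @examples
#' min_attainable_pvalue(list(x = 2L, a = 0L, n = 4L, n1 = 2L))
#' @export
min_attainable_pvalue <- function(counts) {
  pmin_vec(matrix(counts$x, ncol = 1), counts$n, counts$n1)[1]
}

# Vectorized minimum attainable p-value; x is C x P.
pmin_vec <- function(x, n, n1) {
  stats::pchisq(pmin_T_vec(x, n, n1), 1, lower.tail = FALSE)
}

pmin_T_vec <- function(x, n, n1) {
  e <- x * (n1 / n)
  v <- x * (n - x) * as.numeric(n1) * (n - n1) / (as.numeric(n)^2 * pmax(n - 1, 1))
  v[n <= 1, ] <- 0
  den <- colSums(v)
  aU <- pmin(x, n1)
  aL <- pmax(x - (n - n1), 0)
  TU <- (colSums(aU - e))^2
  TL <- (colSums(aL - e))^2
  ifelse(den > 0, pmax(TU, TL) / den, 0)
}

#' Envelope: lower bound on descendant minimum attainable p-values
#'
#' Any descendant of a pattern (a pattern generated from it by extending
#' intervals) has a support that is a superset of the pattern's support, so
#' its per-stratum carrier counts lie in the box `x_j <= x'_j <= n_j`. The
#' envelope is a certified lower bound on the minimum attainable p-value over
#' that whole box: when it exceeds the current significance threshold, no
#' descendant can ever become testable and the subtree can be pruned. The
#' bound is monotone along descent (the box only shrinks), so a pruning
#' decision stays valid as the threshold decreases.
#'
#' @inheritParams cmh_pvalue
#' @param tight if `TRUE` (default) the corner statistics are maximized
#'   jointly over the cartesian product of per-stratum candidate counts; if
#'   `FALSE` a separable Cauchy-Schwarz bound is used, which is looser but
#'   valid by construction.
#' @return a lower bound on `min_attainable_pvalue` over all descendants.
#' @examples
#' envelope_pvalue(list(x = 1L, a = 1L, n = 4L, n1 = 2L))
#' @export
envelope_pvalue <- function(counts, tight = TRUE) {
  penv_vec(matrix(counts$x, ncol = 1), counts$n, counts$n1, tight = tight)[1]
}

# Vectorized envelope p-value; x is C x P.
penv_vec <- function(x, n, n1, tight = TRUE) {
  Tenv <- .bm_envelope_T(x, as.integer(n), as.integer(n1), isTRUE(tight))
  stats::pchisq(Tenv, 1, lower.tail = FALSE)
}
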