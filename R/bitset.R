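#' Packed sample bitsets
#'
#' A `sample_bitset` is a packed-bit membership vector over the `n` samples of
#' a dataset, stored in 64-bit words. It is the in-memory representation of a
#' pattern's support: bit `i` is set when sample `i` carries the pattern.
#' Bit-level operations (union, intersection counts) back the miner's support
#' computation, so that combining patterns costs one word-wise OR instead of a
#' scan over samples.
#'
#' @param x logical vector of sample memberships.
#' @return `as_bitset()` returns a `sample_bitset`; `as.logical()` recovers the
#'   membership vector.
#' @examples
#' b <- as_bitset(c(TRUE, FALSE, TRUE))
#' support_count(b)
#' @export
as_bitset <- function(x) {
  stopifnot(is.logical(x), !anyNA(x))
  new_bitset(.bs_pack(x), length(x))
}

new_bitset <- function(words, n) {
  structure(words, n = as.integer(n), class = "sample_bitset")
}

#' @rdname as_bitset
#' @param ... unused.
#' @export
as.logical.sample_bitset <- function(x, ...) {
  .bs_unpack(unclass(x), attr(x, "n"))
}

#' @export
print.sample_bitset <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("<sample_bitset: %d of %d samples>\n", support_count(x), n))
  invisible(x)
}

#' Number of samples in a bitset's support
#'
#' @param b a `sample_bitset`.
#' @return integer population count.
#' @export
support_count <- function(b) {
  stopifnot(inherits(b, "sample_bitset"))
  .bs_popcount(unclass(b))
}

#' Binarize one genotype row under a genetic encoding
#'
#' Maps an additive genotype row (minor-allele counts in \{0,1,2\}) to a
#' binary carrier indicator. Under the dominant encoding a sample is a carrier
#' when it holds at least one minor allele (value 1 or 2); under the recessive
#' encoding only homozygous-minor samples (value 2) are carriers. Binary-mode
#' input (values in \{0,1\}) under the dominant encoding reproduces the row.
#' The recessive support of a row is always a subset of its dominant support,
#' which gives the encoding half of the pattern partial order.
#'
#' @param genotype_row integer vector with values in \{0,1,2\}.
#' @param encoding `"dominant"` or `"recessive"`.
#' @return a [as_bitset()] `sample_bitset` of carriers.
#' @examples
#' as.logical(binarize_marker(c(0L, 1L, 2L, 0L, 2L), "dominant"))
#' as.logical(binarize_marker(c(0L, 1L, 2L, 0L, 2L), "recessive"))
#' @export
binarize_marker <- function(genotype_row, encoding = c("dominant", "recessive")) {
  encoding <- match.arg(encoding)
  stopifnot(is.numeric(genotype_row), all(genotype_row %in% 0:2))
  m <- matrix(as.integer(genotype_row), nrow = 1)
  new_bitset(.bm_binarize(m, 1L, if (encoding == "dominant") 1L else 2L)[, 1],
             length(genotype_row))
}

#' Union of two supports
#'
#' The support of a meta-marker is the OR of its member markers' supports, so
#' extending a pattern only requires the union of the parent support with the
#' newly added column.
#'
#' @param a,b `sample_bitset`s over the same samples.
#' @return their bitwise union.
#' @export
or_support <- function(a, b) {
  stopifnot(inherits(a, "sample_bitset"), inherits(b, "sample_bitset"))
  if (!identical(attr(a, "n"), attr(b, "n"))) {
    stop("or_support(): bitsets cover different sample counts", call. = FALSE)
  }
  new_bitset(.bs_or(unclass(a), unclass(b)), attr(a, "n"))
}

#' Per-stratum pattern counts
#'
#' Intersects a pattern support with the covariate stratum masks of a dataset
#' and returns, for each stratum `j`, the number of samples carrying the
#' pattern (`x_j`) and the number of those that are cases (`a_j`), together
#' with the stratum margins `n_j` and `n1_j`. These are the margins of the
#' 2x2xC contingency tables that feed the Cochran-Mantel-Haenszel test.
#'
#' @param support a `sample_bitset`.
#' @param masks stratum masks, as found in `dataset$masks` (see
#'   [new_dataset()]) or built with [stratum_masks()].
#' @return an object of class `mm_counts` with fields `x`, `a`, `n`, `n1`.
#' @export
stratified_counts <- function(support, masks) {
  stopifnot(inherits(support, "sample_bitset"))
  if (attr(support, "n") != masks$n) {
    stop("stratified_counts(): support and masks cover different sample counts",
         call. = FALSE)
  }
  cc <- .bm_strat_counts(matrix(unclass(support), ncol = 1),
                         masks$members, masks$cases)
  new_counts(drop(cc$x), drop(cc$a), masks$n_j, masks$n1_j)
}

new_counts <- function(x, a, n, n1) {
  structure(list(x = as.integer(x), a = as.integer(a),
                 n = as.integer(n), n1 = as.integer(n1)),
            class = "mm_counts")
}

#' @export
print.mm_counts <- function(x, ...) {
  cat("<mm_counts over", length(x$n), "strata>\n")
  print(data.frame(n = x$n, n1 = x$n1, x = x$x, a = x$a))
  invisible(x)
}

#' Covariate stratum masks
#'
#' Precomputes, for each covariate class, the packed member and case bitsets
#' used by the counting kernels, plus the margins `n_j` and `n1_j`.
#'
#' @param y integer phenotype labels in \{0,1\}.
#' @param strata integer covariate classes, densely indexed from 0; `NULL`
#'   means a single stratum.
#' @return a list with `members`/`cases` bit-matrix columns per stratum,
#'   `n_j`, `n1_j`, `n`, `C` and the raw `strata` vector.
#' @export
stratum_masks <- function(y, strata = NULL) {
  n <- length(y)
  stopifnot(all(y %in% 0:1))
  if (is.null(strata)) strata <- integer(n)
  stopifnot(length(strata) == n)
  cls <- sort(unique(strata))
  stopifnot(identical(as.integer(cls), seq_along(cls) - 1L))
  C <- length(cls)
  members <- vapply(cls, function(c) .bs_pack(strata == c), integer(length(.bs_pack(logical(n)))))
  cases <- vapply(cls, function(c) .bs_pack(strata == c & y == 1), integer(nrow(members)))
  members <- matrix(members, ncol = C)
  cases <- matrix(cases, ncol = C)
  list(members = members, cases = cases,
       n_j = as.integer(tabulate(strata + 1L, nbins = C)),
       n1_j = as.integer(vapply(cls, function(c) sum(y == 1 & strata == c), numeric(1))),
       n = n, C = C, strata = as.integer(strata))
}
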