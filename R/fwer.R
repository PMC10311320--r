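#' Family-wise error rate control states
#'
#' Both FWER procedures maintain an evolving significance threshold
#' `delta = alpha * grid_ratio^i` on a geometric grid. Tarone's method keeps
#' the testability bound `delta * |T(delta)| <= alpha`, where `T(delta)` is
#' the set of processed patterns whose minimum attainable p-value is at most
#' `delta`; the Westfall-Young procedure keeps the permutation estimate
#' `FWER(delta) = (1/K) #\{j : minp_j <= delta\} <= alpha`, where `minp_j` is
#' the running minimum p-value over processed patterns under the j-th label
#' permutation. In both cases the threshold is non-increasing over a run, and
#' once a grid level becomes infeasible it stays infeasible, so the final
#' threshold is the largest feasible grid value regardless of processing
#' order.
#'
#' @param alpha target FWER level in (0,1).
#' @param grid_ratio geometric grid ratio `gamma` in (0,1); smaller values
#'   descend in coarser steps.
#' @return an environment of class `mm_tarone_state` / `mm_wy_state`
#'   (subclasses of `mm_fwer_state`) with the current threshold available via
#'   [threshold()].
#' @name fwer-states
NULL

LEV_CAP <- 6000L  # delta underflows double precision past alpha * gamma^6000

#' @rdname fwer-states
#' @export
new_tarone_state <- function(alpha = 0.05, grid_ratio = 0.9) {
  stopifnot(alpha > 0, alpha < 1, grid_ratio > 0, grid_ratio < 1)
  st <- new.env(parent = emptyenv())
  st$alpha <- alpha
  st$gamma <- grid_ratio
  st$L <- 0L          # grid index: delta = alpha * gamma^L
  st$tcount <- 0L     # testable patterns at the current level
  st$hist <- numeric(64)  # counts bucketed by grid level of p_min
  st$processed <- 0L
  st$keys <- character(0)
  st$pmins <- numeric(0)
  st$ps <- numeric(0)
  class(st) <- c("mm_tarone_state", "mm_fwer_state")
  st
}

#' @rdname fwer-states
#' @param perms permutation masks from [make_permutations()] (Westfall-Young
#'   only).
#' @export
new_wy_state <- function(alpha = 0.05, perms, grid_ratio = 0.9) {
  stopifnot(alpha > 0, alpha < 1, grid_ratio > 0, grid_ratio < 1)
  st <- new.env(parent = emptyenv())
  st$alpha <- alpha
  st$gamma <- grid_ratio
  st$L <- 0L
  st$K <- perms$K
  st$perm_cases <- perms$case_bits
  st$maxT <- numeric(perms$K)  # running max CMH statistic per permutation
  st$thr <- stats::qchisq(alpha, 1, lower.tail = FALSE)  # grid on the T scale
  st$hist <- numeric(64)  # testability bookkeeping (reporting only)
  st$tcount <- 0L
  st$processed <- 0L
  st$keys <- character(0)
  st$pmins <- numeric(0)
  st$ps <- numeric(0)
  class(st) <- c("mm_wy_state", "mm_fwer_state")
  st
}

#' Current significance threshold of an FWER state
#'
#' @param state an `mm_fwer_state`.
#' @return the current grid threshold `delta`.
#' @export
threshold <- function(state) state$alpha * state$gamma^state$L

#' @export
print.mm_fwer_state <- function(x, ...) {
  cat(sprintf("<%s: alpha=%g, delta=%g (grid level %d), %d processed>\n",
              class(x)[1], x$alpha, threshold(x), x$L, x$processed))
  invisible(x)
}

# Grid level of a minimum attainable p-value: largest i with
# alpha * gamma^i >= p (so the pattern is testable at levels <= i);
# -1 when p > alpha. The epsilon keeps exact grid hits on-grid.
grid_level <- function(state, p) {
  lev <- floor(log(p / state$alpha) / log(state$gamma) + 1e-9)
  lev[p <= 0] <- LEV_CAP
  lev <- pmin(lev, LEV_CAP)
  as.integer(pmax(lev, -1))
}

grow_hist <- function(state, need) {
  if (need > length(state$hist)) {
    state$hist <- c(state$hist, numeric(need - length(state$hist)))
  }
}

# Insert a batch of minimum attainable p-values into a Tarone state,
# lowering the threshold as needed. Returns which patterns entered the
# testable ledger (p_min <= delta at their processing time).
tarone_insert <- function(state, pminv) {
  lev <- grid_level(state, pminv)
  grow_hist(state, max(lev) + 2L)
  inserted <- logical(length(pminv))
  L <- state$L; tcount <- state$tcount; hist <- state$hist
  gamma <- state$gamma
  for (i in seq_along(pminv)) {
    li <- lev[i]
    if (li >= L) {
      inserted[i] <- TRUE
      tcount <- tcount + 1L
      hist[li + 1L] <- hist[li + 1L] + 1
      while (gamma^L * tcount > 1) {
        tcount <- tcount - hist[L + 1L]
        L <- L + 1L
      }
    }
  }
  state$L <- L; state$tcount <- as.integer(tcount); state$hist <- hist
  state$processed <- state$processed + length(pminv)
  inserted
}

#' Process one pattern under Tarone's procedure
#'
#' If the pattern's minimum attainable p-value is at or below the current
#' threshold it enters the testable ledger; the threshold then descends along
#' the geometric grid, dropping no-longer-testable entries, until
#' `delta * |T(delta)| <= alpha` holds again.
#'
#' @param state an `mm_tarone_state`.
#' @param pattern_key canonical pattern identifier.
#' @param p_min minimum attainable p-value of the pattern.
#' @param p observed p-value of the pattern.
#' @return the state, invisibly (modified in place).
#' @export
tarone_update <- function(state, pattern_key, p_min, p) {
  stopifnot(inherits(state, "mm_tarone_state"),
            p_min >= 0, p_min <= 1, p >= 0, p <= 1)
  ins <- tarone_insert(state, p_min)
  if (ins) {
    state$keys <- c(state$keys, pattern_key)
    state$pmins <- c(state$pmins, p_min)
    state$ps <- c(state$ps, p)
  }
  invisible(state)
}

# Threshold on the chi-square statistic scale for grid level i (cached).
wy_thr <- function(state, i) {
  while (length(state$thr) < i + 1L) {
    lev <- length(state$thr)
    state$thr <- c(state$thr,
                   stats::qchisq(state$alpha * state$gamma^lev, 1,
                                 lower.tail = FALSE))
  }
  state$thr[i + 1L]
}

# Descend the WY threshold until the estimated FWER is within alpha.
wy_descend <- function(state) {
  while (mean(state$maxT >= wy_thr(state, state$L)) > state$alpha) {
    state$L <- state$L + 1L
  }
  invisible(state)
}

# Batch WY update: fold the permutation statistics of a block of patterns
# into the running per-permutation maxima, then descend the threshold.
# supports: bit-matrix of the block; esum/den: permutation-invariant CMH
# pieces of each pattern; pminv: minimum attainable p-values (testability
# bookkeeping only).
wy_insert <- function(state, supports, esum, den, pminv) {
  S <- .bm_cross_popcount(supports, state$perm_cases)
  state$maxT <- .wy_max_stat(S, esum, den, state$maxT)
  lev <- grid_level(state, pminv)
  grow_hist(state, max(lev) + 2L)
  keep <- lev >= 0L
  if (any(keep)) {
    tab <- tabulate(lev[keep] + 1L, nbins = length(state$hist))
    state$hist <- state$hist + tab
  }
  state$processed <- state$processed + length(pminv)
  wy_descend(state)
  invisible(state)
}

#' Process one pattern under the Westfall-Young procedure
#'
#' Computes the pattern's CMH p-value under each pre-computed label
#' permutation (the margins `n_j`, `n1_j`, `x_j` are permutation-invariant;
#' only the case counts change), folds them into the per-permutation minimum
#' p-values, and descends the threshold until the estimated FWER is at most
#' `alpha`.
#'
#' @param state an `mm_wy_state`.
#' @param pattern_support the pattern's `sample_bitset`.
#' @param masks stratum masks of the dataset (see [stratum_masks()]).
#' @param pattern_key canonical pattern identifier.
#' @return the state, invisibly (modified in place).
#' @export
wy_update <- function(state, pattern_support, masks, pattern_key = "") {
  stopifnot(inherits(state, "mm_wy_state"))
  counts <- stratified_counts(pattern_support, masks)
  st <- cmh_stat_vec(matrix(counts$x, ncol = 1), matrix(counts$a, ncol = 1),
                     counts$n, counts$n1)
  pm <- min_attainable_pvalue(counts)
  wy_insert(state, matrix(unclass(pattern_support), ncol = 1),
            st$esum, st$den, pm)
  if (st$p[1] <= threshold(state)) {
    state$keys <- c(state$keys, pattern_key)
    state$pmins <- c(state$pmins, pm)
    state$ps <- c(state$ps, st$p[1])
  }
  invisible(state)
}

#' Pre-compute stratified label permutations
#'
#' Draws `K` independent label permutations, permuting uniformly within each
#' covariate stratum so that every permutation preserves the per-stratum case
#' counts `n1_j`. Stratified permutation keeps the CMH margins fixed, which
#' makes one testability/pruning decision simultaneously valid for the
#' observed labels and for all permutations.
#'
#' @param masks stratum masks (see [stratum_masks()]).
#' @param K number of permutations (>= 1).
#' @param seed RNG seed; the result is deterministic given `seed`.
#' @return a list with `case_bits` (packed case masks, one column per
#'   permutation, strata combined) and `K`.
#' @export
make_permutations <- function(masks, K, seed) {
  if (K < 1) stop("make_permutations(): K must be >= 1", call. = FALSE)
  n <- masks$n
  members <- lapply(seq_len(masks$C) - 1L, function(c) which(masks$strata == c))
  W2 <- nrow(masks$members)
  case_bits <- matrix(0L, W2, K)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  for (k in seq_len(K)) {
    z <- logical(n)
    for (c in seq_len(masks$C)) {
      m <- members[[c]]
      z[m[sample.int(length(m), masks$n1_j[c])]] <- TRUE
    }
    case_bits[, k] <- .bs_pack(z)
  }
  list(case_bits = case_bits, K = as.integer(K))
}

#' Finalize an FWER state into a threshold and significant entries
#'
#' @param state an `mm_fwer_state` whose ledger has been filled with
#'   [tarone_update()] / [wy_update()].
#' @return a list with `delta_final` and a data frame `significant` of ledger
#'   entries with `p <= delta_final`.
#' @export
fwer_finalize <- function(state) {
  delta <- threshold(state)
  keep <- state$ps <= delta
  list(delta_final = delta,
       significant = data.frame(key = state$keys[keep],
                                p_min = state$pmins[keep],
                                p = state$ps[keep],
                                stringsAsFactors = FALSE))
}
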