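#' Support of a meta-marker pattern
#'
#' A pattern spans one genomic interval per gene of a gene interaction, each
#' interval binarized under its own dominant/recessive encoding; the pattern's
#' support is the OR over all member markers of their binarized columns.
#'
#' @param dataset an `mm_dataset`.
#' @param genes character vector of gene ids (one interaction).
#' @param intervals `2 x k` integer matrix of gene-local interval bounds
#'   (start and end, 1-based, inclusive).
#' @param encodings per-gene encodings, `"d"`/`"r"` (or
#'   `"dominant"`/`"recessive"`).
#' @return a `sample_bitset`.
#' @export
pattern_support <- function(dataset, genes, intervals, encodings) {
  stopifnot(inherits(dataset, "mm_dataset"))
  k <- length(genes)
  intervals <- matrix(as.integer(intervals), nrow = 2)
  stopifnot(ncol(intervals) == k, length(encodings) == k)
  enc <- match.arg(substr(encodings, 1, 1), c("d", "r"), several.ok = TRUE)
  if (any(enc == "r") && dataset$mode == "binary") {
    stop("recessive encodings are undefined in binary mode", call. = FALSE)
  }
  W2 <- nrow(dataset$bits_dom)
  acc <- integer(W2)
  for (i in seq_len(k)) {
    rows <- dataset$gene_map[[genes[i]]]
    if (is.null(rows)) stop(sprintf("unknown gene '%s'", genes[i]), call. = FALSE)
    s <- intervals[1, i]; e <- intervals[2, i]
    stopifnot(s >= 1, e >= s, e <= length(rows))
    bits <- if (enc[i] == "d") dataset$bits_dom else dataset$bits_rec
    for (t in s:e) {
      acc <- .bs_or(acc, bits[, rows[t]])
    }
  }
  new_bitset(acc, dataset$n)
}

#' Is a pattern closed?
#'
#' A pattern is closed when every immediate interval-shrink predecessor
#' (dropping one marker from either end of any gene interval of length at
#' least 2, same encodings, same interaction) has strictly smaller support.
#' Patterns with all intervals of length 1 are closed by vacuity. Only closed
#' patterns are reported, to avoid redundant output rows describing the same
#' carrier set.
#'
#' @inheritParams pattern_support
#' @return `TRUE` or `FALSE`.
#' @export
is_closed <- function(dataset, genes, intervals, encodings) {
  intervals <- matrix(as.integer(intervals), nrow = 2)
  sup <- support_count(pattern_support(dataset, genes, intervals, encodings))
  for (i in seq_len(length(genes))) {
    if (intervals[2, i] - intervals[1, i] < 1) next
    for (side in 1:2) {
      shr <- intervals
      if (side == 1) shr[1, i] <- shr[1, i] + 1L else shr[2, i] <- shr[2, i] - 1L
      if (support_count(pattern_support(dataset, genes, shr, encodings)) >= sup) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# All single-marker-per-gene interval configurations for gene sizes `sizes`:
# a 2k x prod(sizes) matrix with rows (s1, e1, ..., sk, ek).
initial_ivals <- function(sizes) {
  pos <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  ivals <- matrix(0L, 2L * length(sizes), nrow(pos))
  for (i in seq_along(sizes)) {
    ivals[2L * i - 1L, ] <- as.integer(pos[, i])
    ivals[2L * i, ] <- as.integer(pos[, i])
  }
  ivals
}

# Canonical child generation: extend exactly one gene's interval one marker
# rightward, allowed for gene i only when every lower-index gene still has a
# length-1 interval. Each interval configuration is reachable from exactly
# one parent (the one obtained by retracting the lowest-index long interval),
# so no cross-level deduplication is needed.
gen_children <- function(ivals, sizes, cap = Inf) {
  k <- length(sizes)
  P <- ncol(ivals)
  if (P == 0) {
    return(list(ivals = ivals, parent = integer(0), newcol = integer(0)))
  }
  s_rows <- seq(1L, 2L * k, 2L)
  lens <- ivals[s_rows + 1L, , drop = FALSE] - ivals[s_rows, , drop = FALSE] + 1L
  out_iv <- vector("list", k)
  out_par <- vector("list", k)
  out_new <- vector("list", k)
  offsets <- cumsum(c(0L, sizes[-k]))
  prefix_ok <- rep(TRUE, P)
  for (i in seq_len(k)) {
    ok <- prefix_ok & ivals[2L * i, ] < sizes[i] & lens[i, ] < cap
    if (any(ok)) {
      idx <- which(ok)
      civ <- ivals[, idx, drop = FALSE]
      civ[2L * i, ] <- civ[2L * i, ] + 1L
      out_iv[[i]] <- civ
      out_par[[i]] <- idx
      out_new[[i]] <- offsets[i] + civ[2L * i, ]
    }
    if (i < k) prefix_ok <- prefix_ok & lens[i, ] == 1L
  }
  list(ivals = do.call(cbind, c(out_iv, list(matrix(0L, 2L * k, 0)))),
       parent = as.integer(unlist(out_par)),
       newcol = as.integer(unlist(out_new)))
}

# Combined CMH block statistics for a level: x, a are C x P.
cmh_block <- function(x, a, n, n1) {
  e <- x * (n1 / n)
  v <- x * (n - x) * as.numeric(n1) * (n - n1) / (as.numeric(n)^2 * pmax(n - 1, 1))
  v[n <= 1, ] <- 0
  esum <- colSums(e)
  den <- colSums(v)
  Tobs <- ifelse(den > 0, (colSums(a) - esum)^2 / den, 0)
  aU <- pmin(x, n1)
  aL <- pmax(x - (n - n1), 0)
  Tmin <- ifelse(den > 0,
                 pmax((colSums(aU - e))^2, (colSums(aL - e))^2) / den, 0)
  list(T = Tobs,
       p = stats::pchisq(Tobs, 1, lower.tail = FALSE),
       p_min = stats::pchisq(Tmin, 1, lower.tail = FALSE),
       esum = esum, den = den)
}

#' Mine significant meta-markers
#'
#' Enumerates, for every gene interaction, all patterns made of one genomic
#' interval per gene with a per-gene dominant/recessive encoding (additive
#' mode; binary mode uses the single carrier encoding), breadth-first by
#' total interval length. Each pattern's CMH p-value and minimum attainable
#' p-value feed the FWER state (Tarone's testability correction or
#' Westfall-Young permutations), and subtrees whose descendant envelope
#' exceeds the current threshold are pruned. The FWER state is shared across
#' all interactions, so the final threshold corrects for the entire search.
#'
#' @param dataset an `mm_dataset` from [new_dataset()] / [read_dataset()].
#' @param interactions an `mm_interactions` family of gene sets.
#' @param alpha target FWER level.
#' @param fwer `"tarone"` or `"wy"`.
#' @param K permutation count (Westfall-Young only).
#' @param seed RNG seed for the label permutations.
#' @param max_interval_len optional cap on per-gene interval length.
#' @param grid_ratio geometric grid ratio for the threshold.
#' @param prune disable to force exhaustive enumeration (debugging and
#'   enumeration-count checks).
#' @param envelope_tight use the joint candidate-product envelope (default)
#'   or the separable bound (see [envelope_pvalue()]).
#' @return an `mm_result` with the significant closed patterns (a tibble),
#'   the final threshold `delta_final`, and search counters.
#' @export
mine <- function(dataset, interactions, alpha = 0.05,
                 fwer = c("tarone", "wy"), K = 10000L, seed = 1L,
                 max_interval_len = Inf, grid_ratio = 0.9,
                 prune = TRUE, envelope_tight = TRUE) {
  stopifnot(inherits(dataset, "mm_dataset"))
  fwer <- match.arg(fwer)
  if (!inherits(interactions, "mm_interactions")) {
    interactions <- as_interactions(interactions, dataset$gene_map)
  }
  masks <- dataset$masks
  state <- if (fwer == "tarone") {
    new_tarone_state(alpha, grid_ratio)
  } else {
    new_wy_state(alpha, make_permutations(masks, K, seed), grid_ratio)
  }
  nn <- masks$n_j; n1 <- masks$n1_j
  counters <- list(processed = 0L, pruned = 0L, closed_filtered = 0L)
  entries <- list()          # pattern info for potential significance
  test_pmin <- list()        # (p_min, p) of every pattern with p_min <= alpha
  test_p <- list()

  record <- function(gi, enc_chr, ivals, pm, p, sup_cnt, keep) {
    if (!any(keep)) return()
    entries[[length(entries) + 1L]] <<- list(
      inter = gi, enc = enc_chr,
      ivals = ivals[, keep, drop = FALSE],
      p_min = pm[keep], p = p[keep], support = sup_cnt[keep])
  }

  for (gi in seq_along(interactions)) {
    genes <- interactions[[gi]]
    rows_per_gene <- dataset$gene_map[genes]
    if (any(vapply(rows_per_gene, is.null, TRUE))) {
      warning(sprintf("interaction %d skipped: gene(s) without mapped markers", gi))
      next
    }
    sizes <- lengths(rows_per_gene)
    k <- length(genes)
    enc_sets <- if (dataset$mode == "additive") {
      as.matrix(expand.grid(rep(list(c("d", "r")), k), stringsAsFactors = FALSE))
    } else {
      matrix("d", 1, k)
    }
    for (hi in seq_len(nrow(enc_sets))) {
      h <- enc_sets[hi, ]
      enc_chr <- paste(h, collapse = "")
      mb <- do.call(cbind, lapply(seq_len(k), function(i) {
        bits <- if (h[i] == "d") dataset$bits_dom else dataset$bits_rec
        bits[, rows_per_gene[[i]], drop = FALSE]
      }))
      offsets <- cumsum(c(0L, sizes[-k]))
      ivals <- initial_ivals(sizes)
      first <- offsets[1] + ivals[1, ]
      sup <- mb[, first, drop = FALSE]
      if (k > 1) {
        for (i in 2:k) {
          sup <- .bm_or(sup, mb[, offsets[i] + ivals[2L * i - 1L, ], drop = FALSE])
        }
      }
      repeat {
        P <- ncol(ivals)
        if (P == 0) break
        cc <- .bm_strat_counts(sup, masks$members, masks$cases)
        st <- cmh_block(cc$x, cc$a, nn, n1)
        if (fwer == "tarone") {
          inserted <- tarone_insert(state, st$p_min)
        } else {
          wy_insert(state, sup, st$esum, st$den, st$p_min)
          inserted <- st$p <= threshold(state)
        }
        delta <- threshold(state)
        counters$processed <- counters$processed + P
        testable_now <- st$p_min <= alpha
        if (any(testable_now)) {
          test_pmin[[length(test_pmin) + 1L]] <- st$p_min[testable_now]
          test_p[[length(test_p) + 1L]] <- st$p[testable_now]
        }
        sup_cnt <- colSums(cc$x)
        record(gi, enc_chr, ivals, st$p_min, st$p, sup_cnt, inserted)
        if (prune) {
          penv <- penv_vec(cc$x, nn, n1, tight = envelope_tight)
          keep <- penv <= delta
          counters$pruned <- counters$pruned + sum(!keep)
        } else {
          keep <- rep(TRUE, P)
        }
        ivals <- ivals[, keep, drop = FALSE]
        sup <- sup[, keep, drop = FALSE]
        ch <- gen_children(ivals, sizes, max_interval_len)
        if (length(ch$parent) == 0) break
        sup <- .bm_or_gather(sup, ch$parent, mb, ch$newcol)
        ivals <- ch$ivals
      }
    }
  }

  finalize_mining(dataset, interactions, state, entries, counters,
                  unlist(test_pmin), unlist(test_p),
                  config = list(alpha = alpha, method = fwer, K = K,
                                seed = seed, grid_ratio = grid_ratio,
                                max_interval_len = max_interval_len,
                                prune = prune, mode = dataset$mode))
}

finalize_mining <- function(dataset, interactions, state, entries, counters,
                            test_pmin, test_p, config) {
  delta <- threshold(state)
  testable <- if (inherits(state, "mm_tarone_state")) {
    state$tcount
  } else {
    lev <- seq_along(state$hist) - 1L
    as.integer(sum(state$hist[lev >= state$L]))
  }
  min_p_testable <- if (length(test_pmin) && any(test_pmin <= delta)) {
    min(test_p[test_pmin <= delta])
  } else NA_real_

  rows <- list()
  for (en in entries) {
    keep <- en$p <= delta & en$p_min <= delta
    if (!any(keep)) next
    idx <- which(keep)
    genes <- interactions[[en$inter]]
    k <- length(genes)
    h <- strsplit(en$enc, "")[[1]]
    for (j in idx) {
      iv <- matrix(en$ivals[, j], nrow = 2)
      rows[[length(rows) + 1L]] <- list(
        inter = en$inter, genes = genes, enc = h, ivals = iv,
        p_min = en$p_min[j], p = en$p[j], support = en$support[j],
        key = paste(paste(genes, collapse = ","), en$enc,
                    paste(en$ivals[, j], collapse = "."), sep = "|"))
    }
  }
  if (length(rows)) {
    keys <- vapply(rows, `[[`, "", "key")
    rows <- rows[!duplicated(keys)]
    closed <- vapply(rows, function(r) {
      is_closed(dataset, r$genes, r$ivals, r$enc)
    }, TRUE)
    counters$closed_filtered <- sum(!closed)
    rows <- rows[closed]
    ord <- order(vapply(rows, `[[`, 0, "p"), vapply(rows, `[[`, "", "key"))
    rows <- rows[ord]
  }
  sig <- tibble::tibble(
    p = vapply(rows, `[[`, 0, "p"),
    p_min = vapply(rows, `[[`, 0, "p_min"),
    support = as.integer(vapply(rows, `[[`, 0, "support")),
    interaction = vapply(rows, `[[`, 0L, "inter"),
    genes = vapply(rows, function(r) paste(r$genes, collapse = ","), ""),
    encodings = vapply(rows, function(r) paste(r$enc, collapse = ","), ""),
    intervals = vapply(rows, function(r) {
      paste(vapply(seq_along(r$genes), function(i) {
        gr <- dataset$gene_map[[r$genes[i]]]
        paste0(dataset$marker_ids[gr[r$ivals[1, i]]], "-",
               dataset$marker_ids[gr[r$ivals[2, i]]])
      }, ""), collapse = ";")
    }, ""),
    marker_rows = lapply(rows, function(r) {
      sort(unique(unlist(lapply(seq_along(r$genes), function(i) {
        gr <- dataset$gene_map[[r$genes[i]]]
        gr[r$ivals[1, i]:r$ivals[2, i]]
      }))))
    }),
    key = vapply(rows, `[[`, "", "key")
  )
  counters$testable <- as.integer(testable)
  structure(list(
    significant = sig,
    delta_final = delta,
    alpha = config$alpha,
    method = config$method,
    min_p_testable = min_p_testable,
    counters = counters,
    config = config
  ), class = "mm_result")
}

#' @export
print.mm_result <- function(x, ...) {
  cat(sprintf("<mm_result: %s, alpha=%g, delta_final=%.4g>\n",
              x$method, x$alpha, x$delta_final))
  cat(sprintf("  processed %d patterns (%d pruned subtree roots), %d testable\n",
              x$counters$processed, x$counters$pruned, x$counters$testable))
  cat(sprintf("  %d significant closed patterns (%d non-closed filtered)\n",
              nrow(x$significant), x$counters$closed_filtered))
  if (nrow(x$significant)) {
    print(utils::head(x$significant[, c("p", "support", "genes", "encodings",
                                        "intervals")], 10))
  }
  invisible(x)
}
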