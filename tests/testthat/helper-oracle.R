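# Brute-force oracle miner: enumerates every pattern of every interaction
# with no pruning and no canonical-generation shortcuts, computes each
# pattern's statistics through the scalar public API, and derives the final
# threshold directly from the full pattern list. Used to certify that the
# branch-and-bound miner loses nothing.

oracle_enumerate <- function(dataset, interactions, max_interval_len = Inf) {
  pats <- list()
  for (gi in seq_along(interactions)) {
    genes <- interactions[[gi]]
    k <- length(genes)
    sizes <- lengths(dataset$gene_map[genes])
    enc_sets <- if (dataset$mode == "additive") {
      as.matrix(expand.grid(rep(list(c("d", "r")), k), stringsAsFactors = FALSE))
    } else {
      matrix("d", 1, k)
    }
    per_gene_ivals <- lapply(sizes, function(sz) {
      iv <- expand.grid(s = seq_len(sz), e = seq_len(sz))
      iv <- iv[iv$e >= iv$s & (iv$e - iv$s + 1) <= max_interval_len, ]
      iv
    })
    combos <- expand.grid(lapply(per_gene_ivals, function(iv) seq_len(nrow(iv))))
    for (hi in seq_len(nrow(enc_sets))) {
      h <- enc_sets[hi, ]
      for (ci in seq_len(nrow(combos))) {
        ivm <- vapply(seq_len(k), function(i) {
          iv <- per_gene_ivals[[i]][combos[ci, i], ]
          c(iv$s, iv$e)
        }, integer(2))
        ivm <- matrix(as.integer(ivm), nrow = 2)
        sup <- pattern_support(dataset, genes, ivm, h)
        cc <- stratified_counts(sup, dataset$masks)
        tp <- cmh_pvalue(cc)
        pats[[length(pats) + 1L]] <- list(
          inter = gi, genes = genes, enc = h, ivals = ivm,
          support = sup, counts = cc, p = tp$p,
          p_min = min_attainable_pvalue(cc),
          key = paste(paste(genes, collapse = ","), paste(h, collapse = ""),
                      paste(as.vector(ivm), collapse = "."), sep = "|"))
      }
    }
  }
  pats
}

# Largest grid threshold delta = alpha * gamma^L satisfying the Tarone bound,
# scanning grid levels from the top (infeasible levels stay infeasible).
oracle_tarone_delta <- function(pmins, alpha, gamma) {
  lev <- floor(log(pmins / alpha) / log(gamma) + 1e-9)
  lev[pmins <= 0] <- 1e6
  L <- 0
  repeat {
    cnt <- sum(lev >= L)
    if (gamma^L * cnt <= 1) return(list(delta = alpha * gamma^L, L = L))
    L <- L + 1
  }
}

# Per-permutation minimum p-values computed naively: for every pattern and
# permutation, rebuild the 2x2xC table from the unpacked logical vectors.
oracle_wy_minp <- function(dataset, pats, perms) {
  masks <- dataset$masks
  n <- masks$n
  strata <- masks$strata
  K <- perms$K
  minT <- numeric(K)
  C <- masks$C
  nn <- masks$n_j; n1 <- masks$n1_j
  sup_log <- lapply(pats, function(p) as.logical(p$support))
  for (j in seq_len(K)) {
    case_j <- metaminer:::new_bitset(perms$case_bits[, j], n)
    case_log <- as.logical(case_j)
    best <- 0
    for (pi in seq_along(pats)) {
      s <- sup_log[[pi]]
      a <- vapply(seq_len(C) - 1L, function(c) sum(s & case_log & strata == c), 0)
      cc <- list(x = pats[[pi]]$counts$x, a = as.integer(a), n = nn, n1 = n1)
      Tj <- cmh_pvalue(cc)$T
      if (Tj > best) best <- Tj
    }
    minT[j] <- best
  }
  minT
}

oracle_wy_delta <- function(minT, alpha, gamma, K) {
  L <- 0
  repeat {
    thr <- qchisq(alpha * gamma^L, 1, lower.tail = FALSE)
    if (mean(minT >= thr) <= alpha) return(list(delta = alpha * gamma^L, L = L))
    L <- L + 1
  }
}

# Independent closedness check over the enumerated pattern list: every
# immediate interval shrink must lose support.
oracle_is_closed <- function(pat, support_by_key) {
  iv <- pat$ivals
  k <- ncol(iv)
  cnt <- support_count(pat$support)
  for (i in seq_len(k)) {
    if (iv[2, i] - iv[1, i] < 1) next
    for (side in 1:2) {
      shr <- iv
      if (side == 1) shr[1, i] <- shr[1, i] + 1L else shr[2, i] <- shr[2, i] - 1L
      key <- paste(paste(pat$genes, collapse = ","), paste(pat$enc, collapse = ""),
                   paste(as.vector(shr), collapse = "."), sep = "|")
      if (support_by_key[[key]] >= cnt) return(FALSE)
    }
  }
  TRUE
}

oracle_mine <- function(dataset, interactions, alpha = 0.05,
                        fwer = c("tarone", "wy"), K = 50, seed = 1,
                        grid_ratio = 0.9, max_interval_len = Inf) {
  fwer <- match.arg(fwer)
  pats <- oracle_enumerate(dataset, interactions, max_interval_len)
  pmins <- vapply(pats, `[[`, 0, "p_min")
  ps <- vapply(pats, `[[`, 0, "p")
  if (fwer == "tarone") {
    d <- oracle_tarone_delta(pmins, alpha, grid_ratio)
  } else {
    perms <- make_permutations(dataset$masks, K, seed)
    minT <- oracle_wy_minp(dataset, pats, perms)
    d <- oracle_wy_delta(minT, alpha, grid_ratio, K)
  }
  delta <- d$delta
  sig_idx <- which(ps <= delta & pmins <= delta)
  support_by_key <- new.env(parent = emptyenv())
  for (p in pats) assign(p$key, support_count(p$support), support_by_key)
  sig_idx <- sig_idx[!duplicated(vapply(pats[sig_idx], `[[`, "", "key"))]
  closed <- vapply(pats[sig_idx], oracle_is_closed, TRUE,
                   support_by_key = support_by_key)
  sig_idx <- sig_idx[closed]
  keys <- vapply(pats[sig_idx], `[[`, "", "key")
  ord <- order(ps[sig_idx], keys)
  list(delta_final = delta,
       sig_keys = keys[ord],
       sig_p = ps[sig_idx][ord],
       n_patterns = length(pats))
}

# Random tiny mining instance shared by the oracle-equivalence tests.
random_tiny_instance <- function(seed, mode = c("binary", "additive")) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- sample(20:50, 1)
  n_genes <- sample(2:4, 1)
  sizes <- sample(1:4, n_genes, replace = TRUE)
  L <- sum(sizes)
  geno <- matrix(sample(0:(if (mode == "binary") 1 else 2), L * n, replace = TRUE,
                        prob = if (mode == "binary") c(0.7, 0.3) else c(0.55, 0.3, 0.15)),
                 L, n)
  # occasionally plant signal so significant sets are non-trivial
  y <- if (seed %% 3 == 0) {
    as.integer(geno[1, ] >= 1)
  } else {
    sample(0:1, n, replace = TRUE)
  }
  if (length(unique(y)) < 2) y[sample(n, 2)] <- c(0L, 1L)
  strata <- sample(0:(sample(1:2, 1) - 1L), n, replace = TRUE)
  gene_map <- split(seq_len(L), rep(seq_len(n_genes), sizes))
  names(gene_map) <- paste0("g", seq_len(n_genes))
  ds <- suppressWarnings(new_dataset(geno, y, gene_map, strata = strata, mode = mode))
  genes <- names(gene_map)
  ints <- list()
  for (g in genes) ints[[length(ints) + 1L]] <- g
  if (n_genes >= 2) ints[[length(ints) + 1L]] <- genes[1:2]
  if (n_genes >= 3) ints[[length(ints) + 1L]] <- genes[1:3]
  list(dataset = ds, interactions = as_interactions(ints, ds))
}
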