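# Shared fixture builders. Everything is generated in code at test time.

# Tiny deterministic dataset: L x n genotypes from a literal matrix.
fixture_dataset <- function(geno, y, gene_map, strata = NULL,
                            mode = "binary") {
  suppressWarnings(new_dataset(geno, y, gene_map, strata = strata, mode = mode))
}

# Random stratified margins (n, n1 per stratum) plus a carrier count x and an
# achievable case-carrier count a.
random_margins <- function(C_max = 3, n_max = 30, degenerate_ok = TRUE) {
  C <- sample(seq_len(C_max), 1)
  n <- sample(seq(2, n_max), C, replace = TRUE)
  lo <- if (degenerate_ok) 0 else 1
  n1 <- vapply(n, function(m) sample(seq(lo, m - lo), 1), 0)
  x <- vapply(n, function(m) sample(seq(lo, m - lo), 1), 0)
  aL <- pmax(0, x - (n - n1))
  aU <- pmin(x, n1)
  a <- mapply(function(l, u) if (u >= l) sample(seq(l, u), 1) else l, aL, aU)
  list(x = as.integer(x), a = as.integer(a), n = as.integer(n),
       n1 = as.integer(n1))
}

# Direct per-sample counting oracle for stratified_counts.
naive_strat_counts <- function(support_lgl, strata, y) {
  C <- length(unique(strata))
  list(x = vapply(seq_len(C) - 1L, function(c) sum(support_lgl & strata == c), 0),
       a = vapply(seq_len(C) - 1L, function(c) sum(support_lgl & strata == c & y == 1), 0))
}

# Draw a simulated dataset conditional on label-balance feasibility: the
# carrier success-probability shift requires rho <= (1 - pi) / pi for carrier
# fraction pi, so seeds whose planted draw is too common are skipped
# deterministically. `rho_check` lets callers demand feasibility at a larger
# rho than the one generated, so that the same seed (hence the same genotype
# and planted-truth draw) can be reused across a whole rho grid.
sim_feasible <- function(seed, rho, rho_check = rho, ..., max_tries = 200) {
  for (t in seq_len(max_tries) - 1L) {
    s <- seed + t * 1000003L
    ok <- tryCatch({
      simulate_dataset(seed = s, rho = rho_check, ...)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(simulate_dataset(seed = s, rho = rho, ...))
  }
  stop("no feasible simulation draw found")
}
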