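#' Simulate a dataset with a planted meta-marker
#'
#' Generates the synthetic study design used for power and error-control
#' experiments: an Erdos-Renyi G(n, m) gene network, a per-gene SNP count
#' drawn uniformly from `snps_per_gene`, i.i.d. genotypes per marker
#' (Bernoulli(maf) in binary mode, Binomial(2, maf) in additive mode, with
#' maf drawn uniformly from `maf_range`), and a planted meta-marker: a random
#' connected subgraph of `k_star` genes, one short genomic interval per gene,
#' whose OR-aggregated indicator `z` shifts the phenotype probability.
#' Carriers (`z = 1`) are cases with probability `0.5 + rho/2`; non-carriers
#' with the probability `q` that keeps the expected overall prevalence at
#' 0.5. `rho = 0` therefore yields labels independent of the genotypes. The
#' covariate is drawn independently of both.
#'
#' @param n_genes,n_edges gene-network size (G(n, m) model).
#' @param n_samples number of samples.
#' @param snps_per_gene inclusive range of per-gene SNP counts.
#' @param mode `"binary"` or `"additive"` genotype encoding.
#' @param maf_range inclusive range of minor-allele frequencies.
#' @param k_star planted connected-subgraph size.
#' @param planted_len inclusive range of planted interval lengths.
#' @param planted_encoding encoding of the planted intervals (additive mode;
#'   binary mode forces dominant).
#' @param rho association strength in `[0, 1)`; must satisfy
#'   `rho <= (1 - pi) / pi` with `pi` the carrier fraction, or the balancing
#'   probability `q` would leave `[0, 1]`.
#' @param n_covariate_classes number of (independent) covariate classes.
#' @param seed RNG seed; output is deterministic given `seed`.
#' @return an `mm_sim` list: `dataset` (an `mm_dataset`), `truth` (planted
#'   genes, gene-local intervals, encodings, marker rows, carrier vector
#'   `z`), and `network` (edge matrix).
#' @export
simulate_dataset <- function(n_genes = 75L, n_edges = 100L, n_samples = 3000L,
                             snps_per_gene = c(3L, 10L),
                             mode = c("binary", "additive"),
                             maf_range = c(0.1, 0.4),
                             k_star = 3L, planted_len = c(1L, 3L),
                             planted_encoding = c("dominant", "recessive"),
                             rho = 0.2, n_covariate_classes = 2L, seed = 1L) {
  mode <- match.arg(mode)
  planted_encoding <- match.arg(planted_encoding)
  if (mode == "binary") planted_encoding <- "dominant"
  stopifnot(rho >= 0, rho < 1, k_star >= 1, k_star <= n_genes,
            n_edges <= choose(n_genes, 2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)

  genes <- sprintf("g%d", seq_len(n_genes))
  # G(n, m): m distinct unordered pairs, uniform
  pair_idx <- sample.int(choose(n_genes, 2), n_edges)
  all_pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  edges <- cbind(genes[all_pairs[pair_idx, 1]], genes[all_pairs[pair_idx, 2]])

  sizes <- sample(seq(snps_per_gene[1], snps_per_gene[2]), n_genes,
                  replace = TRUE)
  L <- sum(sizes)
  gene_map <- split(seq_len(L), rep(seq_len(n_genes), sizes))
  names(gene_map) <- genes

  maf <- stats::runif(L, maf_range[1], maf_range[2])
  trials <- if (mode == "binary") 1L else 2L
  geno <- matrix(stats::rbinom(L * n_samples, trials, rep(maf, n_samples)),
                 nrow = L, ncol = n_samples)

  planted_genes <- grow_connected(edges, genes, k_star)
  k <- length(planted_genes)
  intervals <- matrix(0L, 2, k)
  for (i in seq_len(k)) {
    sz <- sizes[match(planted_genes[i], genes)]
    len <- min(sample(seq(planted_len[1], planted_len[2]), 1), sz)
    s <- sample.int(sz - len + 1L, 1)
    intervals[, i] <- c(s, s + len - 1L)
  }
  marker_rows <- sort(unique(unlist(lapply(seq_len(k), function(i) {
    gr <- gene_map[[planted_genes[i]]]
    gr[intervals[1, i]:intervals[2, i]]
  }))))
  thr <- if (planted_encoding == "dominant") 1L else 2L
  z <- as.integer(colSums(geno[marker_rows, , drop = FALSE] >= thr) > 0)

  p1 <- 0.5 + rho / 2
  pi_c <- mean(z)
  if (pi_c >= 1) stop("planted meta-marker carried by every sample; cannot balance labels")
  q <- (0.5 - pi_c * p1) / (1 - pi_c)
  if (q < 0 || q > 1) {
    stop(sprintf("infeasible rho = %g for carrier fraction %.3f (need rho <= %.3f)",
                 rho, pi_c, (1 - pi_c) / pi_c), call. = FALSE)
  }
  y <- stats::rbinom(n_samples, 1, ifelse(z == 1, p1, q))
  strata <- sample.int(n_covariate_classes, n_samples, replace = TRUE) - 1L

  dataset <- new_dataset(geno, y, gene_map, strata = strata, mode = mode)
  truth <- list(genes = planted_genes, intervals = intervals,
                encodings = rep(substr(planted_encoding, 1, 1), k),
                marker_rows = marker_rows, z = z, rho = rho)
  structure(list(dataset = dataset, truth = truth, network = edges),
            class = "mm_sim")
}

# Uniform-ish random connected subgraph of size k: BFS-style growth from a
# random start, adding a uniformly chosen neighbor of the current set at each
# step; restarts if the start's component is too small.
grow_connected <- function(edges, genes, k) {
  if (k == 1) return(sample(genes, 1))
  adj <- lapply(stats::setNames(vector("list", length(genes)), genes), identity)
  for (j in seq_len(nrow(edges))) {
    a <- edges[j, 1]; b <- edges[j, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  starts <- sample(genes)
  for (s in starts) {
    sub <- s
    repeat {
      if (length(sub) == k) return(sort(sub))
      nb <- setdiff(unique(unlist(adj[sub])), sub)
      if (length(nb) == 0) break
      sub <- c(sub, sample(nb, 1))
    }
  }
  stop(sprintf("no connected subgraph of size %d exists in the network", k),
       call. = FALSE)
}

#' Binarize an additive dataset under a fixed encoding
#'
#' Utility for wrong-encoding experiments: collapses an additive-mode dataset
#' to binary mode by applying one encoding to every marker (dominant: 1 and 2
#' map to 1; recessive: only 2 maps to 1).
#'
#' @param dataset an additive-mode `mm_dataset`.
#' @param encoding `"dominant"` or `"recessive"`.
#' @return a binary-mode `mm_dataset` over the same samples and genes.
#' @export
binarize_dataset <- function(dataset, encoding = c("dominant", "recessive")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(dataset, "mm_dataset"), dataset$mode == "additive")
  thr <- if (encoding == "dominant") 1L else 2L
  geno <- matrix(as.integer(dataset$genotypes >= thr), nrow = dataset$L)
  new_dataset(geno, dataset$y, dataset$gene_map, strata = dataset$strata,
              marker_ids = dataset$marker_ids, mode = "binary")
}

#' Count true positives against a planted ground truth
#'
#' A significant pattern counts as a true positive when its marker set
#' intersects the planted marker set (overlap counting; an exact-match rule
#' would understate partially recovered signals).
#'
#' @param result an `mm_result`.
#' @param truth the `truth` component of an [simulate_dataset()] `mm_sim`.
#' @return integer count.
#' @export
count_true_positives <- function(result, truth) {
  stopifnot(inherits(result, "mm_result"))
  if (nrow(result$significant) == 0) return(0L)
  sum(vapply(result$significant$marker_rows, function(rows) {
    length(intersect(rows, truth$marker_rows)) > 0
  }, TRUE))
}
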