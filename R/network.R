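#' Enumerate connected subgraphs of a gene network
#'
#' Gene interactions can be derived from a biological network (e.g. a
#' protein-protein interaction graph) as the node sets of size `1..k_max`
#' that induce a connected subgraph. Enumeration uses ESU-style recursive
#' extension with exclusive neighborhoods, which emits every connected
#' subgraph exactly once; output order is deterministic (sorted canonical
#' keys).
#'
#' @param edges two-column matrix or data frame of undirected gene-id edges;
#'   self-loops are dropped.
#' @param k_max maximum subgraph size (>= 1).
#' @param min_size smallest size to emit (e.g. 2 to mine only edges and
#'   larger).
#' @param nodes optional full node set (needed to emit singletons for
#'   isolated genes); defaults to the genes incident to `edges`.
#' @return an `mm_interactions` object.
#' @examples
#' connected_subgraphs(cbind(c("a", "b"), c("b", "c")), k_max = 3)
#' @export
connected_subgraphs <- function(edges, k_max, min_size = 1L, nodes = NULL) {
  if (k_max < 1) stop("connected_subgraphs(): k_max must be >= 1", call. = FALSE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && length(edges) > 0) {
    stop("edges must have two columns", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- unique(as.character(edges))
  nodes <- sort(unique(as.character(nodes)))
  N <- length(nodes)
  adj <- vector("list", N)
  if (nrow(edges) > 0) {
    e1 <- match(as.character(edges[, 1]), nodes)
    e2 <- match(as.character(edges[, 2]), nodes)
    if (anyNA(e1) || anyNA(e2)) stop("edge references unknown node", call. = FALSE)
    keep <- e1 != e2
    e1 <- e1[keep]; e2 <- e2[keep]
    for (i in seq_len(N)) adj[[i]] <- integer(0)
    for (j in seq_along(e1)) {
      adj[[e1[j]]] <- c(adj[[e1[j]]], e2[j])
      adj[[e2[j]]] <- c(adj[[e2[j]]], e1[j])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  } else {
    for (i in seq_len(N)) adj[[i]] <- integer(0)
  }

  out <- list()
  emit <- function(sub) {
    if (length(sub) >= min_size) out[[length(out) + 1L]] <<- sort(sub)
  }
  # ESU: grow only with nodes of larger index than the root that are not yet
  # in the subgraph's closed neighborhood, so each subgraph has one parent.
  extend <- function(sub, ext, root, in_nbhd) {
    emit(sub)
    if (length(sub) == k_max) return()
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      excl <- setdiff(adj[[w]][adj[[w]] > root], which(in_nbhd))
      in_nbhd2 <- in_nbhd
      in_nbhd2[c(w, adj[[w]])] <- TRUE
      extend(c(sub, w), c(ext, excl), root, in_nbhd2)
    }
  }
  for (v in seq_len(N)) {
    in_nbhd <- logical(N)
    in_nbhd[c(v, adj[[v]])] <- TRUE
    extend(v, adj[[v]][adj[[v]] > v], v, in_nbhd)
  }
  sets <- lapply(out, function(s) nodes[s])
  keys <- vapply(sets, paste, "", collapse = "\x1f")
  as_interactions(sets[order(lengths(sets), keys)])
}

#' Turn protein-complex gene lists into interactions
#'
#' Complexes with more than `max_size` genes, or containing a gene without
#' mapped markers, are skipped (with a warning for unmapped genes); the rest
#' become gene interactions.
#'
#' @param complex_lists list of character vectors of gene ids (one complex
#'   each).
#' @param gene_map named gene map (or an `mm_dataset`).
#' @param max_size largest complex to keep; larger ones are dropped to avoid
#'   a combinatorial blow-up of the pattern space.
#' @return an `mm_interactions` object.
#' @export
complexes_to_interactions <- function(complex_lists, gene_map, max_size = 5L) {
  if (inherits(gene_map, "mm_dataset")) gene_map <- gene_map$gene_map
  kept <- list()
  for (i in seq_along(complex_lists)) {
    genes <- unique(as.character(complex_lists[[i]]))
    if (length(genes) > max_size) next
    unmapped <- setdiff(genes, names(gene_map))
    if (length(unmapped)) {
      warning(sprintf("complex %d skipped: gene '%s' has no mapped markers",
                      i, unmapped[1]))
      next
    }
    kept[[length(kept) + 1L]] <- genes
  }
  as_interactions(kept)
}

#' Read a gene-network edge list
#'
#' Two whitespace-separated gene ids per line.
#'
#' @param path edge-list file.
#' @return a two-column character matrix.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop(sprintf("expected two gene ids at line %d of %s", bad[1], path),
         call. = FALSE)
  }
  matrix(unlist(parts), ncol = 2, byrow = TRUE)
}

#' Read protein complexes (one complex per line, genes whitespace-separated)
#'
#' @param path complexes file.
#' @return a list of character vectors.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  strsplit(trimws(lines), "[[:space:]]+")
}
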