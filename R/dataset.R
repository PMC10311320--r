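#' Assemble an in-memory mining dataset
#'
#' Bundles the genotype matrix, phenotype labels, covariate strata and the
#' gene-to-marker map, validates their mutual consistency, and precomputes
#' the stratum masks and the binarized per-marker bitsets that the miner
#' works on.
#'
#' @param genotypes integer matrix, markers in rows (genomic order), samples
#'   in columns; values in \{0,1,2\} (`mode = "additive"`) or \{0,1\}
#'   (`mode = "binary"`).
#' @param y integer phenotype labels in \{0,1\}, one per sample.
#' @param gene_map named list: gene id -> ordered integer vector of marker row
#'   indices (1-based). A marker may belong to several genes.
#' @param strata optional integer covariate classes (densely re-indexed to
#'   0..C-1); `NULL` means no covariate (a single stratum).
#' @param marker_ids optional marker labels; default `m1..mL`. Row index is
#'   the canonical marker identity, ids are labels for reporting.
#' @param mode `"binary"` or `"additive"`.
#' @return an object of class `mm_dataset`.
#' @export
new_dataset <- function(genotypes, y, gene_map, strata = NULL,
                        marker_ids = NULL, mode = c("binary", "additive")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 1, ncol(genotypes) >= 1)
  storage.mode(genotypes) <- "integer"
  L <- nrow(genotypes); n <- ncol(genotypes)
  alphabet <- if (mode == "binary") 0:1 else 0:2
  bad <- !(genotypes %in% alphabet)
  if (any(bad)) {
    r <- which(bad)[1]
    stop(sprintf("genotype value %d not allowed in %s mode (marker row %d)",
                 genotypes[r], mode, (r - 1L) %% L + 1L), call. = FALSE)
  }
  y <- as.integer(y)
  if (length(y) != n) {
    stop(sprintf("labels length (%d) does not match number of samples (%d)",
                 length(y), n), call. = FALSE)
  }
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2) {
    warning("phenotype has a single class; no association can be detected")
  }
  if (!is.null(strata)) {
    strata <- as.integer(strata)
    if (length(strata) != n) {
      stop(sprintf("covariates length (%d) does not match number of samples (%d)",
                   length(strata), n), call. = FALSE)
    }
    strata <- match(strata, sort(unique(strata))) - 1L  # dense re-index
  } else {
    strata <- integer(n)
  }
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(L))
  stopifnot(length(marker_ids) == L, !anyDuplicated(marker_ids))
  stopifnot(is.list(gene_map), length(gene_map) >= 1, !is.null(names(gene_map)))
  gene_map <- lapply(gene_map, as.integer)
  for (g in names(gene_map)) {
    idx <- gene_map[[g]]
    if (length(idx) < 1 || any(idx < 1 | idx > L)) {
      stop(sprintf("gene '%s' maps to no valid marker rows", g), call. = FALSE)
    }
  }
  masks <- stratum_masks(y, strata)
  ds <- structure(list(
    genotypes = genotypes, marker_ids = as.character(marker_ids),
    y = y, strata = strata, C = masks$C,
    gene_map = gene_map, mode = mode, n = n, L = L,
    masks = masks,
    bits_dom = .bm_binarize(genotypes, seq_len(L), 1L),
    bits_rec = if (mode == "additive") .bm_binarize(genotypes, seq_len(L), 2L) else NULL
  ), class = "mm_dataset")
  ds
}

#' @export
print.mm_dataset <- function(x, ...) {
  cat(sprintf("<mm_dataset: %d markers x %d samples (%s mode), %d genes, %d covariate classes, %d cases>\n",
              x$L, x$n, x$mode, length(x$gene_map), x$C, sum(x$y)))
  invisible(x)
}

# One integer per line canonically; multiple whitespace-separated values on a
# line are tolerated.
read_int_lines <- function(path, what) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  lineno <- rep(seq_along(lines), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)
  keep <- nzchar(flat)
  flat <- flat[keep]; lineno <- lineno[keep]
  v <- suppressWarnings(as.integer(flat))
  if (anyNA(v)) {
    stop(sprintf("%s: non-integer token '%s' at line %d of %s",
                 what, flat[which(is.na(v))[1]], lineno[which(is.na(v))[1]],
                 path), call. = FALSE)
  }
  v
}

#' Read a dataset from plain-text files
#'
#' File dialects: the genotype file holds one whitespace-separated row per
#' marker, column `i` being sample `i`; the labels and covariates files hold
#' one integer per line; the gene map has lines
#' `gene_id<TAB>marker,marker,...` where each marker is either a marker id
#' (`m3`) or a 1-based row index (`3`).
#'
#' @param genotype_path,labels_path,genemap_path input files.
#' @param covariates_path optional covariate file; absent means one stratum.
#' @param mode `"binary"` or `"additive"`.
#' @return an `mm_dataset`; see [new_dataset()].
#' @export
read_dataset <- function(genotype_path, labels_path, genemap_path,
                         covariates_path = NULL,
                         mode = c("binary", "additive")) {
  mode <- match.arg(mode)
  lines <- readLines(genotype_path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(tok) {
    suppressWarnings(as.integer(tok))
  })
  for (i in seq_along(rows)) {
    if (anyNA(rows[[i]])) {
      stop(sprintf("genotypes: non-integer token at line %d of %s", i,
                   genotype_path), call. = FALSE)
    }
  }
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    stop(sprintf("genotypes: ragged matrix in %s (line %d has %d values, expected %d)",
                 genotype_path, which(ncols != ncols[1])[1],
                 ncols[which(ncols != ncols[1])[1]], ncols[1]), call. = FALSE)
  }
  geno <- do.call(rbind, rows)
  alphabet <- if (mode == "binary") 0:1 else 0:2
  for (i in seq_along(rows)) {
    if (!all(rows[[i]] %in% alphabet)) {
      v <- rows[[i]][!(rows[[i]] %in% alphabet)][1]
      stop(sprintf("value %d not allowed in %s mode (line %d of %s)",
                   v, mode, i, genotype_path), call. = FALSE)
    }
  }
  y <- read_int_lines(labels_path, "labels")
  if (length(y) != ncol(geno)) {
    stop(sprintf("length mismatch: %s has %d labels but %s has %d samples",
                 labels_path, length(y), genotype_path, ncol(geno)),
         call. = FALSE)
  }
  strata <- NULL
  if (!is.null(covariates_path)) {
    strata <- read_int_lines(covariates_path, "covariates")
    if (length(strata) != ncol(geno)) {
      stop(sprintf("length mismatch: %s has %d covariates but %s has %d samples",
                   covariates_path, length(strata), genotype_path, ncol(geno)),
           call. = FALSE)
    }
  }
  marker_ids <- paste0("m", seq_len(nrow(geno)))
  gm_lines <- readLines(genemap_path)
  gm_lines <- gm_lines[nzchar(trimws(gm_lines))]
  gene_map <- list()
  for (i in seq_along(gm_lines)) {
    parts <- strsplit(gm_lines[i], "\t")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("gene map: expected 'gene<TAB>markers' at line %d of %s",
                   i, genemap_path), call. = FALSE)
    }
    toks <- strsplit(trimws(parts[2]), ",")[[1]]
    idx <- match(toks, marker_ids)
    raw <- suppressWarnings(as.integer(toks))
    idx[is.na(idx)] <- raw[is.na(idx)]
    if (anyNA(idx) || any(idx < 1 | idx > nrow(geno))) {
      stop(sprintf("gene map: unknown marker '%s' at line %d of %s",
                   toks[which(is.na(idx) | idx < 1 | idx > nrow(geno))[1]],
                   i, genemap_path), call. = FALSE)
    }
    gene_map[[trimws(parts[1])]] <- idx
  }
  new_dataset(geno, y, gene_map, strata = strata, marker_ids = marker_ids,
              mode = mode)
}

#' Gene-interaction sets
#'
#' An interaction set is an ordered family of gene-id sets; each set restricts
#' the miner to meta-markers spanning exactly those genes. Duplicate sets
#' (regardless of within-line order) are removed, keeping the first
#' occurrence.
#'
#' @param gene_sets list of character vectors of gene ids.
#' @param gene_map named gene map used to validate ids (a `mm_dataset` is also
#'   accepted); `NULL` skips validation.
#' @return an object of class `mm_interactions` (list of sorted character
#'   vectors).
#' @export
as_interactions <- function(gene_sets, gene_map = NULL) {
  if (inherits(gene_map, "mm_dataset")) gene_map <- gene_map$gene_map
  sets <- lapply(gene_sets, function(g) sort(unique(as.character(g))))
  keep <- !duplicated(vapply(sets, paste, "", collapse = "\x1f"))
  sets <- sets[keep]
  if (!is.null(gene_map)) {
    for (i in seq_along(sets)) {
      missing <- setdiff(sets[[i]], names(gene_map))
      if (length(missing)) {
        stop(sprintf("interaction %d references unknown gene '%s'",
                     i, missing[1]), call. = FALSE)
      }
    }
  }
  structure(sets, class = "mm_interactions")
}

#' @export
print.mm_interactions <- function(x, ...) {
  k <- lengths(x)
  cat(sprintf("<mm_interactions: %d interactions, sizes %s>\n", length(x),
              paste(names(table(k)), table(k), sep = "x", collapse = ", ")))
  invisible(x)
}

#' Read gene interactions from a file
#'
#' One interaction per line, gene ids separated by whitespace. Sets are
#' deduplicated; file order is preserved for reporting.
#'
#' @param path interactions file.
#' @param gene_map named gene map (or `mm_dataset`) to validate ids against.
#' @return an `mm_interactions` object.
#' @export
read_interactions <- function(path, gene_map) {
  if (inherits(gene_map, "mm_dataset")) gene_map <- gene_map$gene_map
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- strsplit(trimws(lines), "[[:space:]]+")
  for (i in seq_along(sets)) {
    missing <- setdiff(sets[[i]], names(gene_map))
    if (length(missing)) {
      stop(sprintf("unknown gene '%s' at line %d of %s", missing[1],
                   lineno[i], path), call. = FALSE)
    }
  }
  as_interactions(sets)
}

#' Write mining results to disk
#'
#' Produces `<prefix>.sig.tsv` with one row per significant closed pattern
#' (p-value, minimum attainable p-value, support count, interaction genes,
#' per-gene encoding d/r, per-gene interval as first/last marker id) sorted by
#' ascending p-value with ties broken by the pattern's canonical key, and
#' `<prefix>.summary.txt` with the run parameters, the final threshold and the
#' search counters.
#'
#' @param result an `mm_result` from [mine()].
#' @param out_prefix path prefix for the two output files.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, out_prefix) {
  stopifnot(inherits(result, "mm_result"))
  sig <- result$significant
  tsv <- file.path(paste0(out_prefix, ".sig.tsv"))
  df <- data.frame(
    p_value = format_num(sig$p), min_p = format_num(sig$p_min),
    support_count = sig$support,
    genes = sig$genes, encodings = sig$encodings, intervals = sig$intervals,
    stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  smry <- file.path(paste0(out_prefix, ".summary.txt"))
  co <- result$counters
  writeLines(c(
    sprintf("alpha\t%s", format_num(result$alpha)),
    sprintf("method\t%s", result$method),
    sprintf("delta_final\t%s", format_num(result$delta_final)),
    sprintf("n_processed\t%d", co$processed),
    sprintf("n_testable\t%d", co$testable),
    sprintf("n_pruned\t%d", co$pruned),
    sprintf("n_closed_filtered\t%d", co$closed_filtered),
    sprintf("n_significant\t%d", nrow(sig))
  ), smry)
  invisible(c(tsv, smry))
}

format_num <- function(x) sprintf("%.12g", x)

#' Write a dataset (and optional ground truth) as plain-text files
#'
#' Emits the [read_dataset()] dialect: `genotypes.txt`, `labels.txt`,
#' `covariates.txt`, `genemap.txt`, plus `network.txt` (gene-graph edge list)
#' and `truth.tsv` when a simulation is supplied.
#'
#' @param dataset an `mm_dataset`.
#' @param dir output directory (created if missing).
#' @param network optional two-column matrix/data frame of gene-id edges.
#' @param truth optional ground truth from [simulate_dataset()].
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir, network = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(apply(dataset$genotypes, 1, paste, collapse = " "),
             file.path(dir, "genotypes.txt"))
  writeLines(as.character(dataset$y), file.path(dir, "labels.txt"))
  writeLines(as.character(dataset$strata), file.path(dir, "covariates.txt"))
  gm <- vapply(names(dataset$gene_map), function(g) {
    paste0(g, "\t", paste(dataset$marker_ids[dataset$gene_map[[g]]],
                          collapse = ","))
  }, "")
  writeLines(gm, file.path(dir, "genemap.txt"))
  if (!is.null(network)) {
    writeLines(paste(network[, 1], network[, 2]), file.path(dir, "network.txt"))
  }
  if (!is.null(truth)) {
    tf <- data.frame(
      gene = truth$genes,
      interval_start = truth$intervals[1, ],
      interval_end = truth$intervals[2, ],
      encoding = truth$encodings,
      markers = vapply(seq_along(truth$genes), function(i) {
        rows <- dataset$gene_map[[truth$genes[i]]]
        paste(dataset$marker_ids[rows[truth$intervals[1, i]:truth$intervals[2, i]]],
              collapse = ",")
      }, ""),
      stringsAsFactors = FALSE)
    utils::write.table(tf, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
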