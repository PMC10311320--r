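write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("a small genotype/label file pair parses into a validated dataset", {
  g <- write_lines_tmp(c("0 1 2 0", "1 0 0 2", "0 0 1 1"))
  y <- write_lines_tmp(c("1", "0", "1", "0"))
  gm <- write_lines_tmp(c("gA\tm1,m2", "gB\tm3"))
  ds <- read_dataset(g, y, gm, mode = "additive")
  expect_s3_class(ds, "mm_dataset")
  expect_identical(ds$L, 3L)
  expect_identical(ds$n, 4L)
  expect_identical(ds$C, 1L)
  expect_identical(sum(ds$y), 2L)
  expect_identical(ds$gene_map, list(gA = c(1L, 2L), gB = 3L))
})

test_that("binary mode rejects additive values with a line number", {
  g <- write_lines_tmp(c("0 1 2 0", "1 0 0 2"))
  y <- write_lines_tmp(c("1", "0", "1", "0"))
  gm <- write_lines_tmp("gA\tm1,m2")
  expect_error(read_dataset(g, y, gm, mode = "binary"),
               "value 2 not allowed in binary mode.*line 1")
})

test_that("file length mismatches are reported with both file names", {
  g <- write_lines_tmp(c("0 1 0 1", "1 0 0 1"))
  y5 <- write_lines_tmp(c("1", "0", "1", "0", "1"))
  gm <- write_lines_tmp("gA\tm1,m2")
  err <- tryCatch(read_dataset(g, y5, gm), error = identity)
  expect_match(conditionMessage(err), "length mismatch")
  expect_match(conditionMessage(err), basename(y5))
  expect_match(conditionMessage(err), basename(g))
  cov <- write_lines_tmp(c("0", "1", "0"))
  y <- write_lines_tmp(c("1", "0", "1", "0"))
  expect_error(read_dataset(g, y, gm, covariates_path = cov),
               "length mismatch")
})

test_that("gene maps accept ids or indices and reject unknown markers", {
  g <- write_lines_tmp(c("0 1 0 1", "1 0 0 1"))
  y <- write_lines_tmp(c("1", "0", "1", "0"))
  gm_idx <- write_lines_tmp("gA\t1,2")
  ds <- read_dataset(g, y, gm_idx)
  expect_identical(ds$gene_map$gA, c(1L, 2L))
  gm_bad <- write_lines_tmp("gA\tm1,m9")
  expect_error(read_dataset(g, y, gm_bad), "unknown marker 'm9'.*line 1")
})

test_that("covariate classes are densely re-indexed on read", {
  g <- write_lines_tmp("0 1 0 1")
  y <- write_lines_tmp(c("1", "0", "1", "0"))
  gm <- write_lines_tmp("gA\tm1")
  cov <- write_lines_tmp(c("7", "7", "3", "3"))
  ds <- read_dataset(g, y, gm, covariates_path = cov)
  expect_identical(sort(unique(ds$strata)), c(0L, 1L))
  expect_identical(ds$C, 2L)
})

test_that("interaction files deduplicate order-insensitively and keep singletons", {
  gm <- list(gA = 1L, gB = 2L, gC = 3L)
  f <- write_lines_tmp(c("gA gB", "gB gA", "gA"))
  ints <- read_interactions(f, gm)
  expect_length(ints, 2)
  expect_identical(ints[[1]], c("gA", "gB"))
  expect_identical(ints[[2]], "gA")
  fbad <- write_lines_tmp(c("gA gB", "gA gX"))
  expect_error(read_interactions(fbad, gm), "unknown gene 'gX' at line 2")
})

test_that("result files round out: header-only when empty, sorted rows otherwise", {
  set.seed(30)
  geno <- rbind(rep(c(0L, 1L), each = 10), rep(c(0L, 1L), each = 10),
                sample(0:1, 20, replace = TRUE))
  y <- as.integer(geno[1, ])
  ds <- fixture_dataset(geno, y, list(gA = 1L, gB = 2L, gC = 3L))
  # two identical marker rows in two singleton interactions: identical p,
  # ties broken deterministically by the canonical key
  res <- mine(ds, as_interactions(list("gA", "gB", "gC"), ds))
  pre <- withr::local_tempfile()
  write_results(res, pre)
  tab <- read.delim(paste0(pre, ".sig.tsv"))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$genes, c("gA", "gB"))  # equal p, key order
  smry <- readLines(paste0(pre, ".summary.txt"))
  expect_true(any(grepl("^n_significant\t2$", smry)))

  # empty significant set
  y2 <- sample(0:1, 20, replace = TRUE)
  ds2 <- fixture_dataset(geno, y2, list(gA = 1L, gB = 2L, gC = 3L))
  res2 <- mine(ds2, as_interactions(list("gC"), ds2))
  pre2 <- withr::local_tempfile()
  write_results(res2, pre2)
  tab2 <- read.delim(paste0(pre2, ".sig.tsv"))
  expect_identical(nrow(tab2), 0L)
  expect_true(any(grepl("^n_significant\t0$",
                        readLines(paste0(pre2, ".summary.txt")))))
})

test_that("a written dataset re-reads entry-for-entry identical", {
  sim <- simulate_dataset(n_genes = 6, n_edges = 7, n_samples = 40,
                          k_star = 2, rho = 0, mode = "additive", seed = 31)
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir, network = sim$network, truth = sim$truth)
  ds2 <- read_dataset(file.path(dir, "genotypes.txt"),
                      file.path(dir, "labels.txt"),
                      file.path(dir, "genemap.txt"),
                      covariates_path = file.path(dir, "covariates.txt"),
                      mode = "additive")
  expect_identical(ds2$genotypes, sim$dataset$genotypes)
  expect_identical(ds2$y, sim$dataset$y)
  expect_identical(ds2$strata, sim$dataset$strata)
  expect_identical(ds2$gene_map, sim$dataset$gene_map)
  net <- read_network(file.path(dir, "network.txt"))
  expect_identical(net, unname(sim$network))
})

test_that("in-memory constructor enforces the basic invariants", {
  geno <- matrix(c(0L, 1L, 1L, 0L), 1)
  expect_error(new_dataset(geno, c(1L, 0L, 1L), list(g = 1L)),
               "does not match")
  expect_error(new_dataset(geno, c(1L, 0L, 1L, 0L), list(g = 5L)),
               "no valid marker rows")
  expect_error(new_dataset(matrix(c(0L, 1L, 2L, 0L), 1), c(1L, 0L, 1L, 0L),
                           list(g = 1L), mode = "binary"),
               "not allowed in binary mode")
  expect_warning(new_dataset(matrix(0:1, 1, 2), c(1L, 1L), list(g = 1L)),
                 "single class")
})
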