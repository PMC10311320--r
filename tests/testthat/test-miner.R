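test_that("level-one candidate counts follow the position/encoding combinatorics", {
  set.seed(40)
  n <- 30
  geno <- matrix(sample(0:2, 5 * n, replace = TRUE), 5, n)
  y <- sample(0:1, n, replace = TRUE)
  gm <- list(gA = 1:3, gB = 4:5)
  # capping intervals at length 1 restricts the search to the initial level
  ds_add <- fixture_dataset(geno, y, gm, mode = "additive")
  r <- mine(ds_add, as_interactions(list(c("gA", "gB")), ds_add),
            prune = FALSE, max_interval_len = 1)
  expect_equal(r$counters$processed, 24L)  # 3 * 2 positions x 2^2 encodings
  ds_bin <- fixture_dataset(matrix(as.integer(geno > 0), 5, n), y, gm)
  rb <- mine(ds_bin, as_interactions(list(c("gA", "gB")), ds_bin),
             prune = FALSE, max_interval_len = 1)
  expect_identical(rb$counters$processed, 6L)
  r1 <- mine(ds_add, as_interactions(list("gA"), ds_add),
             prune = FALSE, max_interval_len = 1)
  expect_identical(r1$counters$processed, 6L)  # 3 positions x 2 encodings
})

test_that("canonical child generation extends one gene rightward, lowest-index first", {
  sizes <- c(3L, 2L)
  # parent ([1,1],[1,1]): both genes extendable
  ch <- metaminer:::gen_children(matrix(c(1L, 1L, 1L, 1L), 4, 1), sizes)
  expect_identical(ncol(ch$ivals), 2L)
  expect_identical(ch$ivals[, 1], c(1L, 2L, 1L, 1L))
  expect_identical(ch$ivals[, 2], c(1L, 1L, 1L, 2L))
  # parent ([1,2],[1,1]): gene 2 blocked because gene 1 is long
  ch2 <- metaminer:::gen_children(matrix(c(1L, 2L, 1L, 1L), 4, 1), sizes)
  expect_identical(ncol(ch2$ivals), 1L)
  expect_identical(ch2$ivals[, 1], c(1L, 3L, 1L, 1L))
  # right-boundary parent with other genes long: no children
  ch3 <- metaminer:::gen_children(matrix(c(1L, 2L, 1L, 2L), 4, 1), c(2L, 2L))
  expect_identical(length(ch3$parent), 0L)
})

test_that("every interval configuration is generated exactly once", {
  set.seed(41)
  for (trial in 1:20) {
    k <- sample(1:3, 1)
    sizes <- sample(1:4, k, replace = TRUE)
    frontier <- metaminer:::initial_ivals(sizes)
    seen <- apply(frontier, 2, paste, collapse = ".")
    repeat {
      ch <- metaminer:::gen_children(frontier, sizes)
      if (length(ch$parent) == 0) break
      keys <- apply(ch$ivals, 2, paste, collapse = ".")
      expect_identical(anyDuplicated(keys), 0L)
      expect_length(intersect(keys, seen), 0)
      seen <- c(seen, keys)
      frontier <- ch$ivals
    }
    expect_equal(length(seen), prod(sizes * (sizes + 1) / 2))
  }
})

test_that("a support equal to the case set is maximally associated", {
  y <- rep(c(1L, 0L), each = 10)
  masks <- stratum_masks(y, NULL)
  cc <- stratified_counts(as_bitset(y == 1L), masks)
  r <- cmh_pvalue(cc)
  expect_equal(r$T, 19)  # T = n - 1 at perfect association
  expect_equal(r$p, pchisq(19, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(min_attainable_pvalue(cc), 0.05)
})

test_that("degenerate supports are untestable; empty support is still expandable", {
  y <- rep(c(1L, 0L), each = 10)
  masks <- stratum_masks(y, NULL)
  full <- stratified_counts(as_bitset(rep(TRUE, 20)), masks)
  expect_equal(min_attainable_pvalue(full), 1)
  expect_equal(envelope_pvalue(full), 1)      # prunable
  empty <- stratified_counts(as_bitset(rep(FALSE, 20)), masks)
  expect_equal(min_attainable_pvalue(empty), 1)
  expect_lt(envelope_pvalue(empty), 0.001)    # descendants can gain support
})

test_that("closedness compares against interval-shrink predecessors", {
  geno <- rbind(c(0L, 1L, 0L, 1L, 0L, 1L),
                c(0L, 0L, 0L, 0L, 0L, 0L),   # adds nothing to row 1
                c(1L, 0L, 0L, 0L, 1L, 0L))
  y <- c(1L, 0L, 1L, 0L, 1L, 0L)
  ds <- fixture_dataset(geno, y, list(g = 1:3))
  # single-marker patterns are closed by vacuity
  expect_true(is_closed(ds, "g", c(1, 1), "d"))
  # the added all-zero marker changes nothing: not closed
  expect_false(is_closed(ds, "g", c(1, 2), "d"))
  # both shrinks of [1,3]... left shrink [2,3] loses sample 2's carrier etc.
  expect_true(is_closed(ds, "g", c(1, 3), "d"))
})

test_that("cached supports equal recomputation and children only grow", {
  set.seed(42)
  inst <- random_tiny_instance(7, "additive")
  res <- mine(inst$dataset, inst$interactions, prune = FALSE)
  for (j in seq_len(min(nrow(res$significant), 20))) {
    row <- res$significant[j, ]
    genes <- strsplit(row$genes, ",")[[1]]
    enc <- strsplit(row$encodings, ",")[[1]]
    iv <- matrix(unlist(lapply(strsplit(strsplit(row$intervals, ";")[[1]], "-"),
                               function(p) match(p, inst$dataset$marker_ids))),
                 nrow = 2)
    # convert absolute marker rows back to gene-local offsets
    for (i in seq_along(genes)) {
      iv[, i] <- iv[, i] - min(inst$dataset$gene_map[[genes[i]]]) + 1L
    }
    expect_identical(
      support_count(pattern_support(inst$dataset, genes, iv, enc)),
      row$support)
  }
  # support monotonicity along parent -> child edges
  sizes <- c(3L, 2L)
  geno <- matrix(sample(0:1, 5 * 40, replace = TRUE), 5, 40)
  ds <- fixture_dataset(geno, sample(0:1, 40, replace = TRUE),
                        list(gA = 1:3, gB = 4:5))
  frontier <- metaminer:::initial_ivals(sizes)
  pc <- function(iv) support_count(pattern_support(ds, c("gA", "gB"),
                                                   matrix(iv, 2), c("d", "d")))
  repeat {
    ch <- metaminer:::gen_children(frontier, sizes)
    if (length(ch$parent) == 0) break
    for (j in seq_along(ch$parent)) {
      expect_gte(pc(ch$ivals[, j]), pc(frontier[, ch$parent[j]]))
    }
    frontier <- ch$ivals
  }
})

test_that("a planted perfectly-associated marker is discovered", {
  set.seed(43)
  n <- 60
  geno <- matrix(sample(0:1, 3 * n, replace = TRUE, prob = c(0.7, 0.3)), 3, n)
  y <- geno[2, ]
  ds <- fixture_dataset(geno, y, list(g = 1:3))
  res <- mine(ds, as_interactions(list("g"), ds))
  expect_gt(nrow(res$significant), 0)
  expect_true(any(vapply(res$significant$marker_rows,
                         function(r) 2L %in% r, TRUE)))
})

test_that("random labels give an empty significant set on a tiny instance", {
  set.seed(44)
  geno <- matrix(sample(0:1, 4 * 40, replace = TRUE), 4, 40)
  y <- sample(0:1, 40, replace = TRUE)
  ds <- fixture_dataset(geno, y, list(gA = 1:2, gB = 3:4))
  res <- mine(ds, as_interactions(list("gA", "gB", c("gA", "gB")), ds))
  expect_identical(nrow(res$significant), 0L)
})

test_that("interactions with unmapped genes are skipped with a warning", {
  geno <- matrix(sample(0:1, 40, replace = TRUE), 2, 20)
  ds <- fixture_dataset(geno, rep(c(0L, 1L), 10), list(gA = 1:2))
  ints <- structure(list("gZ", "gA"), class = "mm_interactions")
  expect_warning(res <- mine(ds, ints), "skipped")
  expect_gt(res$counters$processed, 0)
})

test_that("the branch-and-bound miner matches the exhaustive oracle on tiny instances", {
  for (s in 1:8) {
    mode <- if (s %% 2 == 0) "additive" else "binary"
    inst <- random_tiny_instance(100 + s, mode)
    for (mth in c("tarone", "wy")) {
      r <- mine(inst$dataset, inst$interactions, fwer = mth, K = 25, seed = 9)
      o <- oracle_mine(inst$dataset, inst$interactions, fwer = mth, K = 25,
                       seed = 9)
      expect_equal(r$delta_final, o$delta_final, tolerance = 1e-12)
      expect_identical(r$significant$key, o$sig_keys)
    }
  }
})

test_that("pruning changes neither the threshold nor the discoveries", {
  for (s in c(3, 6, 9)) {
    inst <- random_tiny_instance(200 + s, if (s %% 2 == 0) "additive" else "binary")
    a <- mine(inst$dataset, inst$interactions, prune = TRUE)
    b <- mine(inst$dataset, inst$interactions, prune = FALSE)
    expect_equal(a$delta_final, b$delta_final, tolerance = 1e-12)
    expect_identical(a$significant$key, b$significant$key)
    expect_gte(b$counters$processed, a$counters$processed)
  }
})

test_that("the interval-length cap restricts enumeration accordingly", {
  set.seed(45)
  geno <- matrix(sample(0:1, 4 * 30, replace = TRUE), 4, 30)
  ds <- fixture_dataset(geno, sample(0:1, 30, replace = TRUE), list(g = 1:4))
  r <- mine(ds, as_interactions(list("g"), ds), prune = FALSE,
            max_interval_len = 2)
  # intervals of length 1 or 2 in a 4-marker gene: 4 + 3
  expect_identical(r$counters$processed, 7L)
})
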