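ranks_from <- function(score_rows) {
  rank_genes_per_cell(score_rows)
}

test_that("scores are euclidean norms with missing propagation", {
  vals <- array(NA_real_, c(2, 2, 2))
  vals[1, 1, ] <- c(3, 4)
  vals[1, 2, ] <- c(0, 0)
  d <- structure(
    list(values = vals, missing = rbind(c(FALSE, FALSE), c(TRUE, TRUE)),
         cell_ids = c("c1", "c2"), gene_ids = c("gA", "gB"),
         dim_names = c("DC1", "DC2"), k = 1L, metric = "euclidean"),
    class = "gene_differentials")
  s <- compute_scores(d)
  expect_equal(s["c1", "gA"], 5)
  expect_equal(s["c1", "gB"], 0)
  expect_true(all(is.na(s["c2", ])))
})

test_that("per-cell ranking is descending, min-rank for ties, compact over NA", {
  s <- rbind(c(0.2, 0.9, 0.5),
             c(0.7, 0.7, 0.1),
             c(NA, 0.3, 0.8))
  dimnames(s) <- list(paste0("c", 1:3), c("gA", "gB", "gC"))
  r <- ranks_from(s)
  expect_identical(unname(r[1, ]), c(3L, 1L, 2L))
  expect_identical(unname(r[2, ]), c(1L, 1L, 3L)) # tied top pair, next is 3
  expect_identical(unname(r[3, ]), c(NA_integer_, 2L, 1L))
})

test_that("local relevance implements the strict-inequality Iverson count", {
  r <- rbind(c(1L, 2L), c(1L, 2L), c(2L, 1L))
  dimnames(r) <- list(paste0("c", 1:3), c("gA", "gB"))
  # gene ranked 1 in every cell: LR = 1 for any cutoff >= 2
  expect_equal(local_relevance(r, 1:2, rank_cutoff = 2)[["gA"]], 1)
  # top-ranked in 2 of 3 cells at cutoff 2
  expect_equal(local_relevance(r, 1:3, rank_cutoff = 2)[["gA"]], 2 / 3)
  # rank exactly at the cutoff never counts under strict <
  expect_equal(local_relevance(r, 1:2, rank_cutoff = 2)[["gB"]], 0)
  expect_equal(local_relevance(r, 1:2, rank_cutoff = 2,
                               inclusive = TRUE)[["gB"]], 1)
  expect_error(local_relevance(r, integer(0), 2), "nonempty")
  # missing ranks count in the denominator, never the numerator
  r2 <- r; r2[1, 1] <- NA
  expect_equal(local_relevance(r2, 1:3, rank_cutoff = 2)[["gA"]], 1 / 3)
})

test_that("global relevance equals local relevance over all cells", {
  inst <- random_instance(21)
  res <- gene_relevance(inst$X, inst$S, k = 4, metric = "euclidean",
                        n_bins = c(3, 3))
  gr <- res$global$relevance
  lr_all <- local_relevance(res$ranks, seq_len(inst$C), 10)
  expect_identical(gr, lr_all)
  expect_true(all(gr >= 0 & gr <= 1))
  # single-cell set gives 0/1 values only
  lr1 <- local_relevance(res$ranks, 1L, 10)
  expect_true(all(lr1 %in% c(0, 1)))
})

test_that("raising the cutoff never decreases relevance", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 30)
    g <- build_knn(inst$X, k = 5, metric = "euclidean")
    d <- estimate_differentials(inst$X, inst$S, g)
    rk <- rank_genes_per_cell(compute_scores(d))
    prev <- local_relevance(rk, seq_len(inst$C), 2)
    for (cutoff in c(4, 7, 11)) {
      cur <- local_relevance(rk, seq_len(inst$C), cutoff)
      expect_true(all(cur >= prev - 1e-15))
      prev <- cur
    }
  }
})

test_that("relevance is invariant to monotone transforms of the scores", {
  inst <- random_instance(44, C = 18, G = 10)
  g <- build_knn(inst$X, k = 4, metric = "euclidean")
  sc <- compute_scores(estimate_differentials(inst$X, inst$S, g))
  r1 <- rank_genes_per_cell(sc)
  r2 <- rank_genes_per_cell(sqrt(sc) + log1p(sc)) # order-preserving
  expect_identical(r1, r2)
})

test_that("bin grids tile the bounding box with a right-closed last bin", {
  e <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  dimnames(e) <- list(paste0("c", 1:4), c("DC1", "DC2"))
  grid <- bin_embedding(e, c(2, 2))
  expect_identical(sort(paste(grid$bin_x, grid$bin_y)),
                   c("1 1", "1 2", "2 1", "2 2"))
  # the exact-max cell lands in the top-right bin, not out of range
  expect_identical(grid$bin_x[4], 2L)
  expect_identical(grid$bin_y[4], 2L)
  # degenerate: identical coordinates all share one bin
  e0 <- matrix(1, 3, 2, dimnames = list(paste0("c", 1:3), c("DC1", "DC2")))
  g0 <- bin_embedding(e0, c(4, 4))
  expect_true(all(g0$bin_x == 1L & g0$bin_y == 1L))
  expect_error(bin_embedding(e, c(0, 2)), ">= 1")
})

test_that("binned relevance reports counts, leaves empty bins undefined", {
  inst <- random_instance(55, C = 25, G = 8, P = 2)
  g <- build_knn(inst$X, k = 4, metric = "euclidean")
  rk <- rank_genes_per_cell(
    compute_scores(estimate_differentials(inst$X, inst$S, g)))
  grid <- bin_embedding(inst$S, c(4, 4))
  tab <- binned_local_relevance(rk, grid, rank_cutoff = 4)
  expect_identical(nrow(tab), as.integer(16 * inst$G))
  expect_true(all(is.na(tab$local_relevance[tab$n_cells == 0])))
  expect_false(anyNA(tab$local_relevance[tab$n_cells > 0]))
  # per-bin values agree with direct local relevance on the bin's cells
  one <- tab[tab$n_cells > 0, ][1, ]
  cells <- which(grid$bin_x == one$bin_x & grid$bin_y == one$bin_y)
  expect_equal(one$local_relevance,
               local_relevance(rk, cells, 4)[[one$gene]])
})

test_that("union of disjoint bins satisfies the weighted-mean identity", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 70, C = 24, G = 9)
    g <- build_knn(inst$X, k = 5, metric = "euclidean")
    rk <- rank_genes_per_cell(
      compute_scores(estimate_differentials(inst$X, inst$S, g)))
    cells_a <- 1:9
    cells_b <- 10:24
    lr_a <- local_relevance(rk, cells_a, 5)
    lr_b <- local_relevance(rk, cells_b, 5)
    lr_union <- local_relevance(rk, 1:24, 5)
    expect_equal(lr_union,
                 (9 * lr_a + 15 * lr_b) / 24, tolerance = 1e-12)
  }
})

test_that("per-cell relevance budget holds when ranks are distinct", {
  inst <- random_instance(91, C = 20, G = 12)
  g <- build_knn(inst$X, k = 5, metric = "euclidean")
  rk <- rank_genes_per_cell(
    compute_scores(estimate_differentials(inst$X, inst$S, g)))
  cutoff <- 6L
  for (ci in seq_len(nrow(rk))) {
    r <- rk[ci, ]
    defined <- r[!is.na(r)]
    if (anyDuplicated(defined)) next # budget identity assumes strict ranks
    expect_identical(sum(defined < cutoff),
                     min(cutoff - 1L, length(defined)))
  }
})
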