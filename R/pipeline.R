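#' Run the full gene relevance pipeline
#'
#' Chains the whole method: k-nearest-neighbor search in expression space
#' (unless a precomputed graph is supplied), median finite-difference
#' differentials with the dropout rule, per-cell scores and rankings, global
#' relevance, binned local relevance over a grid on the first two embedding
#' dimensions, and a smoothed gene relevance map over the globally most
#' relevant genes.
#'
#' @param expr Cells x genes expression matrix (library-size- and
#'   log-normalized expression expected), with cell row names and gene
#'   column names.
#' @param emb Cells x P embedding coordinate matrix, same cells in the same
#'   order (see [pair_inputs()]).
#' @param graph Optional precomputed `knn_graph`; otherwise built with
#'   [build_knn()].
#' @param k,metric Neighborhood parameters, passed to [build_knn()].
#' @param rank_cutoff Rank cutoff `rgmax` for local/global relevance
#'   (default 10) — also sizes the map gene pool unless `top_n` is given.
#' @param inclusive Use `<=` instead of the default strict `<` at the
#'   cutoff (see [local_relevance()]).
#' @param n_bins Bin grid for the local-relevance summaries, default 16x16.
#' @param smooth_m Smoothing steps for the relevance map (default 1).
#' @param gene_pool Explicit map gene pool; overrides selection by global
#'   relevance.
#' @param top_n Map pool size when selecting by global relevance; defaults
#'   to `rank_cutoff`.
#' @param drop_zero_neighbors Stricter dropout handling, see
#'   [estimate_differentials()].
#' @param quiet Suppress progress notes.
#' @return Object of class `gene_relevance`: list with `scores`, `ranks`,
#'   `differentials`, `global` (relevance vector + ranking data frame),
#'   `grid`, `binned`, `map`, `gene_pool`, `graph` and `params` (full
#'   provenance record).
#' @export
#' @examples
#' sim <- simulate_relevance_data(
#'   synthetic_spec(n_cells = 80, n_genes = 30, seed = 7))
#' res <- gene_relevance(sim$expression, sim$embedding, n_bins = c(4, 4))
#' head(res$global$ranking)
gene_relevance <- function(expr, emb, graph = NULL, k = NULL,
                           metric = c("spearman", "euclidean", "cosine"),
                           rank_cutoff = 10L, inclusive = FALSE,
                           n_bins = c(16L, 16L), smooth_m = 1L,
                           gene_pool = NULL, top_n = NULL,
                           drop_zero_neighbors = FALSE, quiet = TRUE) {
  metric <- match.arg(metric)
  check_expression(expr)
  check_embedding(emb)
  check_paired(expr, emb)
  if (is.null(graph)) {
    graph <- build_knn(expr, k = k, metric = metric)
  }
  diff <- estimate_differentials(expr, emb, graph,
                                 drop_zero_neighbors = drop_zero_neighbors,
                                 quiet = quiet)
  scores <- compute_scores(diff)
  ranks <- rank_genes_per_cell(scores)
  global <- global_relevance(ranks, rank_cutoff, inclusive)
  grid <- bin_embedding(emb, n_bins)
  pool <- gene_pool %||%
    select_gene_pool(global, rank_cutoff = rank_cutoff, n = top_n)
  binned <- binned_local_relevance(ranks, grid, rank_cutoff,
                                   genes = pool, inclusive = inclusive)
  map <- build_relevance_map(scores, graph, pool, m = smooth_m)
  params <- list(
    n_cells = nrow(expr), n_genes = ncol(expr), n_dims = ncol(emb),
    k = graph$k, metric = graph$metric, knn_source = graph$source,
    rank_cutoff = as.integer(rank_cutoff), inclusive = inclusive,
    n_bins = as.integer(if (length(n_bins) == 1L) rep(n_bins, 2L) else n_bins),
    smooth_m = as.integer(smooth_m),
    gene_pool = pool,
    drop_zero_neighbors = drop_zero_neighbors,
    na_fraction = mean(diff$missing),
    package_version = as.character(utils::packageVersion("generelevance"))
  )
  structure(
    list(scores = scores, ranks = ranks, differentials = diff,
         global = global, grid = grid, binned = binned, map = map,
         gene_pool = pool, graph = graph, params = params),
    class = "gene_relevance"
  )
}

#' @export
print.gene_relevance <- function(x, n = 10L, ...) {
  p <- x$params
  cat(sprintf(
    "gene_relevance: %d cells x %d genes, %d-D embedding (k = %d, %s)\n",
    p$n_cells, p$n_genes, p$n_dims, p$k, p$metric))
  cat(sprintf("  rank cutoff %d, %.1f%% of differentials undefined\n",
              p$rank_cutoff, 100 * p$na_fraction))
  cat("  top globally relevant genes:\n")
  top <- utils::head(x$global$ranking, n)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %-12s GR = %.3f\n",
                top$rank[i], top$gene[i], top$relevance[i]))
  }
  invisible(x)
}
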