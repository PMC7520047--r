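#' Select the gene pool for a relevance map
#'
#' The map labels each cell with its locally most relevant gene from a pool
#' \eqn{\Omega}, usually the globally most relevant genes.  The pool size is
#' governed by the rank cutoff (acting here as a sensitivity parameter:
#' larger cutoffs admit more genes) or by an explicit `n`.
#'
#' @param global Result of [global_relevance()] (or its `ranking` data
#'   frame).
#' @param rank_cutoff Pool size when `n` is not given.
#' @param n Explicit pool size, overriding `rank_cutoff`.
#' @return Character vector of gene ids, ordered by descending global
#'   relevance (ties lexicographic).
#' @export
select_gene_pool <- function(global, rank_cutoff = 10L, n = NULL) {
  ranking <- if (is.data.frame(global)) global else global$ranking
  size <- n %||% rank_cutoff
  if (size < 1L) {
    stop_("gene pool size must be >= 1")
  }
  utils::head(ranking$gene, size)
}

#' Initial relevance-map labels (no smoothing)
#'
#' Labels every cell with the pool gene attaining the highest relevance
#' score in that cell.  Ties go to the lexicographically smallest gene id;
#' cells where every pool gene is undefined stay unlabeled (`NA`).
#'
#' @param scores Cells x genes score matrix from [compute_scores()].
#' @param gene_pool Nonempty character vector of genes \eqn{\Omega}.
#' @return Object of class `relevance_map`: list with `labels` (per-cell
#'   gene id or `NA`), `m = 0`, `gene_pool`, `support` (`NA` until smoothed
#'   against a graph) and `cell_ids`.
#' @export
initial_labels <- function(scores, gene_pool) {
  if (!length(gene_pool)) {
    stop_("gene_pool must be nonempty")
  }
  missing_genes <- setdiff(gene_pool, colnames(scores))
  if (length(missing_genes)) {
    stop_("unknown genes in pool: ",
          paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  pool_sorted <- gene_pool[id_order(gene_pool)]
  sub <- scores[, pool_sorted, drop = FALSE]
  labels <- apply(sub, 1L, function(s) {
    if (all(is.na(s))) NA_character_ else pool_sorted[which.max(s)]
  })
  structure(
    list(labels = unname(labels), m = 0L, gene_pool = gene_pool,
         support = rep(NA_real_, nrow(scores)),
         cell_ids = rownames(scores)),
    class = "relevance_map"
  )
}

#' Smooth a relevance map by neighbor majority vote
#'
#' Each smoothing step replaces, for every cell, the per-gene value with the
#' fraction of its `k` out-neighbors currently carrying that gene as label,
#' then relabels the cell with the argmax gene (ties to the
#' lexicographically smallest id).  Updates are synchronous: every cell is
#' relabeled from the previous step's labels.  Unlabeled neighbors vote for
#' no gene; a cell with no labeled neighbor keeps its current label (or
#' stays unlabeled).  More smoothing steps `m` trade locality for
#' robustness: genes relevant only in a small region progressively vanish
#' from the map as `m` grows.
#'
#' After the last step the per-cell `support` is recomputed as the fraction
#' of the cell's `k` neighbors sharing its final label, so downstream plots
#' can fade uncertain regions.
#'
#' @param state `relevance_map` from [initial_labels()] (or a previous
#'   smoothing call).
#' @param graph `knn_graph` over the same cells.
#' @param steps Number of smoothing iterations (`steps = 0` leaves labels
#'   untouched and only fills in `support`).
#' @return A `relevance_map` with `m` increased by `steps`.
#' @export
smooth_map <- function(state, graph, steps = 1L) {
  if (steps < 0L) {
    stop_("steps must be >= 0")
  }
  if (nrow(graph$index) != length(state$labels)) {
    stop_("graph and map cover different cell counts")
  }
  pool_sorted <- state$gene_pool[id_order(state$gene_pool)]
  labels <- state$labels
  C <- length(labels)
  k <- graph$k
  for (s in seq_len(steps)) {
    prev <- labels
    for (ci in seq_len(C)) {
      nb <- prev[graph$index[ci, ]]
      nb <- nb[!is.na(nb)]
      if (length(nb)) {
        counts <- tabulate(match(nb, pool_sorted), length(pool_sorted))
        labels[ci] <- pool_sorted[which.max(counts)]
      } # else: keep previous label (possibly unlabeled)
    }
  }
  support <- vapply(seq_len(C), function(ci) {
    if (is.na(labels[ci])) {
      return(NA_real_)
    }
    nb <- labels[graph$index[ci, ]]
    sum(!is.na(nb) & nb == labels[ci]) / k
  }, numeric(1))
  structure(
    list(labels = labels, m = state$m + as.integer(steps),
         gene_pool = state$gene_pool, support = support,
         cell_ids = state$cell_ids),
    class = "relevance_map"
  )
}

#' Build a gene relevance map in one call
#'
#' Convenience wrapper: initial labels from the score matrix over a gene
#' pool, followed by `m` rounds of neighbor-majority smoothing.
#'
#' @inheritParams initial_labels
#' @inheritParams smooth_map
#' @param m Number of smoothing steps (default 1: removes single-cell
#'   speckle while preserving small coherent regions; `m = 0` for the raw
#'   argmax map).
#' @return A `relevance_map`.
#' @export
build_relevance_map <- function(scores, graph, gene_pool, m = 1L) {
  state <- initial_labels(scores, gene_pool)
  smooth_map(state, graph, steps = m)
}

#' @export
print.relevance_map <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("relevance_map: %d cells, m = %d, pool of %d genes\n",
              length(x$labels), x$m, length(x$gene_pool)))
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
  if (anyNA(x$labels)) {
    cat("  unlabeled cells:", sum(is.na(x$labels)), "\n")
  }
  invisible(x)
}
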