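#' Estimate per-cell gene differentials by median finite differences
#'
#' For every cell `c`, gene `g` and embedding dimension `p`, estimates the
#' partial derivative of expression with respect to the embedding coordinate
#' as the median finite-difference quotient over the cell's neighborhood:
#'
#' \deqn{(d_{gc})_p = \mathrm{median}_{n \in NN_k(c),\, n \ne c}
#'   \frac{x_{gc} - x_{gn}}{s_{pn} - s_{pc}}}
#'
#' To cope with dropout, the differential is left undefined (`NA`) wherever
#' the cell itself does not express the gene (`x_gc = 0`).  Note the quotient
#' as defined above equals the negative of the forward-difference slope; the
#' sign is irrelevant to the relevance scores (which take norms), and
#' [expression_change_field()] can flip it for plotting.
#'
#' Neighbors sharing a coordinate with the cell (`s_pn = s_pc`) are excluded
#' from that dimension's median to avoid infinite quotients; if every
#' neighbor is excluded for some dimension the whole differential for that
#' (cell, gene) is marked missing.
#'
#' @param expr Cells x genes expression matrix (dense or sparse), row and
#'   column names required.
#' @param emb Cells x P embedding coordinate matrix, same cell order.
#' @param graph `knn_graph` over the same cells (see [build_knn()]).
#' @param drop_zero_neighbors If `TRUE`, neighbors with `x_gn = 0` are also
#'   excluded from the median (a stricter dropout rule).  Default `FALSE`:
#'   only `x_gc = 0` triggers missingness.
#' @param quiet Suppress the note about genes undefined in every cell.
#' @return An object of class `gene_differentials`: list with `values`
#'   (cells x genes x P array, `NA` where undefined), `missing` (cells x
#'   genes logical), `cell_ids`, `gene_ids`, `dim_names`, and the `k` and
#'   `metric` used.
#' @export
#' @examples
#' s <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(paste0("c", 1:3), "DC1"))
#' x <- matrix(s[, 1] + 0.5, ncol = 1,
#'   dimnames = list(rownames(s), "geneA"))
#' g <- import_knn(rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
#' d <- estimate_differentials(x, s, g)
#' d$values[, , 1] # -1 for every cell: x = s + 0.5 has slope 1
estimate_differentials <- function(expr, emb, graph,
                                   drop_zero_neighbors = FALSE,
                                   quiet = FALSE) {
  check_expression(expr)
  check_embedding(emb)
  check_paired(expr, emb)
  if (nrow(graph$index) != nrow(expr)) {
    stop_("neighbor graph covers ", nrow(graph$index),
          " cells but expression has ", nrow(expr))
  }
  C <- nrow(expr)
  G <- ncol(expr)
  P <- ncol(emb)
  vals <- array(NA_real_, dim = c(C, G, P))
  S <- as.matrix(emb)
  for (ci in seq_len(C)) {
    nn <- graph$index[ci, ]
    xn <- as.matrix(expr[nn, , drop = FALSE]) # k x G
    xc <- as.numeric(expr[ci, ])
    dx <- sweep(-xn, 2L, xc, `+`) # x_gc - x_gn
    if (drop_zero_neighbors) {
      dx[xn == 0] <- NA_real_
    }
    for (p in seq_len(P)) {
      ds <- S[nn, p] - S[ci, p] # s_pn - s_pc
      q <- dx / ds # recycles ds down each gene column
      q[ds == 0, ] <- NA_real_
      vals[ci, , p] <- apply(q, 2L, median_defined)
    }
  }
  # Dropout rule: undefined wherever the cell itself is silent; and a
  # differential with any undefined component is wholly undefined.
  zero <- as.matrix(expr == 0)
  miss <- zero
  for (p in seq_len(P)) {
    miss <- miss | is.na(vals[, , p, drop = TRUE])
  }
  for (p in seq_len(P)) {
    v <- vals[, , p, drop = TRUE]
    v[miss] <- NA_real_
    vals[, , p] <- v
  }
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing) && !quiet) {
    message(sum(all_missing),
            " gene(s) have no defined differential in any cell")
  }
  dimnames(vals) <- list(rownames(expr), colnames(expr), colnames(emb))
  structure(
    list(values = vals, missing = miss,
         cell_ids = rownames(expr), gene_ids = colnames(expr),
         dim_names = colnames(emb) %||% paste0("DC", seq_len(P)),
         k = graph$k, metric = graph$metric),
    class = "gene_differentials"
  )
}

#' Extract one gene's expression-change field
#'
#' Returns the per-cell differential vectors of a single gene as a data
#' frame, suitable for arrow/overlay plots on the embedding.  By default the
#' values carry the sign produced by the finite-difference definition (the
#' negative of the forward slope, see [estimate_differentials()]);
#' `orient_forward = TRUE` negates them so arrows point in the direction of
#' increasing expression.
#'
#' @param diff `gene_differentials` object.
#' @param gene Gene id (must exist).
#' @param orient_forward Negate the field for intuitive plotting.
#' @return Data frame with `cell_id`, one column per embedding dimension,
#'   and a logical `missing` column; cell order matches the embedding.
#' @export
expression_change_field <- function(diff, gene, orient_forward = FALSE) {
  gi <- match(gene, diff$gene_ids)
  if (is.na(gi)) {
    stop_("unknown gene: ", gene)
  }
  v <- diff$values[, gi, , drop = TRUE]
  if (is.null(dim(v))) {
    v <- matrix(v, ncol = length(diff$dim_names))
  }
  if (orient_forward) {
    v <- -v
  }
  colnames(v) <- diff$dim_names
  out <- data.frame(cell_id = diff$cell_ids, v,
                    missing = diff$missing[, gi],
                    row.names = NULL, check.names = FALSE)
  out
}

#' @export
print.gene_differentials <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "gene_differentials: %d cells x %d genes x %d dims (%.1f%% undefined)\n",
    d[1L], d[2L], d[3L], 100 * mean(x$missing)))
  invisible(x)
}
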