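#' Build a k-nearest-neighbor graph in expression space
#'
#' Finds, for every cell, the `k` cells minimizing the chosen distance in
#' gene expression space.  The graph is directed (each cell points to its own
#' neighbors) and never contains self-edges.  Distance ties at the k-th
#' neighbor are broken by ascending cell index so results are deterministic.
#'
#' Supported distances:
#' \describe{
#'   \item{spearman}{`1 - rho` where `rho` is the Pearson correlation of the
#'     per-cell expression rank vectors (average ranks for ties).  Invariant
#'     to strictly monotone per-cell transforms of expression; the default,
#'     and the usual choice for zero-inflated single-cell data.}
#'   \item{euclidean}{Plain euclidean distance between expression vectors.}
#'   \item{cosine}{`1 - cos(angle)`; invariant to per-cell positive scaling.}
#' }
#'
#' The default `k` is `min(C - 1, max(10, round(sqrt(C))))` for `C` cells:
#' square-root scaling keeps neighborhoods local as datasets grow while the
#' floor of 10 keeps the median-based differential estimates stable.
#'
#' @param expr Cells x genes matrix (dense or `Matrix` sparse) with row and
#'   column names.
#' @param k Number of neighbors per cell, `1 <= k < C`.  Default as above.
#' @param metric One of `"spearman"`, `"euclidean"`, `"cosine"`.
#' @return An object of class `knn_graph`: list with `k`, `index` (cells x k
#'   integer matrix of 1-based cell indices), `metric`, `source`
#'   (`"computed"` or `"imported"`) and `cell_ids`.
#' @seealso [import_knn()] to reuse a neighbor search performed elsewhere
#'   (e.g. during embedding construction).
#' @export
#' @examples
#' x <- matrix(runif(40), 8, 5,
#'   dimnames = list(paste0("c", 1:8), paste0("g", 1:5)))
#' g <- build_knn(x, k = 3, metric = "euclidean")
#' g$index
build_knn <- function(expr, k = NULL,
                      metric = c("spearman", "euclidean", "cosine")) {
  metric <- match.arg(metric)
  check_expression(expr)
  X <- as.matrix(expr)
  C <- nrow(X)
  k <- k %||% default_k(C)
  k <- as.integer(k)
  if (k < 1L || k >= C) {
    stop_("k must satisfy 1 <= k < number of cells (got k=", k, ", C=", C, ")")
  }
  # Distances are compared after rounding to 12 significant digits: exact
  # mathematical ties (frequent for rank-based distances on zero-inflated
  # data) then break by ascending cell index regardless of floating-point
  # accumulation order.
  D <- signif(pairwise_distances(X, metric), 12)
  index <- matrix(0L, C, k)
  for (i in seq_len(C)) {
    d <- D[i, ]
    d[i] <- Inf
    o <- order(d, seq_len(C)) # stable: ties by ascending cell index
    index[i, ] <- o[seq_len(k)]
  }
  new_knn_graph(k, index, metric, "computed", rownames(X))
}

#' Import a precomputed k-nearest-neighbor graph
#'
#' Accepts a neighbor index computed elsewhere (for instance during the
#' embedding itself) after validating the graph invariants: no self-edges,
#' all indices in range, no duplicate neighbor within a row, `k < C`.
#'
#' @param neighbor_index Cells x k integer matrix of 1-based cell indices.
#' @param cell_ids Optional character vector of cell ids (row order).
#' @param metric Label recorded for provenance; distances are not
#'   recomputed.
#' @return A `knn_graph` with `source = "imported"`.
#' @export
import_knn <- function(neighbor_index, cell_ids = NULL, metric = "imported") {
  idx <- as.matrix(neighbor_index)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  C <- nrow(idx)
  k <- ncol(idx)
  if (anyNA(idx)) {
    stop_("neighbor index contains missing values")
  }
  if (k >= C) {
    stop_("k (", k, ") must be smaller than the number of cells (", C, ")")
  }
  if (any(idx < 1L) || any(idx > C)) {
    bad <- which(rowSums(idx < 1L | idx > C) > 0L)
    stop_("neighbor indices out of range in rows: ",
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  self <- which(idx == row(idx), arr.ind = TRUE)
  if (nrow(self)) {
    stop_("cells listed as their own neighbor in rows: ",
          paste(utils::head(unique(self[, 1L]), 10L), collapse = ", "))
  }
  dup <- which(apply(idx, 1L, anyDuplicated) > 0L)
  if (length(dup)) {
    stop_("duplicate neighbors within rows: ",
          paste(utils::head(dup, 10L), collapse = ", "))
  }
  new_knn_graph(k, idx, metric, "imported", cell_ids)
}

new_knn_graph <- function(k, index, metric, source, cell_ids = NULL) {
  structure(
    list(k = k, index = index, metric = metric, source = source,
         cell_ids = cell_ids),
    class = "knn_graph"
  )
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d cells, k = %d, metric = %s (%s)\n",
              nrow(x$index), x$k, x$metric, x$source))
  invisible(x)
}

default_k <- function(C) {
  min(C - 1L, max(10L, as.integer(round(sqrt(C)))))
}

# Full pairwise distance matrix; fine for the tens of thousands of cells the
# method targets since C x C doubles dominate, not C x C x G work.
pairwise_distances <- function(X, metric) {
  switch(metric,
    euclidean = as.matrix(stats::dist(X)),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      zero <- which(nrm == 0)
      if (length(zero)) {
        stop_("cosine distance undefined for all-zero expression vectors, ",
              "cells: ", paste(name_or_index(X, zero), collapse = ", "))
      }
      d <- 1 - tcrossprod(X / nrm)
      diag(d) <- 0
      d
    },
    spearman = {
      R <- t(apply(X, 1L, rank)) # average ranks for ties
      if (nrow(R) != nrow(X)) R <- t(R) # guards the single-gene edge case
      ctr <- R - rowMeans(R)
      ss <- sqrt(rowSums(ctr^2))
      flat <- which(ss == 0)
      if (length(flat)) {
        stop_("spearman distance undefined for constant expression vectors, ",
              "cells: ", paste(name_or_index(X, flat), collapse = ", "))
      }
      d <- 1 - tcrossprod(ctr / ss)
      diag(d) <- 0
      d
    }
  )
}

name_or_index <- function(X, i) {
  if (is.null(rownames(X))) as.character(i) else rownames(X)[i]
}
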