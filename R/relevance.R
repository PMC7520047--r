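#' Per-cell gene relevance scores
#'
#' The relevance score of gene `g` in cell `c` is the euclidean norm of its
#' differential, \eqn{\|d_{gc}\|_2 = \sqrt{\sum_p (d_{gc})_p^2}}: how much
#' the gene's expression changes per unit displacement in the embedding
#' around that cell.  Missing differentials yield missing scores.
#'
#' @param diff `gene_differentials` from [estimate_differentials()].
#' @return Cells x genes numeric matrix of scores, `NA` where undefined.
#' @export
compute_scores <- function(diff) {
  P <- dim(diff$values)[3L]
  acc <- diff$values[, , 1L, drop = TRUE]^2
  if (is.null(dim(acc))) {
    acc <- matrix(acc, nrow = length(diff$cell_ids))
  }
  if (P > 1L) {
    for (p in 2L:P) {
      v <- diff$values[, , p, drop = TRUE]
      if (is.null(dim(v))) v <- matrix(v, nrow = length(diff$cell_ids))
      acc <- acc + v^2
    }
  }
  s <- sqrt(acc)
  dimnames(s) <- list(diff$cell_ids, diff$gene_ids)
  s
}

#' Rank genes within each cell by relevance score
#'
#' Higher scores get smaller rank numbers (rank 1 = most relevant).  Ties
#' share the better rank (min/competition ranking); genes with a missing
#' score in a cell are excluded from that cell's ranking entirely and carry
#' a missing rank, with the remaining genes ranked compactly.
#'
#' @param scores Cells x genes score matrix from [compute_scores()].
#' @return Cells x genes integer matrix of ranks (`NA` where undefined).
#' @export
rank_genes_per_cell <- function(scores) {
  ranks <- t(apply(scores, 1L, rank_one_cell))
  if (nrow(ranks) != nrow(scores)) ranks <- t(ranks) # single-gene edge case
  dimnames(ranks) <- dimnames(scores)
  storage.mode(ranks) <- "integer"
  ranks
}

rank_one_cell <- function(s) {
  r <- rep(NA_integer_, length(s))
  ok <- !is.na(s)
  if (any(ok)) {
    r[ok] <- as.integer(rank(-s[ok], ties.method = "min"))
  }
  r
}

#' Local gene relevance for a set of cells
#'
#' The local relevance of gene `g` for a cell set \eqn{\Psi} is the fraction
#' of cells in \eqn{\Psi} where the gene ranks above the cutoff:
#' \deqn{LR_{r_{gmax}}(g, \Psi) = \frac{\sum_{c \in \Psi}
#'   [\, r_g^{(c)} < r_{gmax} \,]}{|\Psi|}}
#' using the Iverson bracket.  The inequality is strict by default (so
#' `rank_cutoff = 10` counts ranks 1-9); some descriptions read the cutoff
#' inclusively ("among the 10 most relevant genes") — set
#' `inclusive = TRUE` for that variant.  Missing ranks never count in the
#' numerator but their cells still count in \eqn{|\Psi|}.
#'
#' @param ranks Cells x genes rank matrix from [rank_genes_per_cell()].
#' @param cells Integer indices (or logical mask, or cell id characters)
#'   selecting the nonempty cell set \eqn{\Psi}.
#' @param rank_cutoff Positive integer rank cutoff (default 10).
#' @param inclusive Count ranks `<= rank_cutoff` instead of `<`.
#' @return Named numeric vector of per-gene relevance values in \[0, 1\].
#' @export
local_relevance <- function(ranks, cells, rank_cutoff = 10L,
                            inclusive = FALSE) {
  if (is.character(cells)) {
    cells <- match(cells, rownames(ranks))
    if (anyNA(cells)) stop_("unknown cell ids in `cells`")
  }
  if (is.logical(cells)) {
    cells <- which(cells)
  }
  if (!length(cells)) {
    stop_("the cell set must be nonempty")
  }
  if (rank_cutoff < 1L) {
    stop_("rank_cutoff must be >= 1")
  }
  sub <- ranks[cells, , drop = FALSE]
  hit <- if (inclusive) sub <= rank_cutoff else sub < rank_cutoff
  hit[is.na(hit)] <- FALSE
  colSums(hit) / length(cells)
}

#' Global gene relevance
#'
#' Global relevance is local relevance evaluated over the set of all cells.
#' Also returns the global ranking as a data frame, ordered by descending
#' relevance with ties broken by lexicographic gene id.
#'
#' @inheritParams local_relevance
#' @return List with `relevance` (named per-gene vector) and `ranking`
#'   (data frame `gene`, `relevance`, `rank` with `rank = 1` the most
#'   globally relevant gene).
#' @export
global_relevance <- function(ranks, rank_cutoff = 10L, inclusive = FALSE) {
  gr <- local_relevance(ranks, seq_len(nrow(ranks)), rank_cutoff, inclusive)
  genes <- colnames(ranks)
  o <- order(-gr, genes, method = "radix")
  ranking <- data.frame(
    gene = genes[o],
    relevance = unname(gr[o]),
    rank = seq_along(o),
    stringsAsFactors = FALSE
  )
  list(relevance = gr, ranking = ranking)
}

#' Divide the embedding into a regular bin grid
#'
#' Tiles the bounding box of the first two embedding dimensions (or a single
#' dimension when `P = 1`) with equal-width bins.  Bins are left-closed; the
#' final bin is right-closed so cells sitting exactly on the maximum
#' coordinate are kept.  Dimensions beyond the second are ignored for
#' binning (they still contribute to scores upstream).
#'
#' @param emb Cells x P embedding matrix.
#' @param n_bins Integer vector of length 1 or 2: bins along x (and y).
#'   Default `c(16, 16)`.
#' @return Object of class `bin_grid`: list with `n_bins_x`, `n_bins_y`,
#'   `edges_x`, `edges_y` (`NULL` in 1-D), and per-cell integer vectors
#'   `bin_x`, `bin_y` (`bin_y` all 1 in 1-D).
#' @export
bin_embedding <- function(emb, n_bins = c(16L, 16L)) {
  check_embedding(emb)
  if (any(n_bins < 1L)) {
    stop_("n_bins must be >= 1")
  }
  P <- ncol(emb)
  nx <- as.integer(n_bins[1L])
  ny <- if (length(n_bins) >= 2L) as.integer(n_bins[2L]) else nx
  ax <- assign_axis_bins(emb[, 1L], nx)
  if (P >= 2L) {
    ay <- assign_axis_bins(emb[, 2L], ny)
  } else {
    ny <- 1L
    ay <- list(edges = NULL, bin = rep(1L, nrow(emb)))
  }
  structure(
    list(n_bins_x = nx, n_bins_y = ny,
         edges_x = ax$edges, edges_y = ay$edges,
         bin_x = ax$bin, bin_y = ay$bin,
         cell_ids = rownames(emb)),
    class = "bin_grid"
  )
}

assign_axis_bins <- function(x, nb) {
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) {
    # Degenerate axis: everything in the first bin; edges span a unit width
    # so they remain strictly increasing.
    return(list(edges = seq(lo, lo + 1, length.out = nb + 1L),
                bin = rep(1L, length(x))))
  }
  edges <- seq(lo, hi, length.out = nb + 1L)
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), nb)
  list(edges = edges, bin = as.integer(b))
}

#' Binned local gene relevance
#'
#' Computes local relevance per gene for the cells falling into each bin of
#' a grid over the embedding — the data behind local-relevance tile plots.
#' Cell counts are reported per bin so plots can fade sparsely populated
#' bins; empty bins are reported with count 0 and an undefined (`NA`)
#' relevance rather than 0.
#'
#' @inheritParams local_relevance
#' @param grid `bin_grid` from [bin_embedding()] over the same cells.
#' @param genes Optional character vector restricting the genes reported.
#' @return Data frame `bin_x`, `bin_y`, `n_cells`, `gene`,
#'   `local_relevance`, ordered by bin then descending relevance (ties by
#'   gene id).
#' @export
binned_local_relevance <- function(ranks, grid, rank_cutoff = 10L,
                                   genes = NULL, inclusive = FALSE) {
  if (length(grid$bin_x) != nrow(ranks)) {
    stop_("bin grid and rank matrix cover different cell counts")
  }
  genes <- genes %||% colnames(ranks)
  missing_genes <- setdiff(genes, colnames(ranks))
  if (length(missing_genes)) {
    stop_("unknown genes: ", paste(utils::head(missing_genes, 5L),
                                   collapse = ", "))
  }
  sub <- ranks[, genes, drop = FALSE]
  out <- vector("list", grid$n_bins_x * grid$n_bins_y)
  i <- 0L
  for (by in seq_len(grid$n_bins_y)) {
    for (bx in seq_len(grid$n_bins_x)) {
      i <- i + 1L
      cells <- which(grid$bin_x == bx & grid$bin_y == by)
      if (length(cells)) {
        lr <- local_relevance(sub, cells, rank_cutoff, inclusive)
      } else {
        lr <- rep(NA_real_, length(genes))
        names(lr) <- genes
      }
      o <- order(-lr, genes, method = "radix", na.last = TRUE)
      out[[i]] <- data.frame(
        bin_x = bx, bin_y = by, n_cells = length(cells),
        gene = genes[o], local_relevance = unname(lr[o]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
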