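#' Read an expression matrix from CSV/TSV or MatrixMarket
#'
#' Reads a cells x genes expression matrix from a delimited text file (first
#' column or row names = ids, header row = the other axis' ids) or from
#' MatrixMarket coordinate format with sidecar newline-delimited gene and
#' cell name files.  Whatever the on-disk orientation, the returned matrix
#' is cells x genes.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param orientation How the file is laid out: `"cells_by_genes"` (rows are
#'   cells) or `"genes_by_cells"` (rows are genes, transposed on read).
#' @param genes_file,cells_file Sidecar name files for MatrixMarket input;
#'   default `<path without .mtx>_genes.txt` / `_cells.txt`.
#' @param max_dense Sparse input is densified when it has at most this many
#'   entries, otherwise kept as a `Matrix` sparse matrix (downstream
#'   computations densify only the k+1 cells of each neighborhood).
#' @return Cells x genes numeric matrix (or sparse `Matrix`) with cell row
#'   names and gene column names; values validated non-negative and free of
#'   NA.
#' @export
read_expression <- function(path,
                            format = c("auto", "csv", "tsv", "mtx"),
                            orientation = c("cells_by_genes",
                                            "genes_by_cells"),
                            genes_file = NULL, cells_file = NULL,
                            max_dense = 5e7) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop_("file not found: ", path)
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop_("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    base <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(base, "_genes.txt")
    cells_file <- cells_file %||% paste0(base, "_cells.txt")
    for (f in c(genes_file, cells_file)) {
      if (!file.exists(f)) stop_("sidecar name file not found: ", f)
    }
    m <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (orientation == "genes_by_cells") {
      m <- Matrix::t(m)
    }
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop_("matrix is ", nrow(m), " x ", ncol(m), " after orientation but ",
            length(cells), " cell and ", length(genes),
            " gene names were supplied")
    }
    dimnames(m) <- list(cells, genes)
    if (length(m) <= max_dense) {
      m <- as.matrix(m)
    } else {
      m <- methods::as(m, "CsparseMatrix")
    }
    check_expression(m)
    return(m)
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- read_id_table(path, sep)
  m <- tab$values
  rownames(m) <- tab$ids
  if (anyNA(m)) {
    stop_("expression table contains missing or non-numeric entries")
  }
  if (orientation == "genes_by_cells") {
    m <- t(m)
  }
  check_expression(m)
  m
}

# Parse a delimited table whose first column (or row-name column) holds ids
# and whose header names the remaining columns.  Returns ids + numeric
# matrix (non-numeric text becomes NA, reported via `bad`), tolerating both
# "id column named in header" and "R-style header one field short" layouts.
# Column names are taken before subsetting: data-frame subsetting would
# silently uniquify duplicated ids we need to detect.
read_id_table <- function(path, sep) {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) >= 1L && !is.numeric(tab[[1L]])) {
    ids <- as.character(tab[[1L]])
    cn <- colnames(tab)[-1L]
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    colnames(vals) <- cn
  } else {
    ids <- rownames(tab)
    vals <- as.matrix(tab)
  }
  num <- suppressWarnings(
    matrix(as.numeric(vals), nrow(vals), ncol(vals),
           dimnames = dimnames(vals)))
  list(ids = ids, values = num, bad = which(is.na(num), arr.ind = TRUE))
}

#' Read an embedding coordinate table
#'
#' Reads a cells x P table (CSV or TSV by extension; first column = cell
#' id).  Dimension names come from the header, or `DC1..DCP` when absent.
#' Row order is preserved.
#'
#' @param path File path.
#' @return Cells x P numeric matrix with cell row names.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) {
    stop_("file not found: ", path)
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- read_id_table(path, sep)
  m <- tab$values
  if (ncol(m) < 1L) {
    stop_("embedding table has no coordinate columns")
  }
  bad <- tab$bad
  if (nrow(bad)) {
    stop_(sprintf(
      "non-numeric coordinate at row %d, column %d of %s",
      bad[1L, 1L], bad[1L, 2L], path))
  }
  rownames(m) <- tab$ids
  if (is.null(colnames(m)) || !any(nzchar(colnames(m)))) {
    colnames(m) <- paste0("DC", seq_len(ncol(m)))
  }
  check_embedding(m)
  m
}

#' Pair an expression matrix with an embedding
#'
#' Verifies that cell ids agree in content and order; with
#' `reorder = TRUE`, reorders the embedding rows to match the expression
#' matrix by name instead (the sets must still coincide).  Silent positional
#' mismatch being the most dangerous failure mode, matching is by exact
#' string equality — never positional.
#'
#' @param expr Cells x genes expression matrix.
#' @param emb Cells x P embedding matrix.
#' @param reorder Match by name and reorder `emb` if orders differ.
#' @return The (possibly reordered) embedding, invisibly checked against
#'   `expr`.
#' @export
pair_inputs <- function(expr, emb, reorder = FALSE) {
  if (reorder) {
    if (!setequal(rownames(expr), rownames(emb))) {
      stop_("expression and embedding cover different cell sets")
    }
    emb <- emb[rownames(expr), , drop = FALSE]
  }
  check_paired(expr, emb)
  emb
}

#' Read / write a neighbor graph as headerless TSV
#'
#' On disk a neighbor graph is a headerless TSV with one row per cell (in
#' cell order) and `k` 0-based neighbor indices per row.
#'
#' @param path File path.
#' @param cell_ids Optional cell ids attached to the imported graph.
#' @return `read_knn_file`: a validated `knn_graph` (source `"imported"`).
#' @export
read_knn_file <- function(path, cell_ids = NULL) {
  idx <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  import_knn(idx + 1L, cell_ids = cell_ids)
}

#' @rdname read_knn_file
#' @param graph `knn_graph` to write.
#' @export
write_knn_file <- function(graph, path) {
  utils::write.table(graph$index - 1L, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write all relevance result tables
#'
#' Writes, into `out_dir`:
#' \describe{
#'   \item{global_relevance.tsv}{`gene`, `global_relevance`, `rank` —
#'     descending relevance, ties by lexicographic gene id.}
#'   \item{local_relevance_bins.tsv}{`bin_x`, `bin_y`, `n_cells`, `gene`,
#'     `local_relevance` (long format; empty bins have count 0 and `NA`
#'     relevance).}
#'   \item{relevance_map.tsv}{`cell_id`, `most_relevant_gene`, `support`,
#'     `m`.}
#'   \item{params.json}{full parameter/provenance record.}
#' }
#' Numbers are written at full precision (R's 15-significant-digit default,
#' `.` decimal separator) so a read-back reproduces values exactly to the
#' printed precision.
#'
#' @param result A `gene_relevance` result (see [gene_relevance()]).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector manifest of the written files.
#' @export
write_relevance_tables <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_("cannot create output directory: ", out_dir)
  }
  paths <- c(
    global = file.path(out_dir, "global_relevance.tsv"),
    bins = file.path(out_dir, "local_relevance_bins.tsv"),
    map = file.path(out_dir, "relevance_map.tsv"),
    params = file.path(out_dir, "params.json")
  )
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
  }
  ranking <- result$global$ranking
  colnames(ranking) <- c("gene", "global_relevance", "rank")
  write_tsv(ranking, paths[["global"]])
  write_tsv(result$binned, paths[["bins"]])
  map <- result$map
  map_df <- data.frame(
    cell_id = map$cell_ids %||% seq_along(map$labels),
    most_relevant_gene = ifelse(is.na(map$labels), "NA", map$labels),
    support = map$support,
    m = map$m,
    stringsAsFactors = FALSE
  )
  write_tsv(map_df, paths[["map"]])
  jsonlite::write_json(result$params, paths[["params"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths
}
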