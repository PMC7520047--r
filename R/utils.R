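# Internal helpers shared across modules.

# Locale-independent (byte-order) ordering for gene/cell ids, so tie-breaking
# is reproducible across systems.
id_order <- function(ids, decreasing = FALSE) {
  order(ids, method = "radix", decreasing = decreasing)
}

# Index of the maximum of `values`; ties broken by the lexicographically
# smallest of `ids` (C-locale).  NA values never win; returns NA_integer_ if
# everything is NA.
argmax_lex <- function(values, ids) {
  ok <- !is.na(values)
  if (!any(ok)) {
    return(NA_integer_)
  }
  m <- max(values[ok])
  cand <- which(ok & values == m)
  if (length(cand) == 1L) {
    return(cand)
  }
  cand[id_order(ids[cand])[1L]]
}

# Median over the non-NA entries; NA_real_ if none remain.
median_defined <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(NA_real_)
  }
  stats::median(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

# Validate a cells x genes expression matrix (dense or Matrix sparse).
check_expression <- function(expr) {
  if (length(dim(expr)) != 2L) {
    stop_("expression must be a cells x genes matrix")
  }
  cell_ids <- rownames(expr)
  gene_ids <- colnames(expr)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop_("expression matrix must carry cell (row) and gene (column) names")
  }
  check_unique(cell_ids, "cell")
  check_unique(gene_ids, "gene")
  v <- if (inherits(expr, "Matrix")) expr@x else expr
  if (anyNA(v)) {
    stop_("expression matrix contains NA/NaN values")
  }
  if (any(v < 0)) {
    stop_("expression matrix contains negative values")
  }
  invisible(expr)
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_(
      "duplicate ", what, " ids: ",
      paste(utils::head(dup, 5L), collapse = ", "),
      if (length(dup) > 5L) sprintf(" (and %d more)", length(dup) - 5L)
    )
  }
  invisible(ids)
}

# Validate an embedding matrix and its pairing with an expression matrix.
check_embedding <- function(emb) {
  if (length(dim(emb)) != 2L || ncol(emb) < 1L) {
    stop_("embedding must be a cells x P matrix with P >= 1")
  }
  if (!all(is.finite(emb))) {
    stop_("embedding contains non-finite values")
  }
  invisible(emb)
}

check_paired <- function(expr, emb) {
  if (nrow(expr) != nrow(emb)) {
    stop_(
      "expression (", nrow(expr), " cells) and embedding (", nrow(emb),
      " cells) disagree in cell count"
    )
  }
  re <- rownames(expr)
  rm_ <- rownames(emb)
  if (!is.null(re) && !is.null(rm_) && !identical(re, rm_)) {
    stop_(
      "cell ids of expression and embedding differ in content or order; ",
      "use pair_inputs(reorder = TRUE) to match by name"
    )
  }
  invisible(TRUE)
}
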