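#' Describe a planted gene for the synthetic generator
#'
#' @param gene Integer index of the gene to plant (within `n_genes`).
#' @param region `"all"` (whole embedding), `"branch1"`/`"branch2"` (the
#'   post-bifurcation arms of the two-branch layout), or a numeric interval
#'   `c(lo, hi)` on the latent position in \[0, 1\].
#' @param effect `"linear"` or `"sigmoid"` shape of expression along the
#'   region-relative position.
#' @param slope Effect magnitude: expression rises by `slope` across the
#'   region (for the sigmoid, `slope` is the plateau height).
#' @return A `planted_gene` descriptor list.
#' @export
planted_gene <- function(gene, region = "all",
                         effect = c("linear", "sigmoid"), slope = 1) {
  effect <- match.arg(effect)
  if (is.numeric(region)) {
    if (length(region) != 2L || region[1L] >= region[2L]) {
      stop_("numeric region must be an interval c(lo, hi) with lo < hi")
    }
  } else if (!region %in% c("all", "branch1", "branch2")) {
    stop_("region must be 'all', 'branch1', 'branch2' or an interval")
  }
  if (slope <= 0) {
    stop_("slope must be positive")
  }
  structure(list(gene = as.integer(gene), region = region,
                 effect = effect, slope = slope),
            class = "planted_gene")
}

#' Specification for a synthetic relevance benchmark
#'
#' Describes a reproducible synthetic dataset: cells on a low-dimensional
#' latent layout, planted genes whose expression is a smooth (linear or
#' sigmoidal) function of latent position in all or part of the cells,
#' pure-noise genes elsewhere, gaussian noise, zero-clipping and independent
#' dropout.  Defaults define the package's standard benchmark: 300 cells and
#' 200 genes on a Y-shaped two-branch layout with five planted genes — four
#' across the whole embedding (two linear, two sigmoidal) and one
#' restricted to the second branch — slope 1.0, noise sd 0.3 (so effect
#' size is about 3.3x the noise), baseline 1.0 and 20\% dropout, a regime
#' comparable to log-normalized plate-based single-cell data after
#' highly-variable-gene selection.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param embedding_kind `"two_branches"` (Y-shaped bifurcation, P = 2),
#'   `"line"` (1-D trajectory, P = 1) or `"grid"` (uniform square, P = 2).
#' @param planted_genes List of [planted_gene()] descriptors; `NULL` for
#'   the default set described above (adapted to the layout: on non-branch
#'   layouts the region-restricted gene uses the interval `c(0.5, 1)`).
#' @param dropout_rate Probability in \[0, 1) of zeroing any entry.
#' @param noise_sd Gaussian noise standard deviation (expression units).
#' @param baseline Mean expression of unaffected entries.
#' @param coord_jitter_sd Gaussian jitter on embedding coordinates, making
#'   the observed embedding an imperfect image of the latent position.
#' @param count_mode If `TRUE`, expression is generated as
#'   `log1p(Poisson(scale * value))` counts instead of the continuous
#'   log-like scale.
#' @param count_scale Poisson scale used in count mode.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 300L, n_genes = 200L,
                           embedding_kind = c("two_branches", "line", "grid"),
                           planted_genes = NULL,
                           dropout_rate = 0.2, noise_sd = 0.3,
                           baseline = 1, coord_jitter_sd = 0.01,
                           count_mode = FALSE, count_scale = 20,
                           seed = 1L) {
  embedding_kind <- match.arg(embedding_kind)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_("dropout_rate must lie in [0, 1)")
  }
  if (noise_sd < 0) {
    stop_("noise_sd must be non-negative")
  }
  if (is.null(planted_genes)) {
    restricted <- if (embedding_kind == "two_branches") "branch2" else c(0.5, 1)
    planted_genes <- list(
      planted_gene(1L, "all", "linear", 1),
      planted_gene(2L, "all", "linear", 1),
      planted_gene(3L, "all", "sigmoid", 1),
      planted_gene(4L, "all", "sigmoid", 1),
      planted_gene(5L, restricted, "linear", 1)
    )
  }
  idx <- vapply(planted_genes, `[[`, integer(1), "gene")
  if (any(idx < 1L) || any(idx > n_genes)) {
    stop_("planted gene indices must lie within 1..n_genes")
  }
  if (anyDuplicated(idx)) {
    stop_("planted gene indices must be unique")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         embedding_kind = embedding_kind, planted_genes = planted_genes,
         dropout_rate = dropout_rate, noise_sd = noise_sd,
         baseline = baseline, coord_jitter_sd = coord_jitter_sd,
         count_mode = count_mode, count_scale = count_scale,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic expression matrix and embedding
#'
#' Draws a dataset from a [synthetic_spec()]: latent positions and branch
#' assignments, jittered embedding coordinates, planted-gene effects plus
#' gaussian noise clipped at zero (or Poisson counts in count mode), and
#' independent dropout.  A single seed is expanded into independent
#' substreams for layout, noise, count sampling and dropout, so outputs are
#' bit-identical across runs of the same spec.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `expression` (cells x genes matrix), `embedding`
#'   (cells x P matrix), `truth` (data frame of planted genes: `gene`,
#'   `region`, `effect`, `slope`) and `cells` (data frame `cell_id`, `t`
#'   latent position, `branch`: 0 = trunk, 1/2 = arms, NA off the
#'   two-branch layout).
#' @export
#' @examples
#' sim <- simulate_relevance_data(synthetic_spec(n_cells = 50, n_genes = 20))
#' dim(sim$expression)
#' sim$truth
simulate_relevance_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_cells
  g <- spec$n_genes
  set.seed(spec$seed)
  substream <- sample.int(.Machine$integer.max, 4L)

  # --- latent layout and embedding -------------------------------------
  set.seed(substream[1L])
  t_pos <- runif(n)
  branch <- rep(NA_integer_, n)
  if (spec$embedding_kind == "two_branches") {
    branch <- ifelse(t_pos < 0.5, 0L,
                     sample(c(1L, 2L), n, replace = TRUE))
    arm <- ifelse(branch == 1L, 1, ifelse(branch == 2L, -1, 0))
    coords <- cbind(t_pos, pmax(t_pos - 0.5, 0) * arm)
  } else if (spec$embedding_kind == "line") {
    coords <- cbind(t_pos)
  } else { # grid
    coords <- cbind(t_pos, runif(n))
  }
  if (spec$coord_jitter_sd > 0) {
    coords <- coords + matrix(rnorm(length(coords), 0, spec$coord_jitter_sd),
                              nrow = n)
  }
  colnames(coords) <- paste0("DC", seq_len(ncol(coords)))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  gene_ids <- sprintf("gene%04d", seq_len(g))
  rownames(coords) <- cell_ids

  # --- expression: baseline + planted effects + noise ------------------
  set.seed(substream[2L])
  raw <- matrix(rnorm(n * g, mean = spec$baseline, sd = spec$noise_sd),
                nrow = n, ncol = g)
  for (pg in spec$planted_genes) {
    u <- region_position(pg$region, t_pos, branch)
    eff <- effect_value(pg$effect, u, pg$slope)
    raw[, pg$gene] <- raw[, pg$gene] + eff
  }
  if (spec$count_mode) {
    set.seed(substream[3L])
    lambda <- pmax(raw, 0) * spec$count_scale
    expr <- matrix(log1p(rpois(n * g, lambda)), nrow = n, ncol = g)
  } else {
    expr <- pmax(raw, 0)
  }

  # --- dropout ---------------------------------------------------------
  set.seed(substream[4L])
  if (spec$dropout_rate > 0) {
    expr[matrix(runif(n * g) < spec$dropout_rate, nrow = n)] <- 0
  }
  dimnames(expr) <- list(cell_ids, gene_ids)

  truth <- data.frame(
    gene = gene_ids[vapply(spec$planted_genes, `[[`, integer(1), "gene")],
    region = vapply(spec$planted_genes, function(p) {
      if (is.numeric(p$region)) {
        sprintf("[%g,%g]", p$region[1L], p$region[2L])
      } else {
        p$region
      }
    }, character(1)),
    effect = vapply(spec$planted_genes, `[[`, character(1), "effect"),
    slope = vapply(spec$planted_genes, `[[`, numeric(1), "slope"),
    stringsAsFactors = FALSE
  )
  list(
    expression = expr,
    embedding = coords,
    truth = truth,
    cells = data.frame(cell_id = cell_ids, t = t_pos, branch = branch,
                       stringsAsFactors = FALSE)
  )
}

# Region-relative position in [0, 1]; NA outside the region (no effect).
region_position <- function(region, t_pos, branch) {
  if (is.numeric(region)) {
    inside <- t_pos >= region[1L] & t_pos <= region[2L]
    u <- (t_pos - region[1L]) / (region[2L] - region[1L])
    u[!inside] <- NA_real_
    return(u)
  }
  switch(region,
    all = t_pos,
    branch1 = ,
    branch2 = {
      b <- if (region == "branch1") 1L else 2L
      inside <- !is.na(branch) & branch == b
      u <- (t_pos - 0.5) / 0.5
      u[!inside] <- NA_real_
      u
    }
  )
}

effect_value <- function(effect, u, slope) {
  eff <- switch(effect,
    linear = slope * u,
    sigmoid = slope * plogis(10 * (u - 0.5))
  )
  eff[is.na(eff)] <- 0
  eff
}
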