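# Independent brute-force reference implementations used as oracles.
# Everything here is written as plain loops over the definitions, kept
# deliberately separate from the package's vectorized code paths.

bf_distance <- function(x, y, metric) {
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    cosine = 1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2))),
    spearman = 1 - stats::cor(rank(x), rank(y))
  )
}

bf_knn <- function(X, k, metric) {
  C <- nrow(X)
  idx <- matrix(0L, C, k)
  for (i in seq_len(C)) {
    d <- rep(Inf, C)
    for (j in seq_len(C)) {
      # 12-significant-digit snap: the documented tie contract
      if (j != i) d[j] <- signif(bf_distance(X[i, ], X[j, ], metric), 12)
    }
    o <- order(d, seq_len(C)) # ties by ascending index
    idx[i, ] <- o[seq_len(k)]
  }
  idx
}

bf_differentials <- function(X, S, nn_idx) {
  C <- nrow(X); G <- ncol(X); P <- ncol(S)
  vals <- array(NA_real_, c(C, G, P))
  for (ci in seq_len(C)) {
    for (gi in seq_len(G)) {
      if (X[ci, gi] == 0) next
      v <- numeric(P)
      ok <- TRUE
      for (p in seq_len(P)) {
        q <- c()
        for (n in nn_idx[ci, ]) {
          ds <- S[n, p] - S[ci, p]
          if (ds != 0) q <- c(q, (X[ci, gi] - X[n, gi]) / ds)
        }
        if (!length(q)) { ok <- FALSE; break }
        v[p] <- stats::median(q)
      }
      if (ok) vals[ci, gi, ] <- v
    }
  }
  vals
}

bf_scores <- function(vals) {
  C <- dim(vals)[1L]; G <- dim(vals)[2L]
  s <- matrix(NA_real_, C, G)
  for (ci in seq_len(C)) {
    for (gi in seq_len(G)) {
      v <- vals[ci, gi, ]
      if (!anyNA(v)) s[ci, gi] <- sqrt(sum(v^2))
    }
  }
  s
}

bf_ranks <- function(scores) {
  C <- nrow(scores); G <- ncol(scores)
  r <- matrix(NA_integer_, C, G)
  for (ci in seq_len(C)) {
    s <- scores[ci, ]
    for (gi in seq_len(G)) {
      if (is.na(s[gi])) next
      # competition (min) rank: 1 + number of strictly larger defined scores
      r[ci, gi] <- 1L + sum(!is.na(s) & s > s[gi])
    }
  }
  r
}

bf_local_relevance <- function(ranks, cells, cutoff) {
  G <- ncol(ranks)
  lr <- numeric(G)
  for (gi in seq_len(G)) {
    hits <- 0L
    for (ci in cells) {
      if (!is.na(ranks[ci, gi]) && ranks[ci, gi] < cutoff) hits <- hits + 1L
    }
    lr[gi] <- hits / length(cells)
  }
  lr
}

# One synchronous majority-vote smoothing step on gene labels (NA =
# unlabeled); pool ties resolved towards the lexicographically smallest id.
bf_smooth_step <- function(labels, nn_idx, pool) {
  pool <- sort(pool, method = "radix")
  out <- labels
  for (ci in seq_along(labels)) {
    nb <- labels[nn_idx[ci, ]]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    counts <- vapply(pool, function(g) sum(nb == g), integer(1))
    best <- pool[counts == max(counts)]
    out[ci] <- sort(best, method = "radix")[1L]
  }
  out
}

# Depth-by-depth RBO summation: finite prefix terms plus the constant-
# agreement extrapolation tail.
bf_rbo <- function(a, b, p) {
  s <- min(length(a), length(b))
  l <- max(length(a), length(b))
  total <- 0
  X <- numeric(l)
  for (d in seq_len(l)) {
    X[d] <- length(intersect(head(a, d), head(b, d)))
    agreement <- if (d <= s) {
      X[d] / d
    } else {
      (X[d] + X[s] * (d - s) / s) / d
    }
    total <- total + (1 - p) * p^(d - 1) * agreement
  }
  total + p^l * ((X[l] - X[s]) / l + X[s] / s)
}

# Small random expression/embedding instance exercising zeros and all
# pipeline stages.
random_instance <- function(seed, C = NULL, G = NULL, P = NULL) {
  set.seed(seed)
  C <- C %||% sample(8:30, 1)
  G <- G %||% sample(8:15, 1)
  P <- P %||% sample(1:3, 1)
  X <- matrix(pmax(0, rnorm(C * G, mean = 1, sd = 0.4)), C, G)
  X[matrix(runif(C * G) < 0.15, C)] <- 0
  # guard the (vanishingly rare) all-zero cell, which no metric supports
  flat <- rowSums(X > 0) == 0
  X[flat, 1] <- 1
  dimnames(X) <- list(sprintf("c%02d", 1:C), sprintf("g%02d", 1:G))
  S <- matrix(rnorm(C * P), C, P,
              dimnames = list(rownames(X), paste0("DC", 1:P)))
  list(X = X, S = S, C = C, G = G, P = P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
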