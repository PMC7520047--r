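#' Rank-biased overlap between two ranked gene lists
#'
#' Rank-biased overlap (RBO) compares two indefinite rankings by averaging
#' their overlap fraction at every depth `d` with geometric weights
#' \eqn{(1-p)p^{d-1}}.  The persistence parameter `p` sets how top-heavy the
#' measure is; `p = 0.9` places about 86\% of the total weight on the first
#' 10 ranks (see [rbo_weight()]).  This implementation computes the
#' extrapolated point estimate for lists of (possibly) unequal length: the
#' shorter list's agreement is extrapolated at its final overlap rate, so
#' the result lies in \[0, 1\] and equals 1 for identical lists.
#'
#' @param list_a,list_b Character vectors of unique items, most relevant
#'   first.  Ties must be resolved before calling (the relevance module's
#'   deterministic tie rule guarantees strict orders).
#' @param p Persistence parameter in (0, 1); default 0.9.
#' @param depth Optional evaluation depth: both lists are truncated to at
#'   most `depth` items first.
#' @return RBO value in \[0, 1\]; symmetric in its arguments.
#' @references Webber, Moffat & Zobel (2010) A similarity measure for
#'   indefinite rankings. ACM TOIS 28(4).
#' @export
#' @examples
#' rbo(c("a", "b", "c"), c("a", "b", "c"), p = 0.9) # 1
#' rbo(c("a", "b", "c"), c("x", "y", "z"), p = 0.9) # 0
rbo <- function(list_a, list_b, p = 0.9, depth = NULL) {
  if (p <= 0 || p >= 1) {
    stop_("p must lie strictly between 0 and 1")
  }
  a <- as.character(list_a)
  b <- as.character(list_b)
  if (anyDuplicated(a) || anyDuplicated(b)) {
    stop_("ranked lists must not contain duplicate items")
  }
  if (!is.null(depth)) {
    a <- utils::head(a, depth)
    b <- utils::head(b, depth)
  }
  if (!length(a) || !length(b)) {
    stop_("ranked lists must be nonempty")
  }
  s <- min(length(a), length(b))
  l <- max(length(a), length(b))
  # Overlap X_d = |a[1:min(d,|a|)] /\ b[1:min(d,|b|)]| for d = 1..l.
  X <- overlap_at_depths(a, b, l)
  d <- seq_len(l)
  total <- sum(p^d * X / d)
  if (l > s) {
    dd <- (s + 1L):l
    total <- total + sum(p^dd * X[s] * (dd - s) / (s * dd))
  }
  (1 - p) / p * total + ((X[l] - X[s]) / l + X[s] / s) * p^l
}

overlap_at_depths <- function(a, b, l) {
  X <- numeric(l)
  seen_a <- character(0)
  seen_b <- character(0)
  for (d in seq_len(l)) {
    if (d <= length(a)) seen_a <- c(seen_a, a[d])
    if (d <= length(b)) seen_b <- c(seen_b, b[d])
    X[d] <- length(intersect(seen_a, seen_b))
  }
  X
}

#' Cumulative RBO weight of the first d ranks
#'
#' Fraction of the total rank-biased-overlap weight carried by ranks
#' `1..d` under persistence `p`, by the closed form
#' \deqn{W(1\!:\!d) = 1 - p^{d-1} + d\,\frac{1-p}{p}\Big(\ln\frac{1}{1-p}
#'   - \sum_{i=1}^{d-1} \frac{p^i}{i}\Big).}
#' For `p = 0.9`, about 86\% of the weight falls on the first 10 ranks.
#'
#' @param p Persistence parameter in (0, 1).
#' @param d Depth, a positive integer.
#' @return Weight fraction in \[0, 1\], increasing in `d` towards 1.
#' @export
#' @examples
#' round(rbo_weight(0.9, 10), 2) # 0.86
rbo_weight <- function(p, d) {
  if (p <= 0 || p >= 1) {
    stop_("p must lie strictly between 0 and 1")
  }
  if (d < 1L) {
    stop_("d must be >= 1")
  }
  i <- seq_len(d - 1L) # empty when d = 1
  1 - p^(d - 1L) + d * ((1 - p) / p) * (log(1 / (1 - p)) - sum(p^i / i))
}

#' Overlap of the top k items of two ranked lists
#'
#' @inheritParams rbo
#' @param k Depth of the comparison, `k >= 1`.
#' @return Integer: size of the intersection of the two top-`k` sets.
#' @export
top_k_overlap <- function(list_a, list_b, k) {
  if (k < 1L) {
    stop_("k must be >= 1")
  }
  length(intersect(utils::head(as.character(list_a), k),
                   utils::head(as.character(list_b), k)))
}
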