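make_line_fixture <- function(C = 10, a = 2, b = 0.5, k = 3) {
  s <- matrix(seq(0, 1, length.out = C), ncol = 1,
              dimnames = list(sprintf("c%02d", 1:C), "DC1"))
  x <- matrix(a * s[, 1] + b, ncol = 1,
              dimnames = list(rownames(s), "gA"))
  g <- build_knn(cbind(x, gB = seq_len(C) / C), k = k, metric = "euclidean")
  list(s = s, x = x, g = g)
}

test_that("hand-evaluated 1-D example: slope-1 gene gives quotient -1", {
  s <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "DC1"))
  x <- matrix(c(0.5, 1.5, 2.5), ncol = 1,
              dimnames = list(rownames(s), "gA")) # x = s + 0.5
  g <- import_knn(rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  d <- estimate_differentials(x, s, g)
  # middle cell: quotients (1.5-0.5)/(0-1) = -1 and (1.5-2.5)/(2-1) = -1
  expect_equal(unname(d$values[2, 1, 1]), -1)
  expect_equal(unname(d$values[, 1, 1]), c(-1, -1, -1))
  sc <- compute_scores(d)
  expect_equal(unname(sc[, 1]), c(1, 1, 1))
})

test_that("affine genes yield exactly -a for every cell and any k", {
  for (k in c(1, 2, 4, 7)) {
    fx <- make_line_fixture(C = 12, a = 3.7, b = 0.2, k = k)
    d <- estimate_differentials(cbind(fx$x, gB = seq_len(12) / 12),
                                fx$s, fx$g)
    expect_equal(unname(d$values[, 1, 1]), rep(-3.7, 12),
                 tolerance = 1e-13)
  }
})

test_that("dropout rule: zero expression in the cell itself blanks d_gc", {
  fx <- make_line_fixture()
  x <- cbind(fx$x, gB = rep(1, 10))
  x[4, "gA"] <- 0
  d <- estimate_differentials(x, fx$s, fx$g)
  expect_true(is.na(d$values[4, 1, 1]))
  expect_true(d$missing[4, 1])
  expect_false(anyNA(d$values[-4, 1, 1]))
})

test_that("zero-expression neighbors vote by default, are droppable on request", {
  s <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(paste0("c", 1:3), "DC1"))
  x <- matrix(c(1, 0, 3), ncol = 1, dimnames = list(rownames(s), "gA"))
  g <- import_knn(rbind(c(2L, 3L), c(1L, 3L), c(2L, 1L)))
  d <- estimate_differentials(x, s, g)
  # cell 1 keeps its zero neighbor: quotients (1-0)/1 = 1, (1-3)/2 = -1
  expect_equal(unname(d$values[1, 1, 1]), 0)
  strict <- estimate_differentials(x, s, g, drop_zero_neighbors = TRUE)
  # now only the nonzero neighbor contributes
  expect_equal(unname(strict$values[1, 1, 1]), -1)
  # a cell whose every neighbor is zero-excluded goes missing entirely
  g2 <- import_knn(matrix(c(2L, 1L, 2L), ncol = 1))
  d2 <- estimate_differentials(x, s, g2, drop_zero_neighbors = TRUE)
  expect_true(is.na(d2$values[1, 1, 1]))
  expect_true(d2$missing[1, 1])
})

test_that("constant nonzero genes have zero differential and score", {
  fx <- make_line_fixture()
  x <- cbind(fx$x, const = rep(2, 10))
  d <- estimate_differentials(x, fx$s, fx$g)
  expect_identical(unname(d$values[, 2, 1]), rep(0, 10))
  expect_identical(unname(compute_scores(d)[, 2]), rep(0, 10))
})

test_that("scale equivariance and shift invariance hold exactly", {
  inst <- random_instance(11, C = 20, G = 8, P = 2)
  g <- build_knn(inst$X, k = 5, metric = "euclidean")
  d0 <- estimate_differentials(inst$X, inst$S, g)
  # scaling dimension 2 by lambda divides its component by lambda
  lambda <- 4
  S2 <- inst$S
  S2[, 2] <- S2[, 2] * lambda
  d2 <- estimate_differentials(inst$X, S2, g)
  expect_equal(d2$values[, , 2], d0$values[, , 2] / lambda)
  expect_equal(d2$values[, , 1], d0$values[, , 1])
  # shifting a gene up changes nothing where it was already nonzero
  # (formerly-zero entries gain a differential, as the dropout rule demands)
  Xs <- inst$X
  Xs[, 3] <- Xs[, 3] + 5
  ds <- estimate_differentials(Xs, inst$S, g)
  nz <- inst$X[, 3] > 0
  expect_equal(ds$values[nz, 3, ], d0$values[nz, 3, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(anyNA(ds$values[, 3, ]))
})

test_that("missingness is monotone in dropout", {
  inst <- random_instance(13, C = 15, G = 6, P = 2)
  g <- build_knn(inst$X, k = 4, metric = "euclidean")
  d0 <- estimate_differentials(inst$X, inst$S, g)
  X1 <- inst$X
  nz <- which(X1 > 0, arr.ind = TRUE)
  pick <- nz[3, ]
  X1[pick[1], pick[2]] <- 0
  d1 <- estimate_differentials(X1, inst$S, g)
  expect_true(all(d1$missing[d0$missing]))
  expect_true(d1$missing[pick[1], pick[2]])
})

test_that("zero embedding-coordinate differences are excluded, not Inf", {
  s <- matrix(c(0, 0, 1, 2), ncol = 1,
              dimnames = list(paste0("c", 1:4), "DC1"))
  x <- matrix(c(1, 2, 3, 4), ncol = 1,
              dimnames = list(rownames(s), "gA"))
  g <- import_knn(rbind(c(2L, 3L), c(1L, 3L), c(2L, 4L), c(3L, 2L)))
  d <- estimate_differentials(x, s, g)
  expect_true(all(is.finite(d$values[!d$missing, 1, 1])))
  # cell 1's neighbor 2 shares its coordinate; only neighbor 3 contributes
  expect_equal(unname(d$values[1, 1, 1]), (1 - 3) / (1 - 0))
})

test_that("an entirely-absent gene is permitted and flagged", {
  fx <- make_line_fixture()
  x <- cbind(fx$x, silent = rep(0, 10))
  expect_message(
    d <- estimate_differentials(x, fx$s, fx$g, quiet = FALSE),
    "no defined differential")
  expect_true(all(d$missing[, 2]))
})

test_that("expression change fields preserve cell order and orientation", {
  fx <- make_line_fixture(a = 2)
  x <- cbind(fx$x, gB = rep(1, 10))
  d <- estimate_differentials(x, fx$s, fx$g)
  f <- expression_change_field(d, "gA")
  expect_identical(f$cell_id, rownames(fx$s))
  expect_equal(f$DC1, rep(-2, 10))
  ff <- expression_change_field(d, "gA", orient_forward = TRUE)
  expect_equal(ff$DC1, rep(2, 10)) # forward slope of x = 2s + b
  expect_error(expression_change_field(d, "nope"), "unknown gene")
  # a gene missing everywhere is flagged missing in every row
  x2 <- cbind(x, zz = rep(0, 10))
  d2 <- estimate_differentials(x2, fx$s, fx$g)
  expect_true(all(expression_change_field(d2, "zz")$missing))
})
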