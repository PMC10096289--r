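test_that("spearman correlation matches a rank-then-Pearson oracle and its contracts", {
  expect_equal(spearman_correlation(c(3, 1, 4, 1.5, 9), c(3, 1, 4, 1.5, 9)), 1.0)
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1.0)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_correlation(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  # symmetry + monotone invariance + tie handling
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(10); y <- sample(rep(1:5, 2))  # y has ties
    expect_equal(spearman_correlation(x, y), spearman_correlation(y, x))
    expect_equal(spearman_correlation(exp(x), y), spearman_correlation(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_correlation(x, y),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  # constant vector convention
  expect_equal(spearman_correlation(rep(1, 5), rnorm(5)), 0)
  expect_error(spearman_correlation(1:3, 1:4), class = "dtimoa_invalid_input")
  expect_error(spearman_correlation(1, 2), class = "dtimoa_invalid_input")
})

test_that("correlation matrix is symmetric with unit diagonal and matches pairwise calls", {
  expect_equal(correlation_matrix(list(c(1, 2, 3)))[1, 1], 1.0, ignore_attr = TRUE)
  two <- correlation_matrix(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(unname(two), matrix(1, 2, 2))
  sigs <- make_signatures(3, 10, seed = 11)
  R <- correlation_matrix(sigs)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      expect_equal(R[i, j],
                   spearman_correlation(sigs[[i]]$values, sigs[[j]]$values))
    }
  }
  mixed <- c(sigs[1:2], make_signatures(1, 9, seed = 2))
  expect_error(correlation_matrix(mixed), class = "dtimoa_invalid_input")
})

test_that("weighted average obeys its degenerate fast paths", {
  s <- make_signatures(1, 8, seed = 3)[[1]]
  res <- weighted_average(list(s))
  expect_equal(res$vector, s$values)
  expect_equal(res$weights, 1.0)
  pair <- make_signatures(2, 8, seed = 4)
  res2 <- weighted_average(pair)
  expect_equal(res2$weights, c(0.5, 0.5))
  expect_equal(res2$vector, (pair[[1]]$values + pair[[2]]$values) / 2)
  expect_error(weighted_average(list()), class = "dtimoa_empty_input")
})

test_that("weighted average matches the literal formula oracle on random instances", {
  s1 <- c(1, 2, 3, 4, 5); s2 <- c(1, 2, 3, 5, 4); s3 <- c(5, 4, 3, 2, 1)
  res <- weighted_average(list(s1, s2, s3))
  o <- oracle_weighted_average(cbind(s1, s2, s3))
  expect_equal(res$vector, o$vector, tolerance = 1e-12)
  expect_equal(res$weights, o$weights, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:6, 1); G <- sample(5:30, 1)
    X <- matrix(rnorm(n * G), ncol = n)
    res <- weighted_average(asplit(X, 2))
    o <- oracle_weighted_average(X)
    expect_equal(res$vector, o$vector, tolerance = 1e-10)
    expect_equal(sum(res$weights), 1, tolerance = 1e-9)
  }
})

test_that("aggregation weights are convex and permutation/replication invariants hold", {
  set.seed(5)
  X <- matrix(rnorm(60), ncol = 5)
  res <- weighted_average(asplit(X, 2))
  expect_true(all(res$weights > 0))
  expect_true(all(res$vector >= apply(X, 1, min) - 1e-12))
  expect_true(all(res$vector <= apply(X, 1, max) + 1e-12))
  perm <- c(3, 1, 5, 2, 4)
  resp <- weighted_average(asplit(X[, perm], 2))
  expect_equal(resp$vector, res$vector, tolerance = 1e-12)
  expect_equal(resp$weights, res$weights[perm], tolerance = 1e-12)
  # m identical replicates return the replicate exactly
  v <- rnorm(12)
  rep_res <- weighted_average(replicate(4, v, simplify = FALSE))
  expect_equal(rep_res$vector, v)
  expect_equal(rep_res$weights, rep(0.25, 4))
})

test_that("two-stage aggregation matches a hand-staged oracle and differs from pooling", {
  G <- 12
  panel <- gene_panel(sprintf("g%02d", seq_len(G)))
  set.seed(9)
  mk <- function(v, cell, cond, id) signature(v, "GX", "knockdown", cell, cond, id, panel)
  vs <- replicate(4, rnorm(G), simplify = FALSE)
  sigs <- list(mk(vs[[1]], "A", "c1", "s1"), mk(vs[[2]], "A", "c2", "s2"),
               mk(vs[[3]], "B", "c1", "s3"), mk(vs[[4]], "B", "c2", "s4"))
  two <- aggregate_target(sigs)
  innerA <- weighted_average(vs[1:2]); innerB <- weighted_average(vs[3:4])
  staged <- weighted_average(list(innerA$vector, innerB$vector))
  expect_equal(two$vector, staged$vector, tolerance = 1e-12)
  pooled <- aggregate_target(sigs, single_stage = TRUE)
  expect_false(isTRUE(all.equal(two$vector, pooled$vector, tolerance = 1e-6)))
  # single signature and replicate idempotence
  expect_equal(aggregate_target(sigs[1])$vector, vs[[1]])
  ident <- list(mk(vs[[1]], "A", "c1", "r1"), mk(vs[[1]], "A", "c2", "r2"),
                mk(vs[[1]], "B", "c1", "r3"))
  expect_equal(aggregate_target(ident)$vector, vs[[1]])
  expect_error(aggregate_target(list()), class = "dtimoa_empty_input")
  bad <- list(mk(vs[[1]], "A", "c1", "x1"),
              signature(vs[[2]], "GY", "knockdown", "A", "c1", "x2", panel))
  expect_error(aggregate_target(bad), class = "dtimoa_invalid_input")
})

test_that("two-stage aggregation resists cell-line skew", {
  # cell A floods the pool with 10 noisy replicates of u; cell B has one of v.
  set.seed(21)
  G <- 25
  panel <- gene_panel(sprintf("g%02d", seq_len(G)))
  wins <- 0L
  for (trial in 1:10) {
    u <- rnorm(G); v <- rnorm(G)
    center <- (u + v) / 2
    sigs <- c(lapply(1:10, function(i)
      signature(u + rnorm(G, sd = 0.2), "GX", "knockdown", "A",
                paste0("c", i), paste0("a", i), panel)),
      list(signature(v, "GX", "knockdown", "B", "c1", "b1", panel)))
    two <- aggregate_target(sigs)$vector
    pooled <- aggregate_target(sigs, single_stage = TRUE)$vector
    if (sqrt(sum((two - center)^2)) < sqrt(sum((pooled - center)^2))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 9L)
})
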