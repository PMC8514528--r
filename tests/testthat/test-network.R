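test_that("partial correlation reduces to the marginal and to forced zeros", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.64
  C[1, 3] <- C[3, 1] <- 0.8
  C[2, 3] <- C[3, 2] <- 0.8
  expect_equal(partial_corr(C, 1, 2), 0.64)
  # r_xy = r_xz r_zy exactly -> partial given z is 0
  expect_equal(partial_corr(C, 1, 2, 3), 0, tolerance = 1e-12)
  expect_error(partial_corr(C, 1, 1, 3), "distinct")
  expect_error(partial_corr(C, 1, 2, 2), "distinct")
})

test_that("inversion form agrees with the residual-regression oracle", {
  set.seed(10)
  for (rep in 1:40) {
    p <- sample(4:6, 1)
    C <- random_sparse_corr(p)
    X <- rmvnorm_chol(200, C)
    Cs <- cor(X)
    nodes <- seq_len(p)
    i <- sample(nodes, 1); j <- sample(setdiff(nodes, i), 1)
    S <- sample(setdiff(nodes, c(i, j)), 2)
    # oracle: regress i and j on S, correlate the residuals
    ri <- residuals(lm(X[, i] ~ X[, S]))
    rj <- residuals(lm(X[, j] ~ X[, S]))
    expect_equal(partial_corr(Cs, i, j, S), cor(ri, rj), tolerance = 1e-10)
  }
})

test_that("Fisher-z test matches its closed form and guards its domain", {
  t0 <- fisher_z_test(0, n = 50, s = 0)
  expect_equal(t0$z, 0)
  expect_equal(t0$p, 1)
  expect_false(t0$significant)
  t1 <- fisher_z_test(0.5, n = 30, s = 0, alpha = 0.01)
  expect_equal(t1$z, atanh(0.5) * sqrt(27), tolerance = 1e-12)
  expect_equal(t1$p, 2 * pnorm(-abs(atanh(0.5) * sqrt(27))), tolerance = 1e-12)
  expect_true(t1$significant)
  expect_error(fisher_z_test(0.5, n = 5, s = 2), "n - s - 3")
  deg <- fisher_z_test(1, n = 30, s = 0)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("skeleton search recovers simple structures", {
  set.seed(77)
  # independent columns: empty graph
  X <- matrix(rnorm(4000), 1000, 4, dimnames = list(NULL, letters[1:4]))
  g0 <- pc_stable_skeleton(X, alpha = 0.01)
  expect_equal(nrow(g0$edges), 0)
  expect_equal(unname(g0$centrality), rep(0, 4))
  # chain x -> y -> z: skeleton {x-y, y-z}, no x-z
  n <- 5000
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, sd = 0.6); z <- 0.8 * y + rnorm(n, sd = 0.6)
  gc <- pc_stable_skeleton(cbind(x = x, y = y, z = z))
  expect_setequal(edge_set(gc), c("x y", "y z"))
})

test_that("skeleton equals the exhaustive oracle on sparse-precision models", {
  set.seed(55)
  ok <- 0
  for (rep in 1:10) {
    p <- sample(5:6, 1)
    C <- random_sparse_corr(p)
    X <- rmvnorm_chol(10000, C)
    colnames(X) <- paste0("v", seq_len(p))
    g <- pc_stable_skeleton(X, alpha = 0.01)
    oracle <- exhaustive_skeleton(cor(X), n = 10000, alpha = 0.01)
    expect_identical(edge_set(g), adj_to_edge_set(oracle, colnames(X)))
    ok <- ok + 1
  }
  expect_equal(ok, 10)
})

test_that("the skeleton is order independent", {
  set.seed(66)
  C <- random_sparse_corr(6)
  X <- rmvnorm_chol(2000, C)
  colnames(X) <- paste0("v", 1:6)
  g <- pc_stable_skeleton(X)
  for (rep in 1:20) {
    perm <- sample(6)
    gp <- pc_stable_skeleton(X[, perm])
    expect_identical(edge_set(gp), edge_set(g))
    # same multiset of tests up to ordering
    key <- function(t) sort(sprintf("%s|%s|%s", pmin(t$i, t$j), pmax(t$i, t$j),
                                    vapply(strsplit(t$S, ","), function(s)
                                      paste(sort(s), collapse = ","), "")))
    expect_identical(key(gp$tests), key(g$tests))
  }
})

test_that("raising alpha never removes edges present at a lower alpha", {
  set.seed(88)
  C <- random_sparse_corr(6)
  X <- rmvnorm_chol(800, C)
  colnames(X) <- paste0("v", 1:6)
  prev <- character(0)
  for (a in c(0.001, 0.01, 0.05, 0.2)) {
    es <- edge_set(pc_stable_skeleton(X, alpha = a))
    expect_true(all(prev %in% es))
    prev <- es
  }
})

test_that("edge weights take the minimal-|rho| significant record", {
  g <- structure(list(
    nodes = c("a", "b"),
    edges = data.frame(from = "a", to = "b", sign = NA_integer_,
                       weight = NA_real_, p = NA_real_),
    tests = data.frame(i = c("a", "a", "b"), j = c("b", "b", "a"),
                       S = c("", "c", "d"), s = c(0L, 1L, 1L),
                       rho = c(0.40, 0.22, 0.35), z = 1, p = 1e-4,
                       significant = TRUE),
    centrality = NULL, alpha = 0.01, n = 100L), class = "trait_graph")
  gw <- assign_edge_weights(g)
  expect_equal(gw$edges$weight, 0.22)
  expect_equal(gw$edges$sign, 1L)
  g$tests$rho <- c(0.40, -0.22, 0.35)
  expect_warning(gw2 <- assign_edge_weights(g), "sign")
  expect_equal(gw2$edges$sign, -1L)
  expect_equal(gw2$edges$weight, 0.22)
})

test_that("centrality sums absolute incident weights", {
  g <- structure(list(
    nodes = c("hub", "l1", "l2"),
    edges = data.frame(from = c("hub", "hub"), to = c("l1", "l2"),
                       sign = c(1L, -1L), weight = c(0.2, 0.3),
                       p = c(1e-5, 1e-5)),
    tests = data.frame(), centrality = NULL, alpha = 0.01, n = 100L),
    class = "trait_graph")
  cen <- weighted_centrality(g)
  expect_equal(unname(cen[c("hub", "l1", "l2")]), c(0.5, 0.2, 0.3))
})

test_that("graph exports round-trip through the standard formats", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n); y <- 0.7 * x + rnorm(n, sd = 0.7); z <- 0.7 * y + rnorm(n, sd = 0.7)
  g <- pc_stable_skeleton(cbind(x = x, y = y, z = z))
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_graphml(g, f1)
  write_edge_list(g, f2)
  write_ci_log(g, f3)
  gi <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::gorder(gi), 3)
  expect_equal(igraph::gsize(gi), nrow(g$edges))
  el <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(el), nrow(g$edges))
  log <- utils::read.csv(f3)
  expect_equal(nrow(log), nrow(g$tests))
})
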