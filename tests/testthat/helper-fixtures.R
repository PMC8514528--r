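# Shared fixtures and independent oracles for the test suite.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

tiny_schema <- function() {
  questionnaire_schema(list(
    instrument("alpha", trait = "warmth", scale = c(1, 5),
               items = data.frame(id = paste0("alpha_q", 1:4),
                                  subdomain = c("s1", "s1", "s2", "s2"),
                                  reverse = c(FALSE, TRUE, FALSE, FALSE))),
    instrument("beta", trait = "worry", n_items = 3, scale = c(0, 3)),
    instrument("aq", trait = "autism", n_items = 2, scale = c(1, 4),
               alt_scoring = "binary")))
}

tiny_responses <- function(schema = tiny_schema(), n = 8, seed = 42) {
  set.seed(seed)
  it <- schema_items(schema)
  vals <- sapply(seq_len(nrow(it)), function(j)
    sample(it$scale_min[j]:it$scale_max[j], n, replace = TRUE))
  colnames(vals) <- it$id
  response_matrix(vals)
}

# random correlation matrix with genuine zero-partial-correlation structure:
# a sparse symmetric diagonally-dominant precision matrix is inverted
random_sparse_corr <- function(p, edge_prob = 0.4) {
  repeat {
    Om <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      if (stats::runif(1) < edge_prob)
        Om[i, j] <- Om[j, i] <- stats::runif(1, -0.5, 0.5)
    diag(Om) <- rowSums(abs(Om)) + stats::runif(p, 0.5, 1.5)
    C <- stats::cov2cor(solve(Om))
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) > 1e-6)
      return(C)
  }
}

rmvnorm_chol <- function(n, C) {
  matrix(stats::rnorm(n * ncol(C)), n) %*% chol(C)
}

# naive O(n^3) WPGMA: recompute the full distance matrix after every merge
wpgma_oracle <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  d <- D
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]
    heights[m] <- best[1]
    newd <- (d[i, ] + d[j, ]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  heights
}

# exhaustive skeleton oracle: keep an edge iff *every* conditioning subset
# of the remaining variables rejects independence
exhaustive_skeleton <- function(C, n, alpha = 0.01) {
  p <- ncol(C)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rest <- setdiff(seq_len(p), c(i, j))
    for (s in 0:length(rest)) {
      if (n - s - 3 <= 0) next
      subsets <- if (s == 0) list(integer(0))
                 else if (length(rest) == s) list(rest)
                 else utils::combn(rest, s, simplify = FALSE)
      done <- FALSE
      for (S in subsets) {
        rho <- traitspace::partial_corr(C, i, j, S)
        if (!traitspace::fisher_z_test(rho, n, s, alpha)$significant) {
          adj[i, j] <- adj[j, i] <- FALSE; done <- TRUE; break
        }
      }
      if (done) break
    }
  }
  adj
}

edge_set <- function(graph) {
  if (!nrow(graph$edges)) return(character(0))
  sort(paste(pmin(graph$edges$from, graph$edges$to),
             pmax(graph$edges$from, graph$edges$to)))
}

adj_to_edge_set <- function(adj, nodes) {
  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (!nrow(ut)) return(character(0))
  sort(paste(pmin(nodes[ut[, 1]], nodes[ut[, 2]]),
             pmax(nodes[ut[, 1]], nodes[ut[, 2]])))
}

# small two-cluster battery for fast end-to-end runs
small_cohort_params <- function(seed = 1, n = 300) {
  cohort_params(
    n_subjects = n,
    traits = list(
      trait_def("t1", 1, 6, loading = 0.8), trait_def("t2", 1, 6, loading = 0.8),
      trait_def("t3", 2, 6, loading = 0.8), trait_def("t4", 2, 6, loading = 0.8),
      trait_def("t5", 2, 6, loading = 0.8)),
    within_cluster_corr = 0.5, between_cluster_corr = -0.3, seed = seed)
}
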