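#' Partial correlation from a correlation matrix
#'
#' Correlation of variables i and j after removing the linear effects of the
#' conditioning set S, computed by inverting the \{i, j\} U S submatrix:
#' with \eqn{\Omega = C_{sub}^{-1}},
#' \eqn{\rho_{ij.S} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}.
#'
#' @param C correlation matrix (symmetric, unit diagonal).
#' @param i,j variable indices or names, distinct and not in `S`.
#' @param S conditioning set (indices or names), possibly empty.
#' @return Partial correlation in \[-1, 1\].
#' @export
partial_corr <- function(C, i, j, S = integer(0)) {
  C <- check_corr_matrix(C)
  idx <- function(v) if (is.character(v)) match(v, colnames(C)) else as.integer(v)
  i <- idx(i); j <- idx(j); S <- idx(S)
  if (anyNA(c(i, j, S))) stop_ts("unknown variable name")
  if (i == j || i %in% S || j %in% S)
    stop_ts("i and j must be distinct and disjoint from S")
  if (!length(S)) return(C[i, j])
  sub <- C[c(i, j, S), c(i, j, S)]
  Om <- tryCatch(solve(sub), error = function(e)
    stop_ts("singular submatrix for pair (%d, %d) given S of size %d", i, j, length(S)))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

#' Fisher-z conditional-independence test
#'
#' Tests whether a partial correlation is zero:
#' \eqn{z = \mathrm{atanh}(\hat\rho)\sqrt{n - |S| - 3}}, two-sided
#' \eqn{p = 2(1 - \Phi(|z|))}.
#'
#' @param rho_hat estimated partial correlation.
#' @param n sample size.
#' @param s conditioning-set size; requires `n - s - 3 > 0`.
#' @param alpha significance level (an edge-defining test is significant
#'   when `p < alpha`).
#' @return list (class `ci_test`): `rho`, `z`, `p`, `significant`, `n`, `s`,
#'   `alpha`, and `degenerate = TRUE` when `|rho_hat| = 1` (p is then 0).
#' @export
fisher_z_test <- function(rho_hat, n, s = 0, alpha = 0.01) {
  check_number(rho_hat, "rho_hat", -1, 1)
  if (n - s - 3 <= 0) stop_ts("need n - s - 3 > 0 (n = %d, s = %d)", n, s)
  degenerate <- abs(rho_hat) >= 1
  z <- if (degenerate) sign(rho_hat) * Inf else atanh(rho_hat) * sqrt(n - s - 3)
  p <- if (degenerate) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(rho = rho_hat, z = z, p = p, significant = p < alpha,
                 n = as.integer(n), s = as.integer(s), alpha = alpha,
                 degenerate = degenerate), class = "ci_test")
}

#' PC-stable skeleton over trait scores
#'
#' Order-independent skeleton phase of the PC algorithm with Fisher-z
#' partial-correlation tests.  Starting from the complete graph, at each
#' level l the adjacency is frozen; for every ordered adjacent pair (i, j)
#' all conditioning sets S of size l drawn from the *frozen* neighbors of i
#' (minus j) are tested, and the edge is deleted on the first accepted
#' independence (p >= alpha).  Because deletions only take effect in the
#' next level's snapshot, the result does not depend on variable order.
#'
#' @param data subjects x variables numeric matrix (trait scores, typically
#'   z-scored totals); requires more subjects than `variables + 3`.
#' @param alpha edge significance level (default 0.01).
#' @param max_cond optional cap on the conditioning-set size (default
#'   unbounded, i.e. p - 2).
#' @return list of class `trait_graph`: `nodes`, `edges` (data frame
#'   `from`, `to`, `sign`, `weight`, `p` -- filled by
#'   [assign_edge_weights()], which is applied automatically),
#'   `tests` (data frame of every CI test performed: `i`, `j`, `S`
#'   (comma-separated names), `s`, `rho`, `z`, `p`, `significant`),
#'   `centrality` (from [weighted_centrality()]), `alpha`, `n`.
#' @export
pc_stable_skeleton <- function(data, alpha = 0.01, max_cond = Inf) {
  X <- as_num_matrix(data, "data")
  p <- ncol(X); n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(p))
  if (n <= p + 3) stop_ts("need more subjects (%d) than variables + 3 (%d)", n, p + 3)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_ts("constant column(s): %s", paste(colnames(X)[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  res <- pc_stable_from_corr(C, n = n, alpha = alpha, max_cond = max_cond)
  assign_edge_weights(res)
}

# Core skeleton search on a correlation matrix; exposed separately so the
# exhaustive oracle in the test suite can share the same CI machinery.
pc_stable_from_corr <- function(C, n, alpha = 0.01, max_cond = Inf) {
  C <- check_corr_matrix(C)
  p <- ncol(C)
  nodes <- colnames(C) %||% paste0("v", seq_len(p))
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  tests <- list(); ti <- 0L
  l <- 0L
  repeat {
    snapshot <- adj
    if (l > min(max_cond, p - 2)) break
    if (max(colSums(snapshot)) - 1 < l) break
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || !adj[i, j]) next
      nbrs <- setdiff(which(snapshot[i, ]), j)
      if (length(nbrs) < l) next
      if (n - l - 3 <= 0) next
      subsets <- if (l == 0L) list(integer(0))
                 else if (length(nbrs) == l) list(nbrs)
                 else utils::combn(nbrs, l, simplify = FALSE)
      for (S in subsets) {
        rho <- partial_corr(C, i, j, S)
        ct <- fisher_z_test(rho, n = n, s = length(S), alpha = alpha)
        ti <- ti + 1L
        tests[[ti]] <- data.frame(
          i = nodes[i], j = nodes[j],
          S = paste(nodes[S], collapse = ","), s = length(S),
          rho = rho, z = ct$z, p = ct$p, significant = ct$significant,
          stringsAsFactors = FALSE)
        if (!ct$significant) { adj[i, j] <- adj[j, i] <- FALSE; break }
      }
    }
    l <- l + 1L
  }
  tests <- if (length(tests)) do.call(rbind, tests)
           else data.frame(i = character(0), j = character(0), S = character(0),
                           s = integer(0), rho = numeric(0), z = numeric(0),
                           p = numeric(0), significant = logical(0))
  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(from = nodes[ut[, 1]], to = nodes[ut[, 2]],
                      sign = rep(NA_integer_, nrow(ut)),
                      weight = rep(NA_real_, nrow(ut)),
                      p = rep(NA_real_, nrow(ut)), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, tests = tests,
                 centrality = NULL, alpha = alpha, n = n),
            class = "trait_graph")
}

#' Assign edge signs and weights from the CI-test log
#'
#' Each surviving edge is weighted by the partial correlation of smallest
#' magnitude among all tests performed for that pair (all of which were
#' significant, otherwise the edge would have been deleted): the weight is
#' that |rho|, the sign its sign -- the "net" pairwise association after the
#' strongest conditioning the search applied.  If other records for the pair
#' disagree in sign with the minimal one, the minimal record's sign is used
#' and a warning is emitted.
#'
#' @param graph a `trait_graph` from the skeleton search.
#' @return The graph with `edges$sign`, `edges$weight`, `edges$p` filled and
#'   `centrality` recomputed.
#' @export
assign_edge_weights <- function(graph) {
  stopifnot(inherits(graph, "trait_graph"))
  ed <- graph$edges
  if (nrow(ed)) for (r in seq_len(nrow(ed))) {
    rec <- graph$tests[(graph$tests$i == ed$from[r] & graph$tests$j == ed$to[r]) |
                       (graph$tests$i == ed$to[r] & graph$tests$j == ed$from[r]), ]
    if (!nrow(rec)) stop_ts("edge %s-%s has no test record", ed$from[r], ed$to[r])
    m <- which.min(abs(rec$rho))
    if (any(sign(rec$rho) != sign(rec$rho[m])))
      warning(sprintf("edge %s-%s: sign of minimal-|rho| record disagrees with other records",
                      ed$from[r], ed$to[r]))
    ed$weight[r] <- abs(rec$rho[m])
    ed$sign[r] <- as.integer(sign(rec$rho[m]))
    ed$p[r] <- rec$p[m]
  }
  graph$edges <- ed
  graph$centrality <- weighted_centrality(graph)
  graph
}

#' Weighted degree ("importance") centrality
#'
#' Sum of absolute incident edge weights per node.  Absolute values keep the
#' importance interpretation well defined for signed graphs.
#'
#' @param graph a `trait_graph`.
#' @return Named numeric vector (0 for isolated nodes), sorted as
#'   `graph$nodes`.
#' @export
weighted_centrality <- function(graph) {
  stopifnot(inherits(graph, "trait_graph"))
  cen <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) for (r in seq_len(nrow(graph$edges))) {
    w <- abs(graph$edges$weight[r])
    if (is.na(w)) w <- 0
    cen[graph$edges$from[r]] <- cen[graph$edges$from[r]] + w
    cen[graph$edges$to[r]] <- cen[graph$edges$to[r]] + w
  }
  cen
}

#' @export
print.trait_graph <- function(x, ...) {
  cat(sprintf("<trait_graph> %d nodes, %d edges (alpha = %g, n = %d), %d CI tests\n",
              length(x$nodes), nrow(x$edges), x$alpha, x$n, nrow(x$tests)))
  if (nrow(x$edges)) {
    ed <- x$edges[order(-x$edges$weight), ]
    for (r in seq_len(min(10, nrow(ed))))
      cat(sprintf("  %s %s %s  (%.3f)\n", ed$from[r],
                  if (ed$sign[r] > 0) "--(+)--" else "--(-)--", ed$to[r],
                  ed$weight[r]))
    if (nrow(ed) > 10) cat(sprintf("  ... %d more\n", nrow(ed) - 10))
  }
  invisible(x)
}

#' Convert a trait graph to igraph
#'
#' @param graph a `trait_graph`.
#' @return An undirected `igraph` object with `weight` (absolute), `sign`
#'   and `p` edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "trait_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  g
}

#' Export a trait graph
#'
#' `write_graphml()` writes GraphML (via igraph); `write_edge_list()` writes
#' a TSV with columns node1, node2, sign, weight, p; `write_ci_log()` writes
#' the full CI-test log as CSV.
#'
#' @param graph a `trait_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(graph, path) {
  ed <- graph$edges
  names(ed)[1:2] <- c("node1", "node2")
  utils::write.table(ed, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_ci_log <- function(graph, path) {
  utils::write.csv(graph$tests, path, row.names = FALSE)
  invisible(path)
}
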