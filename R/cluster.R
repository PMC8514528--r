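#' Correlation distance between profiles
#'
#' `d = 1 - r` with Pearson's r computed between columns (default) or rows
#' of `X`.  This is the distance used both for hierarchical clustering of
#' traits and subjects and for the low-dimensional embedding of items:
#' identical profiles are at distance 0, perfectly anticorrelated ones at 2.
#'
#' @param X numeric matrix (e.g. subjects x traits of z-scores).
#' @param axis `"columns"`: distances between column profiles; `"rows"`:
#'   between row profiles.
#' @return Symmetric distance matrix with zero diagonal, labeled by the
#'   corresponding dimnames.
#' @export
correlation_distance <- function(X, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  X <- as_num_matrix(X, "X")
  if (axis == "rows") X <- t(X)
  if (nrow(X) < 3L) stop_ts("need at least 3 observations per profile")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_ts("constant profile(s): %s",
            paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "))
  D <- 1 - stats::cor(X)
  D[abs(D) < 1e-15] <- 0
  diag(D) <- 0
  D
}

#' WPGMA (weighted-linkage) hierarchical clustering
#'
#' Agglomerative clustering with the weighted-average update: after merging
#' clusters a and b, the distance of the merged cluster to any c is
#' `(d(a,c) + d(b,c)) / 2`, regardless of cluster sizes.  Leaf order follows
#' the merge order; no optimal-leaf reordering is applied.  Ties between
#' candidate merges are broken toward the lowest index pair
#' (`stats::hclust`'s deterministic convention).
#'
#' @param D symmetric distance matrix (e.g. from [correlation_distance()])
#'   or a `dist` object.
#' @return An object of class `hclust` (method `"mcquitty"`), usable with
#'   [cut_tree()], `plot()` and [dendrogram_newick()].
#' @export
wpgma_linkage <- function(D) {
  d <- if (inherits(D, "dist")) D else {
    D <- as_num_matrix(D, "D")
    if (anyNA(D) || any(!is.finite(D)))
      stop_ts("`D` contains non-finite distances")
    if (max(abs(D - t(D))) > 1e-12) stop_ts("`D` must be symmetric")
    stats::as.dist(D)
  }
  if (anyNA(d) || any(!is.finite(d))) stop_ts("`D` contains non-finite distances")
  if (attr(d, "Size") < 2L) stop_ts("need at least 2 leaves")
  stats::hclust(d, method = "mcquitty")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges of the tree.
#'
#' @param dend an `hclust` tree.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return Named integer vector label -> cluster id (1..k).
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  if (k < 1 || k > n) stop_ts("k = %d out of range [1, %d]", k, n)
  stats::cutree(dend, k = k)
}

#' Export a dendrogram as a Newick string
#'
#' @param dend an `hclust` tree.
#' @param path optional file; when given the string is also written there.
#' @return Newick string (invisibly if `path` is given).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "hclust"))
  nw <- ape::write.tree(ape::as.phylo(dend))
  if (!is.null(path)) { writeLines(nw, path); return(invisible(nw)) }
  nw
}

#' Per-subject cluster composite scores
#'
#' The mean z-score over the traits of each cluster -- e.g. the average of
#' the positive-cluster traits and of the negative-cluster traits for every
#' subject.  Each composite is the exact arithmetic mean of its member
#' traits' z-scores.
#'
#' @param trait_z subjects x traits matrix of z-scored trait totals.
#' @param assignment named vector trait -> cluster id (from [cut_tree()]).
#' @return subjects x clusters matrix; column names `cluster_<id>`.
#' @export
composite_scores <- function(trait_z, assignment) {
  trait_z <- as_num_matrix(trait_z, "trait_z")
  miss <- setdiff(colnames(trait_z), names(assignment))
  if (length(miss))
    stop_ts("assignment lacks trait(s): %s", paste(miss, collapse = ", "))
  ks <- sort(unique(assignment[colnames(trait_z)]))
  out <- vapply(ks, function(k) {
    members <- colnames(trait_z)[assignment[colnames(trait_z)] == k]
    if (!length(members)) stop_ts("cluster %s has no member traits", k)
    rowMeans(trait_z[, members, drop = FALSE])
  }, numeric(nrow(trait_z)))
  colnames(out) <- paste0("cluster_", ks)
  rownames(out) <- rownames(trait_z)
  out
}

#' Paired t test on per-subject score pairs
#'
#' @param x,y numeric vectors of equal length (n >= 2), paired by subject.
#' @return list with `t`, `df` (= n - 1), `p` (two-sided), `mean_diff`, `n`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop_ts("x and y must have equal length")
  if (length(x) < 2L) stop_ts("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0 && any(d != 0))
    stop_ts("constant non-zero differences; t undefined")
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0, n = length(d)))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = length(d))
}

#' Within-group correlation of cluster composites
#'
#' Pearson correlation between the two cluster composites (e.g. positive vs
#' negative traits) computed separately inside each subject group, with a
#' two-sided p value from the exact t transform (df = n - 2).
#'
#' @param composites subjects x 2 matrix from [composite_scores()].
#' @param groups named vector subject -> group id.
#' @return data frame: `group`, `n`, `r`, `p`.
#' @export
group_correlation <- function(composites, groups) {
  composites <- as_num_matrix(composites, "composites")
  if (ncol(composites) != 2L) stop_ts("`composites` must have exactly 2 columns")
  groups <- groups[rownames(composites)]
  out <- lapply(sort(unique(groups)), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 3L) stop_ts("group %s has fewer than 3 subjects", g)
    a <- composites[idx, 1]; b <- composites[idx, 2]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop_ts("constant composite within group %s", g)
    ct <- stats::cor.test(a, b)
    data.frame(group = g, n = length(idx), r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
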