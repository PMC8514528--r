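#' Embedding stage parameters
#'
#' Defaults follow the item-embedding configuration used throughout the
#' pipeline: perplexity 10, early-exaggeration factor 80 applied for the
#' first 99 iterations, learning rate 100, at most 5000 iterations.
#'
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (points - 1) / 3`.
#' @param exaggeration early-exaggeration factor multiplying the input
#'   affinities during the opening phase.
#' @param learning_rate gradient-descent step size.
#' @param max_iter iteration cap.
#' @param exaggeration_phase number of opening iterations with exaggeration.
#' @param seed integer seed (used only where an operation needs randomness;
#'   the optimizer itself is deterministic given its initialization).
#' @return list of class `embed_params`.
#' @export
embed_params <- function(perplexity = 10, exaggeration = 80,
                         learning_rate = 100, max_iter = 5000,
                         exaggeration_phase = 99, seed = 1L) {
  for (nm in c("perplexity", "exaggeration", "learning_rate", "max_iter",
               "exaggeration_phase"))
    check_number(get(nm), nm, 0, strict_lower = nm != "exaggeration_phase")
  structure(list(perplexity = perplexity, exaggeration = exaggeration,
                 learning_rate = learning_rate, max_iter = as.integer(max_iter),
                 exaggeration_phase = as.integer(exaggeration_phase),
                 seed = as.integer(seed)), class = "embed_params")
}

new_embedding <- function(coords, labels, trait = NULL, subdomain = NULL) {
  out <- data.frame(label = labels,
                    trait = trait %||% NA_character_,
                    subdomain = subdomain %||% NA_character_,
                    x = coords[, 1], y = coords[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("embedding2d", "data.frame")
  out
}

embedding_coords <- function(emb) {
  stopifnot(inherits(emb, "embedding2d") || is.data.frame(emb))
  m <- as.matrix(emb[, c("x", "y")])
  rownames(m) <- emb$label
  m
}

#' Metric MDS by stress majorization
#'
#' Iterative (non-classical) multidimensional scaling: starting from the
#' classical-scaling (eigendecomposition) configuration, the raw stress
#' \eqn{\sum_{i<j} (\delta_{ij} - d_{ij})^2} is minimized by the Guttman
#' transform, which never increases stress.  Deterministic: a tiny seeded
#' jitter is added only if the classical start is degenerate (coincident
#' points with nonzero target distance).
#'
#' @param D symmetric distance matrix with labels.
#' @param dim embedding dimension (2).
#' @param max_iter,tol iteration cap and relative stress-improvement
#'   tolerance.
#' @param seed seed for the degenerate-start jitter.
#' @return An `embedding2d` data frame with attributes `stress` (final raw
#'   stress) and `stress_trace` (per-iteration values, non-increasing).
#' @export
mds_embed <- function(D, dim = 2, max_iter = 500, tol = 1e-9, seed = 1L) {
  D <- as_num_matrix(D, "D")
  if (any(!is.finite(D))) stop_ts("`D` contains non-finite distances")
  if (max(abs(D - t(D))) > 1e-9) stop_ts("`D` must be symmetric")
  n <- nrow(D)
  if (n < dim + 1) stop_ts("need at least dim + 1 = %d points", dim + 1)
  labels <- rownames(D) %||% paste0("p", seq_len(n))

  # degenerate inputs (e.g. all-zero distances) are handled below, so the
  # classical-scaling eigenvalue warning is uninformative here
  X <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = dim))
  if (ncol(X) < dim) X <- cbind(X, matrix(0, n, dim - ncol(X)))
  ed <- function(X) { E <- as.matrix(stats::dist(X)); E }
  E <- ed(X)
  if (any(E == 0 & D > 0 & upper.tri(D))) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(n * dim, sd = 1e-8), n, dim)
    E <- ed(X)
  }
  stress <- function(E) sum((D[upper.tri(D)] - E[upper.tri(E)])^2)
  trace <- stress(E)
  for (it in seq_len(max_iter)) {
    # Guttman transform: X <- n^{-1} B(X) X
    ratio <- ifelse(E > 0, D / E, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    En <- ed(Xn)
    s <- stress(En)
    trace <- c(trace, s)
    improved <- trace[length(trace) - 1] - s
    X <- Xn; E <- En
    if (improved <= tol * max(s, 1e-12)) break
  }
  out <- new_embedding(X, labels)
  attr(out, "stress") <- trace[length(trace)]
  attr(out, "stress_trace") <- trace
  out
}

# Perplexity-calibrated conditional affinities from a precomputed distance
# matrix (binary search on the Gaussian precision per row, on squared
# distances), then symmetrized: P = (P + t(P)) / (2n).
tsne_affinities <- function(D, perplexity, tol = 1e-5, max_iter = 60) {
  n <- nrow(D)
  D2 <- D^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        pj <- w / sw
        H <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

#' t-SNE on a precomputed distance matrix
#'
#' Standard t-distributed stochastic neighbor embedding run directly on a
#' distance matrix (here 1 - r between item response profiles) rather than
#' on feature vectors.  Conditional affinities are calibrated to the target
#' perplexity per point and symmetrized; the early-exaggeration factor
#' multiplies the affinities for the opening `exaggeration_phase`
#' iterations; optimization is gradient descent with momentum (0.5, then 0.8
#' after iteration 250) and per-coordinate adaptive gains.  The run is
#' deterministic given the initialization.
#'
#' @param D symmetric distance matrix.
#' @param init an `embedding2d` (typically from [mds_embed()]) whose labels
#'   match `D`; used as the starting configuration.
#' @param params an [embed_params()] object.
#' @return An `embedding2d` with attribute `kl_trace`: the KL divergence
#'   recorded every 25 iterations (computed on the unexaggerated
#'   affinities).
#' @export
tsne_embed <- function(D, init, params = embed_params()) {
  D <- as_num_matrix(D, "D")
  n <- nrow(D)
  stopifnot(inherits(params, "embed_params"))
  if (params$perplexity >= (n - 1) / 3)
    stop_ts("perplexity %g infeasible for %d points (need < (n-1)/3)",
            params$perplexity, n)
  labels <- rownames(D) %||% paste0("p", seq_len(n))
  Y <- embedding_coords(init)
  if (!is.null(rownames(Y)) && !is.null(rownames(D))) {
    if (!setequal(rownames(Y), rownames(D)))
      stop_ts("init labels do not match the distance matrix")
    Y <- Y[rownames(D), , drop = FALSE]
  }
  P <- tsne_affinities(D, params$perplexity)
  kl <- function(Q) sum(P * log(P / Q))

  momentum <- 0.5
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  kl_trace <- numeric(0)
  for (iter in seq_len(params$max_iter)) {
    Pe <- if (iter <= params$exaggeration_phase) P * params$exaggeration else P
    sum_Y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_Y, sum_Y, "+") - 2 * (Y %*% t(Y)))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - params$learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
    if (iter %% 25 == 0 || iter == params$max_iter)
      kl_trace <- c(kl_trace, kl(Q))
  }
  out <- new_embedding(Y, labels, trait = init$trait, subdomain = init$subdomain)
  attr(out, "kl_trace") <- kl_trace
  out
}

#' Embed all items of a survey in 2-D
#'
#' Convenience wrapper for the full item-embedding pipeline: correlation
#' distance between z-scored item columns, metric MDS initialization, then
#' t-SNE refinement.  Item trait/subdomain labels are attached from the
#' schema.
#'
#' @param z subjects x items z-score matrix.
#' @param schema a [questionnaire_schema()] covering the items.
#' @param params an [embed_params()].
#' @return An `embedding2d` with trait and subdomain metadata.
#' @export
embed_items <- function(z, schema, params = embed_params()) {
  D <- correlation_distance(z, axis = "columns")
  init <- mds_embed(D, seed = params$seed)
  it <- schema_items(schema)
  rownames(it) <- it$id
  init$trait <- it[init$label, "trait"]
  init$subdomain <- it[init$label, "subdomain"]
  tsne_embed(D, init, params)
}

#' Embed a trait-level correlation matrix
#'
#' Converts a trait correlation matrix to distances `1 - r` and embeds with
#' metric MDS.  Supports placing an externally published correlation matrix
#' (for comparison with the one computed from the data) in the same plane:
#' see [compare_embeddings()].
#'
#' @param C trait correlation matrix, symmetric with unit diagonal.
#' @param ... passed to [mds_embed()].
#' @return An `embedding2d`, one point per trait.
#' @export
embed_trait_matrix <- function(C, ...) {
  C <- check_corr_matrix(C)
  mds_embed(1 - C, ...)
}

#' Procrustes comparison of two embeddings
#'
#' Embeddings are defined only up to rotation, reflection, scaling and
#' translation, so the second configuration is Procrustes-aligned (with
#' scaling) to the first over their shared labels before distances are
#' compared.
#'
#' @param emb1,emb2 `embedding2d` objects with overlapping labels.
#' @return list: `labels`, `rmse` (per-point RMSE after alignment),
#'   `aligned` (emb2's aligned coordinates), `procrustes` (the underlying
#'   fit object).
#' @export
compare_embeddings <- function(emb1, emb2) {
  shared <- intersect(emb1$label, emb2$label)
  if (length(shared) < 3) stop_ts("need at least 3 shared labels")
  A <- embedding_coords(emb1)[shared, , drop = FALSE]
  B <- embedding_coords(emb2)[shared, , drop = FALSE]
  pr <- vegan::procrustes(A, B, scale = TRUE, symmetric = FALSE)
  aligned <- pr$Yrot
  rownames(aligned) <- shared
  list(labels = shared,
       rmse = sqrt(mean(rowSums((A - aligned)^2))),
       aligned = aligned, procrustes = pr)
}

#' Write embedding coordinates as CSV
#'
#' @param emb an `embedding2d`.
#' @param path output path (columns label, trait, subdomain, x, y).
#' @export
write_embedding <- function(emb, path) {
  utils::write.csv(as.data.frame(emb), path, row.names = FALSE)
  invisible(path)
}
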