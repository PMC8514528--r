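#' Linear separability error of two labeled point sets
#'
#' Fits a soft-margin linear maximum-margin classifier (SVM, fixed cost
#' C = 1) to the union of the two 2-D point sets and returns the training
#' misclassification fraction -- the number of points on the wrong side of
#' the learned boundary divided by the total.  Coordinates are standardized
#' internally, and the measure is symmetric in A/B and invariant under
#' rigid transforms of the plane.
#'
#' @param A,B numeric matrices (or data frames) of 2-D coordinates, at least
#'   one point each.
#' @param cost soft-margin regularization constant (default 1).
#' @return Fraction in \[0, 1\]; 0 for well-separated clouds, about 0.5 for
#'   fully intermixed sets of equal size.
#' @export
linear_separability_error <- function(A, B, cost = 1) {
  A <- as_num_matrix(A, "A"); B <- as_num_matrix(B, "B")
  if (ncol(A) != 2L || ncol(B) != 2L) stop_ts("point sets must be 2-D")
  if (nrow(A) < 1L || nrow(B) < 1L) stop_ts("each set needs at least one point")
  X <- rbind(A, B)
  y <- factor(rep(c("a", "b"), c(nrow(A), nrow(B))))
  # center/scale jointly so the fixed cost means the same thing at any
  # embedding scale; guard zero-variance axes
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (nrow(A) == 1L && nrow(B) == 1L)
    return(if (all(A == B)) 0.5 else 0)
  fit <- e1071::svm(x = Xs, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  mean(stats::predict(fit, Xs) != y)
}

#' Prune a scale's items by embedding-based separability screening
#'
#' Operationalizes the refinement of a multi-domain scale whose items leak
#' into other traits' territory in the item embedding:
#' \enumerate{
#'   \item each item of the target scale is tentatively matched to its
#'     nearest trait by distance to trait item-centroids (the target's own
#'     centroid excludes the item itself);
#'   \item for each neighbor trait that attracted target items, the linear
#'     separability error between that matched subset and the neighbor's
#'     items is computed ([linear_separability_error()]);
#'   \item subsets with error above `theta` are declared not linearly
#'     separable from the neighbor and removed from the scale;
#'   \item reliability (Cronbach's alpha) of the surviving items is
#'     recomputed when the keyed response matrix is supplied.
#' }
#' The default `theta = 0.05` sits between errors observed for item groups
#' that clearly intermix with a neighboring trait (roughly 0.08-0.27) and
#' the residual error of a well-localized scale against its closest
#' neighbor (about 0.04).
#'
#' @param emb `embedding2d` covering all target and neighbor items (e.g.
#'   from [embed_items()]).
#' @param schema a [questionnaire_schema()].
#' @param target trait label of the scale being refined.
#' @param neighbors character vector of competing trait labels (default:
#'   every other trait in the embedding).
#' @param theta separability-error threshold for removal.
#' @param responses optional keyed [response_matrix()] for the
#'   alpha-before/after comparison.
#' @return list of class `refinement_report`: `tests` (one row per neighbor
#'   subset: neighbor, items, n_items, error, decision), `matched`
#'   (item -> nearest trait), `removed`, `kept`, `alpha_before`,
#'   `alpha_after`, `schema_variant` (schema restricted to surviving target
#'   items, other instruments untouched).
#' @export
prune_items <- function(emb, schema, target, neighbors = NULL, theta = 0.05,
                        responses = NULL) {
  stopifnot(inherits(schema, "questionnaire_schema"))
  it <- schema_items(schema)
  if (!target %in% it$trait) stop_ts("target trait '%s' not in schema", target)
  emb <- as.data.frame(emb)
  rownames(emb) <- emb$label
  traits_in_emb <- unique(it$trait[it$id %in% emb$label])
  neighbors <- neighbors %||% setdiff(traits_in_emb, target)
  target_items <- it$id[it$trait == target & it$id %in% emb$label]
  if (!length(target_items)) stop_ts("no embedded items for target '%s'", target)
  coords <- embedding_coords(emb)

  centroid <- function(ids) colMeans(coords[ids, , drop = FALSE])
  trait_items <- lapply(stats::setNames(nm = c(target, neighbors)),
                        function(tr) it$id[it$trait == tr & it$id %in% emb$label])
  # step 1: nearest-trait matching
  matched <- vapply(target_items, function(id) {
    d <- vapply(names(trait_items), function(tr) {
      ids <- setdiff(trait_items[[tr]], id)
      if (!length(ids)) return(Inf)
      sum((coords[id, ] - centroid(ids))^2)
    }, 0)
    names(which.min(d))
  }, "")

  # steps 2-3: per-neighbor separability tests
  tests <- list(); removed <- character(0)
  for (nb in neighbors) {
    subset_ids <- target_items[matched == nb]
    if (!length(subset_ids)) next
    err <- linear_separability_error(coords[subset_ids, , drop = FALSE],
                                     coords[trait_items[[nb]], , drop = FALSE])
    decision <- if (err > theta) "remove" else "keep"
    if (decision == "remove") removed <- c(removed, subset_ids)
    tests[[nb]] <- data.frame(neighbor = nb, n_items = length(subset_ids),
                              items = paste(subset_ids, collapse = ","),
                              error = err, decision = decision,
                              stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, c(tests, list(make.row.names = FALSE)))
           else data.frame(neighbor = character(0), n_items = integer(0),
                           items = character(0), error = numeric(0),
                           decision = character(0))
  kept <- setdiff(target_items, removed)
  if (!length(kept))
    stop_ts("pruning removed every item of '%s'; raise theta", target)

  alpha_before <- alpha_after <- NA_real_
  if (!is.null(responses)) {
    stopifnot(inherits(responses, "response_matrix"))
    alpha_before <- cronbach_alpha(responses$values[, target_items, drop = FALSE])
    alpha_after <- cronbach_alpha(responses$values[, kept, drop = FALSE])
  }
  all_kept <- c(setdiff(it$id, target_items), kept)
  structure(list(target = target, theta = theta, tests = tests,
                 matched = matched, removed = removed, kept = kept,
                 alpha_before = alpha_before, alpha_after = alpha_after,
                 schema_variant = subset_schema(schema, all_kept)),
            class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  cat(sprintf("<refinement_report> target '%s': %d kept, %d removed (theta = %g)\n",
              x$target, length(x$kept), length(x$removed), x$theta))
  if (nrow(x$tests))
    for (r in seq_len(nrow(x$tests)))
      cat(sprintf("  vs %-16s %2d item(s)  error %5.1f%%  -> %s\n",
                  x$tests$neighbor[r], x$tests$n_items[r],
                  100 * x$tests$error[r], x$tests$decision[r]))
  if (!is.na(x$alpha_before))
    cat(sprintf("  alpha: %.3f -> %.3f\n", x$alpha_before, x$alpha_after))
  invisible(x)
}

#' Write a refinement report as JSON
#'
#' @param report a `refinement_report`.
#' @param path output path.
#' @export
write_refinement <- function(report, path) {
  out <- report[c("target", "theta", "tests", "removed", "kept",
                  "alpha_before", "alpha_after")]
  out$matched <- as.list(report$matched)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Reassign a trait's items among its subdomains
#'
#' Each item of the trait is assigned to the subdomain whose item centroid
#' (excluding the item itself) lies nearest in the embedding; switches
#' relative to the schema's current membership are reported.
#'
#' @param emb `embedding2d` covering the trait's items.
#' @param schema a [questionnaire_schema()]; the trait needs >= 2 subdomains
#'   with at least one item each.
#' @param trait trait label.
#' @return data frame: `item`, `old`, `new`, `switched`; attribute
#'   `schema_variant` carries the schema with updated memberships.
#' @export
reassign_items <- function(emb, schema, trait) {
  stopifnot(inherits(schema, "questionnaire_schema"))
  it <- schema_items(schema)
  rows <- it[it$trait == trait & !is.na(it$subdomain), ]
  doms <- unique(rows$subdomain)
  if (length(doms) < 2) stop_ts("trait '%s' needs >= 2 subdomains", trait)
  emb <- as.data.frame(emb)
  rownames(emb) <- emb$label
  coords <- embedding_coords(emb)
  ids <- it$id[it$trait == trait & it$id %in% rownames(coords)]
  res <- lapply(ids, function(id) {
    old <- it$subdomain[it$id == id]
    d <- vapply(doms, function(s) {
      members <- setdiff(rows$id[rows$subdomain == s], id)
      if (!length(members)) return(Inf)
      sum((coords[id, ] - colMeans(coords[members, , drop = FALSE]))^2)
    }, 0)
    if (all(!is.finite(d)))
      stop_ts("no populated subdomain centroid available for item '%s'", id)
    new <- names(which.min(d))
    data.frame(item = id, old = old %||% NA_character_, new = new,
               switched = !identical(old, new), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  # emit the updated schema variant
  sch <- schema
  ins_idx <- which(vapply(sch$instruments, `[[`, "", "trait") == trait)[1]
  items <- sch$instruments[[ins_idx]]$items
  items$subdomain[match(res$item, items$id)] <- res$new
  sch$instruments[[ins_idx]]$items <- items
  attr(res, "schema_variant") <- questionnaire_schema(unname(sch$instruments))
  res
}
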