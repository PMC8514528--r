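test_that("separability error hits its documented extremes", {
  set.seed(1)
  A <- cbind(rnorm(20), rnorm(20))
  B <- cbind(rnorm(20) + 10, rnorm(20))
  expect_equal(linear_separability_error(A, B), 0)
  # identical point multisets: any line misclassifies half
  expect_equal(linear_separability_error(A, A), 0.5)
  expect_equal(linear_separability_error(matrix(c(0, 0), 1),
                                         matrix(c(1, 1), 1)), 0)
})

test_that("separability error is symmetric and rigid-transform invariant", {
  set.seed(6)
  A <- cbind(rnorm(15), rnorm(15))
  B <- cbind(rnorm(15, 1.2), rnorm(15, 0.5))
  e <- linear_separability_error(A, B)
  expect_equal(linear_separability_error(B, A), e)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(5, -3)
  e_rot <- linear_separability_error(sweep(A %*% R, 2, shift, "+"),
                                     sweep(B %*% R, 2, shift, "+"))
  expect_equal(e_rot, e, tolerance = 1e-12)
})

# deterministic embedding fixture: three well-separated trait clouds with
# some target items planted inside a neighbor's cloud
planted_embedding <- function(n_stray = 4) {
  set.seed(42)
  mk <- function(n, cx, cy) cbind(rnorm(n, cx, .3), rnorm(n, cy, .3))
  tgt_core <- mk(8, 0, 0)
  stray <- mk(n_stray, 10, 0)       # inside neighbor n1's territory
  n1 <- mk(10, 10, 0)
  n2 <- mk(10, 0, 10)
  coords <- rbind(tgt_core, stray, n1, n2)
  labels <- c(sprintf("tgt_q%d", 1:(8 + n_stray)), sprintf("n1_q%d", 1:10),
              sprintf("n2_q%d", 1:10))
  emb <- data.frame(label = labels,
                    trait = rep(c("tgt", "n1", "n2"), c(8 + n_stray, 10, 10)),
                    subdomain = NA_character_,
                    x = coords[, 1], y = coords[, 2])
  class(emb) <- c("embedding2d", "data.frame")
  emb
}

planted_schema <- function(n_stray = 4) {
  questionnaire_schema(list(
    instrument("tgt", trait = "tgt", n_items = 8 + n_stray, scale = c(1, 5)),
    instrument("n1", trait = "n1", n_items = 10, scale = c(1, 5)),
    instrument("n2", trait = "n2", n_items = 10, scale = c(1, 5))))
}

test_that("pruning removes planted stray items and leaves clean scales alone", {
  emb <- planted_embedding()
  sch <- planted_schema()
  rep_ <- prune_items(emb, sch, "tgt")
  expect_setequal(rep_$removed, sprintf("tgt_q%d", 9:12))
  expect_setequal(rep_$kept, sprintf("tgt_q%d", 1:8))
  expect_equal(rep_$tests$decision[rep_$tests$neighbor == "n1"], "remove")
  expect_gt(rep_$tests$error[rep_$tests$neighbor == "n1"], 0.05)
  # the emitted schema variant drops exactly the removed items
  expect_setequal(schema_items(rep_$schema_variant)$id,
                  c(sprintf("tgt_q%d", 1:8), sprintf("n1_q%d", 1:10),
                    sprintf("n2_q%d", 1:10)))
  # theta = 1: nothing is ever removed
  expect_length(prune_items(emb, sch, "tgt", theta = 1)$removed, 0)
  # idempotence: a second pass at the same theta removes nothing
  emb2 <- emb[!emb$label %in% rep_$removed, ]
  class(emb2) <- c("embedding2d", "data.frame")
  rep2 <- prune_items(emb2, rep_$schema_variant, "tgt")
  expect_length(rep2$removed, 0)
})

test_that("well-separated targets survive pruning with alpha unchanged", {
  emb <- planted_embedding(n_stray = 0)
  sch <- planted_schema(n_stray = 0)
  set.seed(13)
  f <- rnorm(50)
  vals <- sapply(1:28, function(j) pmin(pmax(round(3 + f + rnorm(50, sd = .8)), 1), 5))
  colnames(vals) <- schema_items(sch)$id
  rm <- response_matrix(vals, keyed = TRUE)
  rep_ <- prune_items(emb, sch, "tgt", responses = rm)
  expect_length(rep_$removed, 0)
  expect_equal(rep_$alpha_before, rep_$alpha_after)
  expect_error(prune_items(emb, sch, "nope"), "not in schema")
})

test_that("subdomain reassignment finds planted membership errors", {
  set.seed(77)
  mk <- function(n, cx, cy) cbind(rnorm(n, cx, .2), rnorm(n, cy, .2))
  coords <- rbind(mk(6, 0, 0), mk(6, 8, 0))
  # item s_q1 is labeled subdomain A but sits in B's cloud
  coords[1, ] <- c(8.05, 0.02)
  emb <- data.frame(label = sprintf("s_q%d", 1:12), trait = "s",
                    subdomain = rep(c("A", "B"), each = 6),
                    x = coords[, 1], y = coords[, 2])
  class(emb) <- c("embedding2d", "data.frame")
  sch <- questionnaire_schema(list(
    instrument("s", trait = "s", scale = c(1, 5),
               items = data.frame(id = sprintf("s_q%d", 1:12),
                                  subdomain = rep(c("A", "B"), each = 6),
                                  reverse = FALSE))))
  res <- reassign_items(emb, sch, "s")
  expect_equal(res$new[res$item == "s_q1"], "B")
  expect_true(res$switched[res$item == "s_q1"])
  expect_equal(sum(res$switched), 1)
  # items at their own centroid never switch
  expect_false(any(res$switched[res$item %in% sprintf("s_q%d", 2:6)]))
  var <- attr(res, "schema_variant")
  expect_equal(schema_items(var)$subdomain[schema_items(var)$id == "s_q1"], "B")
})
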