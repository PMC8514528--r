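test_that("schema construction enforces its invariants", {
  sch <- tiny_schema()
  it <- schema_items(sch)
  expect_equal(nrow(it), 9)
  expect_true(all(!duplicated(it$id)))
  # duplicated ids across instruments rejected
  expect_error(questionnaire_schema(list(
    instrument("a", "x", items = data.frame(id = "q1"), scale = c(1, 5)),
    instrument("b", "y", items = data.frame(id = "q1"), scale = c(1, 5)))),
    "unique")
  expect_error(instrument("a", "x", n_items = 3, scale = c(5, 1)), "min < max")
})

test_that("schemas round-trip through YAML and JSON", {
  sch <- tiny_schema()
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_schema(sch, f)
    back <- read_schema(f)
    expect_equal(schema_items(back), schema_items(sch))
    expect_equal(vapply(back$instruments, `[[`, "", "alt_scoring"),
                 vapply(sch$instruments, `[[`, "", "alt_scoring"))
  }
})

test_that("shipped scale-variant fixtures have the documented structure", {
  ext <- function(f) system.file("extdata", f, package = "traitspace")
  s27 <- read_schema(ext("hsps27.yaml"))
  s25 <- read_schema(ext("hsps25.yaml"))
  s16 <- read_schema(ext("hsps16.yaml"))
  it27 <- schema_items(s27)
  expect_equal(nrow(it27), 27)
  expect_equal(as.integer(table(it27$subdomain)[c("aes", "eoe", "lst")]),
               c(7L, 12L, 6L))
  expect_equal(sum(is.na(it27$subdomain)), 2)
  expect_equal(nrow(schema_items(s25)), 25)
  expect_equal(nrow(schema_items(s16)), 16)
  # the 16-item variant is a subset of the 27 with the aes side removed
  expect_true(all(schema_items(s16)$id %in% it27$id))
  expect_equal(sum(schema_items(s16)$subdomain %in% "aes"), 0)
})

test_that("apply_key reverses, range-checks, and is an involution", {
  sch <- tiny_schema()
  rm <- tiny_responses(sch)
  keyed <- apply_key(rm, sch)
  # reverse-keyed item on a 1-5 scale: v -> 6 - v
  expect_equal(keyed$values[, "alpha_q2"], 6 - rm$values[, "alpha_q2"])
  expect_equal(keyed$values[, "alpha_q1"], rm$values[, "alpha_q1"])
  # involution: keying the keyed values restores the raw ones
  expect_equal(apply_key(keyed, sch)$values[, "alpha_q2"],
               rm$values[, "alpha_q2"])
  # out-of-range value names subject and item
  bad <- rm
  bad$values[2, "beta_q1"] <- 9
  expect_error(apply_key(bad, sch), "beta_q1")
  v <- rm$values[, "alpha_q1", drop = FALSE]
  colnames(v) <- "nope"
  expect_error(apply_key(response_matrix(v), sch), "unknown item")
})

test_that("graded and binary scoring of the autism instrument", {
  sch <- tiny_schema()
  v <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4,
              dimnames = list(NULL, c("aq_q1", "aq_q2")))
  graded <- apply_key(response_matrix(v), sch, aq_scoring = "graded")
  expect_equal(unname(graded$values[, "aq_q1"]), c(1, 2, 3, 4))
  binary <- apply_key(response_matrix(v), sch, aq_scoring = "binary")
  expect_equal(unname(binary$values[, "aq_q1"]), c(0, 0, 1, 1))
  expect_equal(unname(binary$values[, "aq_q2"]), c(1, 1, 0, 0))
})

test_that("exclusion filter drops flagged subjects and refuses empty output", {
  rm <- tiny_responses()
  rm$meta$excluded[c(2, 5)] <- TRUE
  rm$meta$exclusion_reason[c(2, 5)] <- "mental_or_brain"
  expect_message(out <- exclude_subjects(rm), "2 subject")
  expect_equal(nrow(out$values), 6)
  none <- tiny_responses()
  expect_identical(exclude_subjects(none)$values, none$values)
  all_out <- tiny_responses()
  all_out$meta$excluded <- TRUE
  expect_error(suppressMessages(exclude_subjects(all_out)), "all subjects")
})

test_that("z-scoring gives exact column moments and rejects constants", {
  expect_equal(unname(zscore_columns(cbind(a = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  set.seed(7)
  z <- zscore_columns(matrix(rnorm(200) * 3 + 5, 20, 10,
                             dimnames = list(NULL, letters[1:10])))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  expect_error(zscore_columns(cbind(a = c(5, 5, 5))), "constant")
})

test_that("trait and subdomain scores follow the scoring rules", {
  sch <- tiny_schema()
  rm <- apply_key(tiny_responses(sch, n = 5), sch)
  ts <- score_traits(rm, sch)
  expect_equal(unname(ts$traits[, "warmth"]),
               unname(rowSums(rm$values[, paste0("alpha_q", 1:4)])))
  # subdomain totals are hand sums over member items only
  expect_equal(unname(ts$subdomains[, "warmth.s1"]),
               unname(rm$values[, "alpha_q1"] + rm$values[, "alpha_q2"]))
  expect_equal(unname(ts$subdomains[, "warmth.s2"]),
               unname(rm$values[, "alpha_q3"] + rm$values[, "alpha_q4"]))
  # mean scoring at the scale maximum stays at the maximum
  msch <- questionnaire_schema(list(
    instrument("h", "sps", n_items = 27, scale = c(1, 7), scoring = "mean")))
  v <- matrix(7, 3, 27, dimnames = list(NULL, paste0("h_q", 1:27)))
  expect_equal(unname(score_traits(response_matrix(v, keyed = TRUE),
                                   msch)$traits[, "sps"]), rep(7, 3))
  expect_error(score_traits(response_matrix(v[, 1:5]), msch), "lacks item")
})

test_that("high-sensitivity prevalence respects the depression screen", {
  tt <- function(sps, dep) {
    structure(list(traits = cbind(sps = sps, depression = dep)),
              class = "trait_scores")
  }
  # 8 eligible subjects, 3 above threshold
  s <- tt(c(10, 20, 99, 99, 99, 10, 10, 10), rep(0, 8))
  expect_equal(sps_high_fraction(s, threshold = 50), 3 / 8)
  expect_equal(sps_high_fraction(tt(rep(99, 4), rep(0, 4)), 50), 1)
  expect_error(sps_high_fraction(tt(rep(99, 4), rep(60, 4)), 50),
               "denominator")
  # depressed subjects leave both numerator and denominator
  s2 <- tt(c(99, 99, 10, 10), c(0, 60, 0, 0))
  expect_equal(sps_high_fraction(s2, 50), 1 / 3)
})

test_that("response CSV round-trips and missing-value policy is explicit", {
  sch <- tiny_schema()
  rm <- tiny_responses(sch)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm, f)
  back <- read_responses(f, sch)
  expect_equal(back$values, rm$values)
  df <- utils::read.csv(f, check.names = FALSE)
  df$alpha_q1[3] <- NA
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_responses(f, sch), "missing")
  expect_message(dropped <- read_responses(f, sch, missing = "drop"), "dropping 1")
  expect_equal(nrow(dropped$values), nrow(rm$values) - 1)
})
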