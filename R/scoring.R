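#' Construct a response matrix
#'
#' Couples a subjects-by-items score matrix with subject metadata (age, sex,
#' exclusion flags).  All downstream stages consume this container.
#'
#' @param values integer matrix, subjects in rows, items in columns; column
#'   names are item ids, row names subject ids.
#' @param meta data frame with one row per subject; recognised columns are
#'   `subject_id`, `age`, `sex`, `excluded` (logical) and `exclusion_reason`.
#'   Missing columns are filled with defaults.
#' @param keyed logical flag recording whether reverse keying has been applied.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, meta = NULL, keyed = FALSE) {
  values <- as_num_matrix(values, "values")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop_ts("`values` must carry item ids as column names")
  if (anyNA(values))
    stop_ts("response matrix contains missing values; drop or exclude those subjects at load time")
  if (is.null(meta)) meta <- data.frame(subject_id = rownames(values))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$subject_id)) meta$subject_id <- rownames(values)
  if (nrow(meta) != nrow(values))
    stop_ts("metadata rows (%d) do not match subjects (%d)", nrow(meta), nrow(values))
  if (is.null(meta$age)) meta$age <- NA_real_
  if (is.null(meta$sex)) meta$sex <- NA_character_
  if (is.null(meta$excluded)) meta$excluded <- FALSE
  meta$excluded <- as.logical(meta$excluded)
  if (is.null(meta$exclusion_reason)) meta$exclusion_reason <- NA_character_
  structure(list(values = values, meta = meta, keyed = keyed),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d subjects x %d items (%s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$keyed) "keyed" else "raw",
              if (any(x$meta$excluded)) sprintf(", %d flagged for exclusion",
                                                sum(x$meta$excluded)) else ""))
  invisible(x)
}

#' Read and write subject responses as CSV
#'
#' The CSV layout is one row per subject with metadata columns
#' (`subject_id`, `age`, `sex`, `excluded`, `exclusion_reason`) followed by
#' one column per item id.  Rows containing missing item responses are
#' rejected by default; `missing = "drop"` removes them (listwise deletion)
#' with a message.  Silent imputation is deliberately not offered because it
#' would distort the correlation structure every later stage depends on.
#'
#' @param path CSV file path.
#' @param schema optional [questionnaire_schema()]; when given, item columns
#'   are checked against the schema's ids and ranges.
#' @param missing `"error"` (default) or `"drop"`.
#' @return A `response_matrix` with `keyed = FALSE`.
#' @export
read_responses <- function(path, schema = NULL, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop_ts("responses file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("subject_id", "age", "sex", "excluded",
                           "exclusion_reason"), names(df))
  item_cols <- setdiff(names(df), meta_cols)
  if (!length(item_cols)) stop_ts("no item columns found in %s", path)
  vals <- as.matrix(df[item_cols])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$subject_id %||% sprintf("s%04d", seq_len(nrow(df)))
  bad <- which(rowSums(is.na(vals)) > 0L)
  if (length(bad)) {
    if (missing == "error")
      stop_ts("missing responses for subject(s) %s; use missing = 'drop' for listwise deletion",
              paste(utils::head(rownames(vals)[bad], 5), collapse = ", "))
    message(sprintf("dropping %d subject(s) with missing responses", length(bad)))
    vals <- vals[-bad, , drop = FALSE]
    df <- df[-bad, , drop = FALSE]
  }
  rm <- response_matrix(vals, df[meta_cols])
  if (!is.null(schema)) check_items_against_schema(rm, schema)
  rm
}

#' @rdname read_responses
#' @param rm a `response_matrix` to serialize.
#' @export
write_responses <- function(rm, path) {
  stopifnot(inherits(rm, "response_matrix"))
  out <- cbind(rm$meta[c("subject_id", "age", "sex", "excluded",
                         "exclusion_reason")],
               as.data.frame(rm$values, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

check_items_against_schema <- function(rm, schema) {
  it <- schema_items(schema)
  unknown <- setdiff(colnames(rm$values), it$id)
  if (length(unknown))
    stop_ts("unknown item id(s): %s", paste(utils::head(unknown, 5), collapse = ", "))
  invisible(rm)
}

#' Apply the scoring key of a schema to raw responses
#'
#' Reverse-keyed items are mirrored within their scale, `v -> min + max - v`.
#' Instruments with `alt_scoring = "binary"` (the Autism Spectrum Quotient)
#' keep their graded 1-4 responses under the default `aq_scoring = "graded"`;
#' `aq_scoring = "binary"` instead collapses keyed responses to 0/1 (upper
#' half of the scale scores 1), reproducing the instrument's original key.
#' Every value is range-checked against its item's declared scale before
#' keying; violations are reported with subject, item and value.
#'
#' @param rm a `response_matrix` with raw (unkeyed) values, or a plain
#'   numeric matrix with item-id column names.
#' @param schema a [questionnaire_schema()] covering every column of `rm`.
#' @param aq_scoring `"graded"` or `"binary"`, applied to instruments
#'   declaring `alt_scoring = "binary"`.
#' @return A keyed `response_matrix`.  Keying is an involution on
#'   reverse-keyed items: applying the reverse map twice restores the input.
#' @export
apply_key <- function(rm, schema, aq_scoring = c("graded", "binary")) {
  aq_scoring <- match.arg(aq_scoring)
  if (!inherits(rm, "response_matrix")) rm <- response_matrix(rm)
  stopifnot(inherits(schema, "questionnaire_schema"))
  it <- schema_items(schema)
  rownames(it) <- it$id
  unknown <- setdiff(colnames(rm$values), it$id)
  if (length(unknown))
    stop_ts("unknown item id(s): %s", paste(utils::head(unknown, 5), collapse = ", "))
  vals <- rm$values
  alt <- vapply(schema$instruments, `[[`, "", "alt_scoring")
  for (j in colnames(vals)) {
    row <- it[j, ]
    v <- vals[, j]
    bad <- which(v < row$scale_min | v > row$scale_max | v != round(v))
    if (length(bad))
      stop_ts("response out of range for subject '%s', item '%s': %g (scale %g-%g)",
              rownames(vals)[bad[1]], j, v[bad[1]], row$scale_min, row$scale_max)
    if (row$reverse) v <- row$scale_min + row$scale_max - v
    if (alt[[row$instrument]] == "binary" && aq_scoring == "binary")
      v <- as.numeric(v > (row$scale_min + row$scale_max) / 2)
    vals[, j] <- v
  }
  response_matrix(vals, rm$meta, keyed = TRUE)
}

#' Drop subjects flagged for exclusion
#'
#' Restricts a response matrix to non-excluded subjects (e.g. removing the
#' group reporting mental or brain-related problems before the main
#' analysis) and reports counts per exclusion reason.
#'
#' @param rm a `response_matrix`.
#' @param reasons optional character vector; only subjects whose
#'   `exclusion_reason` is in this set are dropped.  Default: every subject
#'   with `excluded = TRUE`.
#' @return The restricted `response_matrix`.
#' @export
exclude_subjects <- function(rm, reasons = NULL) {
  stopifnot(inherits(rm, "response_matrix"))
  drop <- rm$meta$excluded
  if (!is.null(reasons)) drop <- drop & rm$meta$exclusion_reason %in% reasons
  if (any(drop)) {
    tab <- table(rm$meta$exclusion_reason[drop], useNA = "ifany")
    message(sprintf("excluding %d subject(s): %s", sum(drop),
                    paste(sprintf("%s=%d", names(tab) %||% "unspecified", tab),
                          collapse = ", ")))
  }
  if (all(drop)) stop_ts("all subjects excluded; nothing left to analyse")
  response_matrix(rm$values[!drop, , drop = FALSE],
                  rm$meta[!drop, , drop = FALSE], keyed = rm$keyed)
}

#' Z-score every item across subjects
#'
#' Column-wise standardization `(v - mean) / sd` with the sample standard
#' deviation (divisor n - 1).  Every column of the result has mean 0 and
#' sample sd 1 to within 1e-10.
#'
#' @param rm a `response_matrix` or numeric matrix (subjects x items).
#' @return Numeric matrix of z-scores with attribute `provenance` naming the
#'   source dimensions.
#' @export
zscore_columns <- function(rm) {
  x <- if (inherits(rm, "response_matrix")) rm$values else as_num_matrix(rm, "rm")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_ts("constant column(s): %s",
            paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", "))
  z <- scale(x, center = TRUE, scale = sds)
  z <- matrix(z, nrow(x), ncol(x), dimnames = dimnames(x))
  attr(z, "provenance") <- sprintf("zscore of %d x %d response matrix",
                                   nrow(x), ncol(x))
  z
}

#' Score traits and subdomains from keyed responses
#'
#' Aggregates each instrument's keyed item scores to a per-subject trait
#' score using the instrument's scoring rule (sum or mean), and likewise for
#' every declared subdomain.
#'
#' @param rm a keyed `response_matrix` containing every schema item.
#' @param schema a [questionnaire_schema()].
#' @return A list of class `trait_scores` with elements `traits` (subjects x
#'   traits matrix), `subdomains` (subjects x `trait.subdomain` matrix, may
#'   have zero columns) and `meta`.
#' @export
score_traits <- function(rm, schema) {
  stopifnot(inherits(rm, "response_matrix"), inherits(schema, "questionnaire_schema"))
  it <- schema_items(schema)
  missing_items <- setdiff(it$id, colnames(rm$values))
  if (length(missing_items))
    stop_ts("response matrix lacks item(s): %s",
            paste(utils::head(missing_items, 5), collapse = ", "))
  agg <- function(ids, rule)
    if (rule == "mean") rowMeans(rm$values[, ids, drop = FALSE])
    else rowSums(rm$values[, ids, drop = FALSE])
  traits <- vapply(schema$instruments, function(ins)
    agg(ins$items$id, ins$scoring), numeric(nrow(rm$values)))
  colnames(traits) <- vapply(schema$instruments, `[[`, "", "trait")
  subs <- list()
  for (ins in schema$instruments) {
    sd_labels <- unique(ins$items$subdomain[!is.na(ins$items$subdomain)])
    for (s in sd_labels)
      subs[[paste(ins$trait, s, sep = ".")]] <-
        agg(ins$items$id[!is.na(ins$items$subdomain) & ins$items$subdomain == s],
            ins$scoring)
  }
  subdomains <- if (length(subs)) do.call(cbind, subs)
                else matrix(numeric(0), nrow(rm$values), 0)
  rownames(traits) <- rownames(rm$values)
  if (ncol(subdomains)) rownames(subdomains) <- rownames(rm$values)
  structure(list(traits = traits, subdomains = subdomains, meta = rm$meta),
            class = "trait_scores")
}

#' @export
print.trait_scores <- function(x, ...) {
  cat(sprintf("<trait_scores> %d subjects, %d traits, %d subdomain scores\n",
              nrow(x$traits), ncol(x$traits), ncol(x$subdomains)))
  invisible(x)
}

#' Fraction of subjects scoring high on a focal trait
#'
#' Among subjects at or below a depression cutoff (default 53, the
#' conventional screening bound of the 18-item depression scale used here),
#' returns the fraction whose focal-trait total exceeds `threshold`.  Used to
#' estimate the prevalence of high sensory processing sensitivity; the
#' high-score threshold itself is instrument convention and must be supplied.
#'
#' @param scores a `trait_scores` object.
#' @param threshold high-score cutoff for the focal trait (strictly above).
#' @param depression_cutoff subjects with depression total strictly above
#'   this are removed from the denominator.
#' @param trait,depression_trait column names in `scores$traits`.
#' @return Single fraction in \[0, 1\].
#' @export
sps_high_fraction <- function(scores, threshold, depression_cutoff = 53,
                              trait = "sps", depression_trait = "depression") {
  stopifnot(inherits(scores, "trait_scores"))
  for (tr in c(trait, depression_trait))
    if (!tr %in% colnames(scores$traits)) stop_ts("trait '%s' not scored", tr)
  eligible <- scores$traits[, depression_trait] <= depression_cutoff
  if (!any(eligible))
    stop_ts("no subjects at or below the depression cutoff; empty denominator")
  mean(scores$traits[eligible, trait] > threshold)
}
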