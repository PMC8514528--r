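#' Cronbach's alpha (coefficient alpha)
#'
#' Internal-consistency reliability
#' \deqn{\rho_T = \frac{k}{k-1}\left(1 - \frac{\sum_{i=1}^k \sigma_i^2}{\sigma_x^2}\right)}
#' where \eqn{k} is the number of items, \eqn{\sigma_i^2} the variance of
#' item \eqn{i} and \eqn{\sigma_x^2} the variance of the total score.  All
#' variances use the sample (n - 1) convention; the formula itself is
#' convention-free as long as numerator and denominator agree, but the choice
#' is fixed and documented for reproducibility.
#'
#' @param items numeric matrix or data frame, subjects in rows, the k >= 2
#'   items of one scale in columns.
#' @return Single numeric value (at most 1; can be negative for scales with
#'   predominantly negative inter-item covariance).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' cronbach_alpha(cbind(x, x, x))  # duplicated items -> exactly 1
cronbach_alpha <- function(items) {
  X <- as_num_matrix(items, "items")
  k <- ncol(X)
  if (k < 2L) stop_ts("alpha needs at least 2 items, got %d", k)
  if (nrow(X) < 2L) stop_ts("alpha needs at least 2 subjects")
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop_ts("total score is constant; alpha undefined")
  item_var <- apply(X, 2, stats::var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Split-half reliability
#'
#' Splits a scale into odd- and even-positioned items, correlates the two
#' half totals, and applies the Spearman-Brown step-up correction
#' \eqn{2r/(1+r)}.  The odd/even partition is a fixed convention of this
#' implementation (split schemes are not interchangeable in general, so the
#' scheme is part of the reported result).
#'
#' @param items numeric matrix, subjects x k items (k >= 2), in scale order.
#' @param scheme currently only `"odd_even"`.
#' @return list with `raw` (half-total correlation), `corrected`
#'   (Spearman-Brown), `k`, `n`.
#' @export
split_half <- function(items, scheme = c("odd_even")) {
  scheme <- match.arg(scheme)
  X <- as_num_matrix(items, "items")
  if (ncol(X) < 2L) stop_ts("split-half needs at least 2 items")
  odd <- rowSums(X[, seq(1, ncol(X), by = 2), drop = FALSE])
  even <- rowSums(X[, seq(2, ncol(X), by = 2), drop = FALSE])
  if (stats::sd(odd) == 0 || stats::sd(even) == 0)
    stop_ts("a half total is constant; split-half undefined")
  r <- stats::cor(odd, even)
  list(raw = r, corrected = 2 * r / (1 + r), k = ncol(X), n = nrow(X))
}

#' Reliability report for every instrument of a schema
#'
#' @param rm keyed `response_matrix`.
#' @param schema a [questionnaire_schema()].
#' @return data frame (one row per instrument) with alpha, raw and corrected
#'   split-half, item count k and subject count n.  Serializable with
#'   [write_reliability()].
#' @export
reliability_report <- function(rm, schema) {
  stopifnot(inherits(rm, "response_matrix"), inherits(schema, "questionnaire_schema"))
  rows <- lapply(schema$instruments, function(ins) {
    X <- rm$values[, ins$items$id, drop = FALSE]
    sh <- split_half(X)
    data.frame(instrument = ins$name, trait = ins$trait,
               alpha = cronbach_alpha(X), split_half_raw = sh$raw,
               split_half = sh$corrected, k = ncol(X), n = nrow(X),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname reliability_report
#' @param report data frame from `reliability_report()`.
#' @param path output JSON path.
#' @export
write_reliability <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
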