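#' Average mother and father parental-bonding forms
#'
#' @param mother,father numeric vectors (one dimension, e.g. care), aligned
#'   by subject; subjects with a missing form are dropped with a message.
#' @return Named numeric vector of per-subject arithmetic means.
#' @export
pbi_average <- function(mother, father) {
  if (length(mother) != length(father))
    stop_ts("mother and father forms must align")
  miss <- is.na(mother) | is.na(father)
  if (any(miss))
    message(sprintf("dropping %d subject(s) with a missing parental form", sum(miss)))
  out <- (mother + father)[!miss] / 2
  names(out) <- (names(mother) %||% as.character(seq_along(mother)))[!miss]
  out
}

#' Split scores into high/low levels
#'
#' @param scores numeric vector, length >= 2.
#' @param rule `"median"` (> median is high) or `"threshold"`.
#' @param threshold cutoff for the threshold rule (> threshold is high).
#' @return factor with levels `low`, `high`, named as `scores`.
#' @export
dichotomize <- function(scores, rule = c("median", "threshold"), threshold = NULL) {
  rule <- match.arg(rule)
  if (length(scores) < 2L) stop_ts("need at least 2 scores")
  cut <- if (rule == "median") {
    if (length(unique(scores)) == 1L)
      stop_ts("all scores equal; median split undefined")
    stats::median(scores)
  } else {
    if (is.null(threshold)) stop_ts("threshold rule needs `threshold`")
    threshold
  }
  out <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' Two-way factorial ANOVA with interaction (Type-II sums of squares)
#'
#' Unbalanced two-factor analysis of variance of `y` on two dichotomous
#' factors.  Main effects use Type-II sums of squares (each main effect
#' adjusted for the other; the interaction tested against the full model),
#' the appropriate convention when cell sizes are unequal, as they are after
#' median or threshold splits.  F statistics share the full-model residual
#' mean square; residual df = n - 4.
#'
#' @param y numeric response (e.g. a cluster composite or one trait score).
#' @param A,B two-level factors (coerced with [factor()]); every A x B cell
#'   must be non-empty.
#' @return data frame of class `anova_table`, rows `A`, `B`, `A:B`,
#'   `Residuals` with columns `SS`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  if (length(y) != length(A) || length(y) != length(B))
    stop_ts("y, A, B must have equal length")
  if (length(y) <= 4L) stop_ts("need n > 4")
  if (any(table(A, B) == 0L)) stop_ts("empty design cell")
  dat <- data.frame(y = y, A = A, B = B)
  rss <- function(fm) sum(stats::residuals(stats::lm(fm, data = dat))^2)
  full <- rss(y ~ A * B)
  both <- rss(y ~ A + B)
  SS <- c(A = rss(y ~ B) - both, B = rss(y ~ A) - both, `A:B` = both - full)
  SS <- pmax(SS, 0)  # guard tiny negative rounding
  df_res <- length(y) - 4L
  ms_res <- full / df_res
  Fv <- if (ms_res > 0) SS / ms_res else ifelse(SS <= 1e-12, 0, Inf)
  pv <- stats::pf(Fv, 1, df_res, lower.tail = FALSE)
  out <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                    SS = c(unname(SS), full), df = c(1L, 1L, 1L, df_res),
                    F = c(unname(Fv), NA), p = c(unname(pv), NA),
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range post-hoc comparisons of group means, using the pooled
#' one-way ANOVA residual mean square of the supplied grouping (for a
#' factorial design pass the interaction cells, e.g.
#' `interaction(A, B)`).
#'
#' @param y numeric response.
#' @param g grouping factor, >= 2 groups with >= 2 observations each.
#' @return data frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(y, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop_ts("need at least 2 groups")
  if (any(table(g) < 2L)) stop_ts("every group needs >= 2 observations")
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample size for detecting a correlation via the Fisher-z transform
#'
#' Smallest n with power `power` to detect a population correlation `r`
#' against zero in a two-sided test at level `alpha`:
#' \deqn{n = \left\lceil \left(\frac{z_{1-\alpha/2} + z_{power}}{\mathrm{atanh}(r)}\right)^2 + 3 \right\rceil}
#'
#' @param r target correlation magnitude, 0 < r < 1.
#' @param alpha two-sided significance level.
#' @param power desired power.
#' @return Integer sample size (e.g. 783 for r = 0.1, alpha = 0.05,
#'   power = 0.80).
#' @export
correlation_power_n <- function(r, alpha = 0.05, power = 0.80) {
  check_number(r, "r", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(power, "power", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  zq <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling((zq / atanh(r))^2 + 3))
}
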