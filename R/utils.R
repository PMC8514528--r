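# Internal helpers shared across the pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ts <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ts("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_ts("`%s` = %g is outside its admissible range", name, x)
  invisible(x)
}

as_num_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_ts("`%s` must be a numeric matrix (or data frame)", name)
  x
}

# Deterministic per-stage seed derived from a master seed.  Keeps every
# derived seed a valid 32-bit integer so the same master seed reproduces the
# whole run while stages remain decoupled.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Symmetry/PSD checks for correlation-like matrices.
check_corr_matrix <- function(C, name = "C", tol = 1e-8) {
  C <- as_num_matrix(C, name)
  if (nrow(C) != ncol(C)) stop_ts("`%s` must be square", name)
  if (max(abs(C - t(C))) > tol) stop_ts("`%s` must be symmetric", name)
  if (max(abs(diag(C) - 1)) > tol) stop_ts("`%s` must have unit diagonal", name)
  C
}
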