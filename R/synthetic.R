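#' Define a synthetic trait
#'
#' @param name trait label (doubles as instrument name).
#' @param cluster which of the two anticorrelated trait clusters (1 or 2)
#'   the trait's latent factor belongs to.
#' @param n_items number of Likert items.
#' @param loading common item loading on the trait factor, in (0, 1].
#' @param scale integer response range `c(min, max)`.
#' @param subdomains optional list of [subdomain_def()]; their item counts
#'   must not exceed `n_items`, remaining items stay uncategorized.
#' @return trait definition (list), consumed by [cohort_params()].
#' @export
trait_def <- function(name, cluster, n_items, loading = 0.7,
                      scale = c(1, 5), subdomains = NULL) {
  if (!cluster %in% 1:2) stop_ts("trait '%s': cluster must be 1 or 2", name)
  check_number(loading, "loading", 0, 1, strict_lower = TRUE)
  if (n_items < 1) stop_ts("trait '%s': n_items must be >= 1", name)
  if (!is.null(subdomains)) {
    tot <- sum(vapply(subdomains, `[[`, 0, "n_items"))
    if (tot > n_items)
      stop_ts("trait '%s': subdomain items (%d) exceed n_items (%d)",
              name, tot, n_items)
  }
  list(name = name, cluster = as.integer(cluster), n_items = as.integer(n_items),
       loading = loading, scale = as.numeric(scale), subdomains = subdomains)
}

#' @rdname trait_def
#' @param cluster_override `NA` (subdomain items load the trait factor, the
#'   label is purely descriptive) or 1/2: the subdomain's items instead load
#'   the *shared factor of that cluster* directly, with effective loading
#'   `loading * sqrt(within_cluster_corr)`.  Override items therefore
#'   correlate with every item of the overridden cluster at the ordinary
#'   between-trait level -- including with each other -- so they form a
#'   diffuse set spread across that cluster rather than a tight cloud of
#'   their own.  This emulates a "spectrum" subdomain (such as aesthetic
#'   sensitivity within the sensory-processing-sensitivity scale) that
#'   intermixes with traits of the opposite cluster.
#' @export
subdomain_def <- function(name, n_items, cluster_override = NA) {
  if (!is.na(cluster_override) && !cluster_override %in% 1:2)
    stop_ts("subdomain '%s': cluster_override must be NA, 1 or 2", name)
  list(name = name, n_items = as.integer(n_items),
       cluster_override = as.integer(cluster_override))
}

#' Parameters of the synthetic cohort generator
#'
#' The response model is a two-level latent factor model.  Two cluster
#' factors \eqn{c_1, c_2} are standard normal with correlation
#' `between_cluster_corr` (negative for anticorrelated clusters).  Each
#' subject belongs to one of the `subject_groups`, which adds the group's
#' mean shifts to the two cluster factors.  Each trait has a factor
#' \eqn{f_t = \sqrt{w}\,\tilde c_{k(t)} + \sqrt{1-w}\,u_t} with
#' `w = within_cluster_corr`, so two traits of one cluster correlate at `w`
#' and across clusters at `w * between_cluster_corr`.  An item of trait t is
#' \eqn{y = \lambda f_t + \epsilon} with
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2 (1-\lambda^2))}; at
#' `noise_sd = 1` (and absent group shifts) items are standardized and two
#' items of one trait correlate at \eqn{\lambda^2}.  Continuous scores are
#' discretized to each item's Likert range by equiprobable normal-quantile
#' thresholds.
#'
#' @param n_subjects cohort size.
#' @param traits list of [trait_def()].
#' @param within_cluster_corr `w`, correlation of two trait factors in one
#'   cluster, in (0, 1).
#' @param between_cluster_corr correlation of the two cluster factors,
#'   in (-1, 1), typically negative.
#' @param subject_groups list of groups, each
#'   `list(proportion =, shift_cluster1 =, shift_cluster2 =)`; proportions
#'   must sum to 1.  Shifts are in latent (standard-normal) units.  An
#'   optional named numeric `trait_shifts` element adds a group-specific
#'   shift to individual trait factors, letting a group carry a distinctive
#'   single-trait signature (e.g. a "moderate" group prominent only on one
#'   trait) on top of the cluster-level shifts.
#' @param noise_sd multiplier on the unique item noise (1 = standardized
#'   items; 0 = items are exact copies of their factor).
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   cohorts.
#' @return Object of class `cohort_params`.
#' @seealso [default_cohort_params()], [generate_cohort()]
#' @export
cohort_params <- function(n_subjects, traits, within_cluster_corr,
                          between_cluster_corr, subject_groups =
                            list(list(proportion = 1, shift_cluster1 = 0,
                                      shift_cluster2 = 0)),
                          noise_sd = 1, seed = 1L) {
  check_number(n_subjects, "n_subjects", 2)
  check_number(within_cluster_corr, "within_cluster_corr", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(between_cluster_corr, "between_cluster_corr", -1, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  props <- vapply(subject_groups, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-8)
    stop_ts("subject group proportions must sum to 1 (got %g)", sum(props))
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_ts("duplicated trait names")
  structure(list(n_subjects = as.integer(n_subjects), traits = traits,
                 within_cluster_corr = within_cluster_corr,
                 between_cluster_corr = between_cluster_corr,
                 subject_groups = subject_groups, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Flat per-item table driving both sampling and the closed-form population
# correlations.  factor_type "trait" items load f_t; "cluster" items
# (subdomain cluster_override) load the shared cluster factor with effective
# loading lambda * sqrt(w).
item_model_table <- function(params) {
  w <- params$within_cluster_corr
  rows <- lapply(params$traits, function(tr) {
    sub <- rep(NA_character_, tr$n_items)
    ov <- rep(NA_integer_, tr$n_items)
    pos <- 1L
    for (s in tr$subdomains %||% list()) {
      idx <- pos:(pos + s$n_items - 1L)
      sub[idx] <- s$name
      ov[idx] <- s$cluster_override
      pos <- pos + s$n_items
    }
    lambda <- ifelse(is.na(ov), tr$loading, tr$loading * sqrt(w))
    data.frame(id = sprintf("%s_q%d", tr$name, seq_len(tr$n_items)),
               trait = tr$name, subdomain = sub,
               factor_type = ifelse(is.na(ov), "trait", "cluster"),
               cluster = ifelse(is.na(ov), tr$cluster, ov),
               lambda = lambda,
               noise_var = params$noise_sd^2 * (1 - lambda^2),
               scale_min = tr$scale[1], scale_max = tr$scale[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Per-item group means: the contribution of subject group g to item i's
# continuous score.  Trait-factor items receive sqrt(w) * cluster shift plus
# any trait-specific shift; cluster-override items the full cluster shift.
item_group_means <- function(params, it) {
  w <- params$within_cluster_corr
  vapply(params$subject_groups, function(g) {
    cl_shift <- c(g$shift_cluster1, g$shift_cluster2)[it$cluster]
    ts <- g$trait_shifts %||% numeric(0)
    tau <- ifelse(it$trait %in% names(ts), ts[it$trait], 0)
    base <- ifelse(it$factor_type == "trait", sqrt(w) * cl_shift + tau, cl_shift)
    it$lambda * base
  }, numeric(nrow(it)))
}

population_item_cov <- function(params) {
  it <- item_model_table(params)
  w <- params$within_cluster_corr
  rho <- params$between_cluster_corr
  Sc <- matrix(c(1, rho, rho, 1), 2)
  tr_f <- it$factor_type == "trait"
  # factor covariance matrix, group shifts excluded
  Phi <- Sc[it$cluster, it$cluster]
  scalef <- ifelse(tr_f, sqrt(w), 1)
  Phi <- Phi * outer(scalef, scalef)
  same_trait <- outer(it$trait, it$trait, "==") & outer(tr_f, tr_f, "&")
  Phi[same_trait] <- Phi[same_trait] + (1 - w)  # unique trait-factor part
  Cov <- Phi * outer(it$lambda, it$lambda)
  # between-group covariance of the item means
  M <- item_group_means(params, it)
  p <- vapply(params$subject_groups, `[[`, 0, "proportion")
  mbar <- as.numeric(M %*% p)
  Mc <- M - mbar
  Cov <- Cov + Mc %*% (p * t(Mc))
  diag(Cov) <- diag(Cov) + it$noise_var
  dimnames(Cov) <- list(it$id, it$id)
  Cov
}

#' Closed-form population correlations of the continuous item model
#'
#' Marginal correlation matrix of the pre-discretization item scores under a
#' [cohort_params()] model, including the covariance contributed by the
#' subject-group mean shifts.  Serves as the oracle that sampled cohorts and
#' the network stage are validated against.
#'
#' @param params a `cohort_params` object.
#' @return items x items correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite; an error is raised if the requested structure is
#'   not PSD).
#' @export
population_correlations <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  Cov <- population_item_cov(params)
  R <- stats::cov2cor(Cov)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop_ts("infeasible correlation structure (min eigenvalue %.3g)", ev)
  R
}

#' Population correlations of continuous trait total scores
#'
#' Aggregates [population_correlations()] through each trait's item sums,
#' giving the trait-level correlation matrix implied by the generator.  Used
#' to compute population partial correlations when checking recovered
#' network edge signs.
#'
#' @param params a `cohort_params` object.
#' @return traits x traits correlation matrix.
#' @export
population_trait_correlations <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  Cov <- population_item_cov(params)
  it <- item_model_table(params)
  traits <- vapply(params$traits, `[[`, "", "name")
  M <- outer(it$trait, traits, "==") * 1
  colnames(M) <- traits
  stats::cov2cor(t(M) %*% Cov %*% M)
}

#' Generate a synthetic questionnaire cohort with planted structure
#'
#' Samples integer Likert responses under the model described in
#' [cohort_params()] and returns them together with the ground truth needed
#' for recovery testing: planted trait clusters, item subdomains and
#' clusters, subject groups, the population correlation matrix, and the
#' continuous (pre-discretization) scores.
#'
#' @param params a [cohort_params()] object.
#' @return list of class `synthetic_cohort` with elements `responses` (a
#'   keyed [response_matrix()]), `schema` (the matching
#'   [questionnaire_schema()]), `truth` (list: `trait_cluster`,
#'   `item_trait`, `item_subdomain`, `item_cluster`, `subject_group`,
#'   `population_corr`, `continuous`, `cluster_factors`) and `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  it <- item_model_table(params)
  pop <- population_correlations(params)  # also validates PSD
  n <- params$n_subjects
  w <- params$within_cluster_corr

  set.seed(params$seed)
  # subject groups: deterministic sizes from the proportions
  props <- vapply(params$subject_groups, `[[`, 0, "proportion")
  sizes <- diff(c(0L, round(cumsum(props) * n)))
  group <- rep(seq_along(sizes), sizes)

  # cluster factors, shifted per group
  rho <- params$between_cluster_corr
  Z <- matrix(stats::rnorm(n * 2), n, 2) %*%
    chol(matrix(c(1, rho, rho, 1), 2))
  shifts <- t(vapply(params$subject_groups,
                     function(g) c(g$shift_cluster1, g$shift_cluster2),
                     numeric(2)))
  C <- Z + shifts[group, , drop = FALSE]
  rownames(C) <- sprintf("s%04d", seq_len(n))

  # trait factors
  traits <- vapply(params$traits, `[[`, "", "name")
  Ftr <- sapply(params$traits, function(tr)
    sqrt(w) * C[, tr$cluster] + sqrt(1 - w) * stats::rnorm(n))
  colnames(Ftr) <- traits
  for (gi in seq_along(params$subject_groups)) {
    ts <- params$subject_groups[[gi]]$trait_shifts %||% numeric(0)
    for (tn in intersect(names(ts), traits))
      Ftr[group == gi, tn] <- Ftr[group == gi, tn] + ts[[tn]]
  }

  # items: continuous then discretized to the Likert range
  Fi <- ifelse(it$factor_type == "trait",
               match(it$trait, traits), -it$cluster)
  Y <- matrix(0, n, nrow(it), dimnames = list(sprintf("s%04d", seq_len(n)), it$id))
  for (j in seq_len(nrow(it))) {
    f <- if (Fi[j] > 0) Ftr[, Fi[j]] else C[, -Fi[j]]
    Y[, j] <- it$lambda[j] * f + sqrt(it$noise_var[j]) * stats::rnorm(n)
  }
  V <- Y
  for (j in seq_len(ncol(Y))) {
    L <- it$scale_max[j] - it$scale_min[j] + 1
    z <- (Y[, j] - mean(Y[, j])) / stats::sd(Y[, j])
    V[, j] <- it$scale_min[j] + findInterval(z, stats::qnorm(seq_len(L - 1) / L))
  }

  meta <- data.frame(subject_id = rownames(Y),
                     age = round(stats::runif(n, 18, 60)),
                     sex = sample(c("f", "m"), n, replace = TRUE),
                     excluded = FALSE, exclusion_reason = NA_character_,
                     stringsAsFactors = FALSE)

  schema <- questionnaire_schema(lapply(params$traits, function(tr) {
    rows <- it[it$trait == tr$name, ]
    instrument(tr$name, trait = tr$name, scale = tr$scale,
               items = data.frame(id = rows$id, subdomain = rows$subdomain,
                                  reverse = FALSE, stringsAsFactors = FALSE))
  }))

  truth <- list(
    trait_cluster = stats::setNames(vapply(params$traits, `[[`, 0L, "cluster"), traits),
    item_trait = stats::setNames(it$trait, it$id),
    item_subdomain = stats::setNames(it$subdomain, it$id),
    item_cluster = stats::setNames(as.integer(it$cluster), it$id),
    subject_group = stats::setNames(group, rownames(Y)),
    population_corr = pop,
    continuous = Y,
    cluster_factors = C)

  structure(list(responses = response_matrix(V, meta, keyed = TRUE),
                 schema = schema, truth = truth, params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d traits, %d items, %d groups (seed %d)\n",
              x$params$n_subjects, length(x$params$traits),
              length(x$truth$item_trait),
              length(x$params$subject_groups), x$params$seed))
  invisible(x)
}

#' Parental-bonding scores tied to the cohort's latent factors
#'
#' Generates mother- and father-form care and overprotection scores (in
#' standardized units) for every subject of an existing cohort.  Each
#' dimension is a shared latent with the requested correlation to one of the
#' cohort's cluster factors, plus independent form noise, so the
#' mother/father *average* attains the stated correlation.
#'
#' @param cohort a [generate_cohort()] result (the latent factors are reused
#'   so the requested correlations refer to this cohort).
#' @param care_corr,overprot_corr target correlation of the averaged care /
#'   overprotection score with its cluster factor.
#' @param care_cluster,overprot_cluster which cluster factor each dimension
#'   tracks (defaults: care follows cluster 1, overprotection cluster 2).
#' @param form_noise_sd sd of the per-form noise around the shared latent.
#' @param seed integer seed (default derived from the cohort's seed).
#' @return data frame: `subject_id`, `care_mother`, `care_father`,
#'   `overprotection_mother`, `overprotection_father`.
#' @export
generate_pbi <- function(cohort, care_corr = 0.3, overprot_corr = 0.3,
                         care_cluster = 1, overprot_cluster = 2,
                         form_noise_sd = 0.7, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  infl <- sqrt(1 + form_noise_sd^2 / 2)
  for (r in c(care_corr, overprot_corr))
    if (abs(r) * infl >= 1)
      stop_ts("|correlation| too large for form_noise_sd = %g (max %.3f)",
              form_noise_sd, 1 / infl)
  set.seed(seed %||% stage_seed(cohort$params$seed, "pbi"))
  n <- nrow(cohort$truth$cluster_factors)
  one <- function(rho, k) {
    c_std <- as.numeric(scale(cohort$truth$cluster_factors[, k]))
    a <- rho * infl
    latent <- a * c_std + sqrt(1 - a^2) * stats::rnorm(n)
    cbind(latent + form_noise_sd * stats::rnorm(n),
          latent + form_noise_sd * stats::rnorm(n))
  }
  care <- one(care_corr, care_cluster)
  over <- one(overprot_corr, overprot_cluster)
  data.frame(subject_id = rownames(cohort$truth$cluster_factors),
             care_mother = care[, 1], care_father = care[, 2],
             overprotection_mother = over[, 1],
             overprotection_father = over[, 2],
             stringsAsFactors = FALSE)
}

#' The default "survey-like" cohort preset
#'
#' Eleven traits measured by 210 items in two anticorrelated clusters --
#' cluster 1: openness, extraversion, conscientiousness, agreeableness;
#' cluster 2: neuroticism, shyness, alexithymia, autism, anxiety, depression
#' and sensory processing sensitivity (sps) -- with three subject groups
#' (positive / moderate / negative trait profiles, sizes 328/296/213 of 837).
#' The sps instrument carries the three-subdomain structure of the 27-item
#' sensitivity scale: aesthetic sensitivity (`aes`, 7 items) overrides to
#' cluster 1, emulating a spectrum trait whose subdomains load on opposite
#' clusters, while ease of excitation (`eoe`, 12), low sensory threshold
#' (`lst`, 6) and 2 uncategorized items stay on the trait factor.
#' Conscientiousness and neuroticism carry the highest loadings of their
#' clusters, making them the planted hub traits.
#'
#' @param n_subjects cohort size (default 837).
#' @param seed integer seed.
#' @return A [cohort_params()] object.
#' @export
default_cohort_params <- function(n_subjects = 837, seed = 1L) {
  traits <- list(
    trait_def("openness",          1, 12, loading = 0.70, scale = c(1, 5)),
    trait_def("extraversion",      1, 12, loading = 0.70, scale = c(1, 5)),
    trait_def("conscientiousness", 1, 12, loading = 0.85, scale = c(1, 5)),
    trait_def("agreeableness",     1, 12, loading = 0.70, scale = c(1, 5)),
    trait_def("neuroticism",       2, 12, loading = 0.85, scale = c(1, 5)),
    trait_def("shyness",           2, 14, loading = 0.70, scale = c(1, 5)),
    trait_def("alexithymia",       2, 20, loading = 0.70, scale = c(1, 5)),
    trait_def("autism",            2, 50, loading = 0.50, scale = c(1, 4)),
    trait_def("anxiety",           2, 21, loading = 0.70, scale = c(0, 3)),
    trait_def("depression",        2, 18, loading = 0.75, scale = c(0, 5)),
    trait_def("sps",               2, 27, loading = 0.70, scale = c(1, 7),
              subdomains = list(
                subdomain_def("aes", 7, cluster_override = 1),
                subdomain_def("eoe", 12),
                subdomain_def("lst", 6),
                subdomain_def("unc", 2))))
  cohort_params(
    n_subjects = n_subjects, traits = traits,
    within_cluster_corr = 0.55, between_cluster_corr = -0.20,
    subject_groups = list(
      # positive group: high positive traits, low negative traits
      list(proportion = 328 / 837, shift_cluster1 = 3.0, shift_cluster2 = -3.0),
      # moderate group: low scores overall with a prominent autism signature
      list(proportion = 296 / 837, shift_cluster1 = 0.0, shift_cluster2 = -3.0,
           trait_shifts = c(autism = 5.4)),
      # negative group: mirror of the positive one; magnitude balances the
      # group proportions so the cohort-level mean profile is flat
      list(proportion = 213 / 837, shift_cluster1 = -4.62, shift_cluster2 = 4.62)),
    noise_sd = 1, seed = seed)
}

#' Spectrum-trait cohort preset without subject groups
#'
#' The same 11-trait, 210-item battery as [default_cohort_params()] but with
#' a single (unshifted) subject group, so that item-level structure -- trait
#' clouds, the diffuse aesthetic-sensitivity subdomain planted in the
#' opposite cluster -- is not overlaid by between-group variance.  This is
#' the preset used to validate the item embedding and the embedding-based
#' refinement of the sensitivity scale.
#'
#' @inheritParams default_cohort_params
#' @return A [cohort_params()] object.
#' @export
spectrum_cohort_params <- function(n_subjects = 837, seed = 1L) {
  p <- default_cohort_params(n_subjects = n_subjects, seed = seed)
  p$subject_groups <- list(list(proportion = 1, shift_cluster1 = 0,
                                shift_cluster2 = 0))
  p
}
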