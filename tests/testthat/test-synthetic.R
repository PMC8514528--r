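test_that("identical parameters and seed give bit-identical cohorts", {
  p <- small_cohort_params(seed = 99)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$responses$values, b$responses$values)
  expect_identical(a$truth$continuous, b$truth$continuous)
  c2 <- generate_cohort(small_cohort_params(seed = 100))
  expect_false(identical(a$responses$values, c2$responses$values))
})

test_that("population correlations follow the factor algebra", {
  # two items of one trait with loading lambda -> r = lambda^2
  p1 <- cohort_params(100, list(trait_def("t", 1, 2, loading = 0.8)),
                      within_cluster_corr = 0.5, between_cluster_corr = -0.3)
  R <- population_correlations(p1)
  expect_equal(R[1, 2], 0.8^2, tolerance = 1e-12)
  # items in different clusters: r = l1 l2 w rho_b
  p2 <- cohort_params(100, list(trait_def("a", 1, 1, loading = 0.9),
                                trait_def("b", 2, 1, loading = 0.6)),
                      within_cluster_corr = 0.4, between_cluster_corr = -0.25)
  expect_equal(population_correlations(p2)[1, 2], 0.9 * 0.6 * 0.4 * -0.25,
               tolerance = 1e-12)
  # same cluster, different traits: r = l1 l2 w
  p3 <- cohort_params(100, list(trait_def("a", 1, 1, loading = 0.9),
                                trait_def("b", 1, 1, loading = 0.6)),
                      within_cluster_corr = 0.4, between_cluster_corr = -0.25)
  expect_equal(population_correlations(p3)[1, 2], 0.9 * 0.6 * 0.4,
               tolerance = 1e-12)
})

test_that("shipped presets are feasible (PSD) and structurally correct", {
  for (p in list(default_cohort_params(), spectrum_cohort_params())) {
    R <- population_correlations(p)
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_equal(nrow(R), 210)
  }
  tr <- default_cohort_params()$traits
  expect_equal(length(tr), 11)
  cl <- vapply(tr, `[[`, 0L, "cluster")
  expect_equal(sum(cl == 1), 4)
  truth <- generate_cohort(small_cohort_params())$truth
  expect_true(all(truth$subject_group %in% 1:3))
})

test_that("noise-free single-trait items are perfect copies", {
  p <- cohort_params(50, list(trait_def("t", 1, 3, loading = 1)),
                     within_cluster_corr = 0.5, between_cluster_corr = -0.3,
                     noise_sd = 0)
  co <- generate_cohort(p)
  cc <- abs(cor(co$truth$continuous))
  expect_equal(unname(cc[upper.tri(cc)]), rep(1, 3), tolerance = 1e-12)
})

test_that("sampled correlations converge to the population matrix", {
  p <- small_cohort_params(seed = 7, n = 5000)
  co <- generate_cohort(p)
  R <- population_correlations(p)
  dev <- abs(cor(co$truth$continuous) - R)
  expect_lt(max(dev[upper.tri(dev)]), 0.05)
  # negative cross-cluster correlation recovered on trait sums (n = 2000)
  p2 <- small_cohort_params(seed = 8, n = 2000)
  p2$between_cluster_corr <- -0.4
  co2 <- generate_cohort(p2)
  tz <- sapply(c("t1", "t3"), function(tr)
    rowSums(co2$truth$continuous[, grep(paste0("^", tr, "_"),
                                        colnames(co2$truth$continuous))]))
  pop <- population_trait_correlations(p2)["t1", "t3"]
  expect_lt(abs(cor(tz[, 1], tz[, 2]) - pop), 0.06)
  expect_lt(pop, 0)
})

test_that("discretization attenuates but preserves correlation signs", {
  p <- small_cohort_params(seed = 21, n = 5000)
  co <- generate_cohort(p)
  R <- population_correlations(p)
  Rhat <- cor(co$responses$values)
  big <- abs(R) > 0.1 & upper.tri(R)
  expect_true(all(sign(Rhat[big]) == sign(R[big])))
  # attenuation: discrete |r| not larger (on clearly nonzero entries)
  expect_lt(mean(abs(Rhat[big])), mean(abs(R[big])))
})

test_that("group mean shifts enter the population correlations", {
  base <- small_cohort_params()
  shifted <- small_cohort_params()
  shifted$subject_groups <- list(
    list(proportion = 0.5, shift_cluster1 = 2, shift_cluster2 = -2),
    list(proportion = 0.5, shift_cluster1 = -2, shift_cluster2 = 2))
  r0 <- population_trait_correlations(base)["t1", "t3"]
  r1 <- population_trait_correlations(shifted)["t1", "t3"]
  expect_lt(r1, r0)  # anticorrelated shifts deepen the cross-cluster negative
  co <- generate_cohort(shifted)
  expect_equal(as.integer(table(co$truth$subject_group)), c(150L, 150L))
})

test_that("parental-bonding scores attain their target correlations", {
  p <- small_cohort_params(seed = 5, n = 5000)
  co <- generate_cohort(p)
  pbi <- generate_pbi(co, care_corr = 0, overprot_corr = -0.3,
                      overprot_cluster = 2)
  care <- pbi_average(pbi$care_mother, pbi$care_father)
  over <- pbi_average(pbi$overprotection_mother, pbi$overprotection_father)
  expect_equal(unname(care),
               unname((pbi$care_mother + pbi$care_father) / 2))
  C <- co$truth$cluster_factors
  expect_lt(abs(cor(care, C[, 1])), 0.05)
  expect_lt(abs(cor(over, C[, 2]) - (-0.3)), 0.05)
  expect_error(generate_pbi(co, care_corr = 0.95), "too large")
})
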