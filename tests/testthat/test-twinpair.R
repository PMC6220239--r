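twin_fixture <- function(n_mz = 60, n_dz = 30, confound_sd = 0, share = 0.5,
                         seed = 33, n_cpgs = 120, causal = 20,
                         effect = c(0.02, 0.05)) {
  cfg <- sim_config(n_cohorts = 1, n_samples = 100, n_cpgs = n_cpgs,
                    n_causal = causal, n_smoking_cpgs = 0,
                    effect_range_education = effect,
                    twin_config = list(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                                       familial_variance_share = share,
                                       confound_sd = confound_sd),
                    seed = seed)
  suppressWarnings(generate_twin_cohort(cfg))
}

test_that("build_pairs keeps complete pairs, logs exclusions, fails on triples", {
  tc <- twin_fixture()
  # drop one member of one family -> that family excluded, counted
  drop_id <- tc$samples$sample_id[1]
  pr <- build_pairs(tc$samples[tc$samples$sample_id != drop_id, ])
  expect_equal(nrow(pr), 89L)
  expect_equal(attr(pr, "excluded"), tc$samples$family_id[1])
  expect_true(all(pr$sample_id_1 < pr$sample_id_2))
  # a third member with the same family id is an error
  tri <- dplyr::bind_rows(tc$samples,
                          dplyr::mutate(tc$samples[2, ], sample_id = "zzz"))
  expect_error(build_pairs(tri), "more than 2 members")
  # stratum bookkeeping matches the sheet
  pr_all <- build_pairs(tc$samples)
  s <- tc$samples
  conc_nev <- sum(vapply(split(s$smoking_status, s$family_id),
                         function(x) all(x == "never"), logical(1)))
  expect_equal(sum(pr_all$smoking_stratum == "concordant_never"), conc_nev)
})

test_that("zero pairs yield an empty table without error", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 50, n_cpgs = 20, n_causal = 0,
                    n_smoking_cpgs = 0,
                    twin_config = list(n_mz_pairs = 0, n_dz_pairs = 0),
                    seed = 5)
  tc <- generate_twin_cohort(cfg)
  expect_equal(nrow(tc$samples), 0L)
  expect_equal(ncol(tc$methylation), 0L)
  expect_equal(nrow(build_pairs(tc$samples)), 0L)
})

test_that("within-pair slopes are flip-invariant and match the fixed-effects oracle", {
  tc <- twin_fixture(n_mz = 40, n_dz = 10, n_cpgs = 40, causal = 10)
  pairs <- build_pairs(tc$samples)
  cpgs <- rownames(tc$methylation)[1:15]
  wp <- within_pair_regression(pairs, tc$samples, tc$methylation, cpgs)

  # flipping every pair's ordering leaves the slope unchanged
  flipped <- dplyr::mutate(pairs, tmp = sample_id_1,
                           sample_id_1 = sample_id_2, sample_id_2 = tmp)
  wp_f <- within_pair_regression(flipped, tc$samples, tc$methylation, cpgs)
  expect_equal(wp$effect, wp_f$effect, tolerance = 1e-10)

  # oracle: the no-intercept difference regression is numerically the pair
  # fixed-effects regression on the stacked data
  wp_ni <- within_pair_regression(pairs, tc$samples, tc$methylation, cpgs,
                                  intercept = FALSE)
  for (cg in cpgs[c(1, 7)]) {
    df <- tibble::tibble(
      y = tc$methylation[cg, tc$samples$sample_id],
      x = tc$samples$education_ridit,
      fam = tc$samples$family_id)
    fit <- lm(y ~ x + fam, data = df)
    expect_equal(wp_ni$effect[wp_ni$cpg_id == cg], unname(coef(fit)["x"]),
                 tolerance = 1e-8)
  }
})

test_that("a degenerate stratum with zero exposure differences errors by name", {
  tc <- twin_fixture(n_mz = 20, n_dz = 0)
  pairs <- build_pairs(tc$samples)
  sam <- tc$samples
  sam$education_ridit <- 0.5
  expect_error(
    within_pair_regression(pairs, sam, tc$methylation,
                           rownames(tc$methylation)[1:5]),
    "exposure differences are zero")
})

test_that("fully shared confounding vanishes within MZ pairs but not in the population", {
  tc <- twin_fixture(n_mz = 300, n_dz = 0, confound_sd = 0.05, share = 1,
                     effect = c(0, 0), seed = 37)
  causal <- tc$truth$cpg_id[tc$truth$causal]
  pairs <- build_pairs(tc$samples)
  wp <- within_pair_regression(pairs, tc$samples, tc$methylation, causal)
  # within-pair slope ~ 0 (95% CI covers 0 at >= 93% of sites)
  cover <- mean(abs(wp$effect) < 1.96 * wp$se)
  expect_gte(cover, 0.9)
  # population regression sees the confounded association
  pop <- run_ewas(tc$methylation, tc$samples,
                  design_spec("custom", covariates = c("sex", "age_at_blood"),
                              se_type = "independence"))
  pop_c <- pop[pop$cpg_id %in% causal, ]
  expect_gt(mean(abs(pop_c$effect) > 1.96 * pop_c$se), 0.5)
})

test_that("direct-only effects give within-pair slopes equal to population slopes", {
  tc <- twin_fixture(n_mz = 250, n_dz = 0, confound_sd = 0,
                     effect = c(0.04, 0.06), seed = 39)
  causal <- tc$truth$cpg_id[tc$truth$causal]
  pairs <- build_pairs(tc$samples)
  wp <- within_pair_regression(pairs, tc$samples, tc$methylation, causal,
                               adjust_smoking = TRUE)
  tr <- tc$truth[match(causal, tc$truth$cpg_id), ]
  agree <- mean(abs(wp$effect - tr$beta_direct) < 2 * wp$se)
  expect_gte(agree, 0.9)
})

test_that("within/population ratios and summaries behave", {
  w <- tibble::tibble(cpg_id = c("a", "b", "c"), effect = c(0.05, 0.02, 0.01))
  p <- tibble::tibble(cpg_id = c("a", "b", "c"), effect = c(0.05, 0.02, 0.01))
  r1 <- within_vs_population_ratio(w, p)
  expect_true(all(r1$ratios$ratio == 1))
  expect_equal(r1$summary$effect_correlation, 1)
  half <- dplyr::mutate(w, effect = effect / 2)
  r2 <- within_vs_population_ratio(half, p)
  expect_equal(r2$summary$mean_ratio, 0.5)
  # small population effects are flagged out of the summary
  p3 <- dplyr::mutate(p, effect = c(0.05, 0.0005, 0.01))
  r3 <- within_vs_population_ratio(w, p3)
  expect_equal(sum(r3$ratios$flag == "ok"), 2L)

  # mean ratio decreases as the shared confounding share rises
  ratios <- vapply(c(0, 1), function(s) {
    tc <- twin_fixture(n_mz = 250, n_dz = 0, confound_sd = 0.04, share = s,
                       effect = c(0.01, 0.02), seed = 41)
    causal <- tc$truth$cpg_id[tc$truth$causal]
    pairs <- build_pairs(tc$samples)
    wp <- within_pair_regression(pairs, tc$samples, tc$methylation, causal)
    pop <- run_ewas(tc$methylation, tc$samples,
                    design_spec("custom",
                                covariates = c("sex", "age_at_blood"),
                                se_type = "independence"))
    within_vs_population_ratio(wp, pop)$summary$mean_ratio
  }, numeric(1))
  expect_gt(ratios[1], ratios[2])
})
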