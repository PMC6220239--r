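test_that("identical config and seed reproduce identical cohorts; seeds differ", {
  cfg <- tiny_config()
  a <- tiny_cohort(1, cfg)
  b <- tiny_cohort(1, cfg)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c2 <- tiny_cohort(2, cfg)
  expect_false(identical(a$methylation[, 1:10], c2$methylation[, 1:10]))
  d <- tiny_cohort(1, tiny_config(seed = 43))
  expect_false(identical(a$methylation, d$methylation))
})

test_that("adding cohorts does not perturb earlier cohorts", {
  cfg2 <- tiny_config()
  cfg4 <- sim_config(n_cohorts = 4, n_samples = 300, n_cpgs = 150,
                     n_causal = 15, n_smoking_cpgs = 15, seed = 42)
  expect_identical(tiny_cohort(1, cfg2)$methylation,
                   suppressWarnings(generate_cohort(cfg4, 1))$methylation)
})

test_that("zero-effect configs carry zero truth and pass a null EWAS", {
  cfg <- tiny_config(effect_range_education = c(0, 0),
                     effect_range_smoking = c(0, 0))
  co <- tiny_cohort(1, cfg)
  expect_true(all(co$truth$beta_total == 0))
  expect_true(all(co$truth$beta_smoking == 0))
  expect_true(all(co$truth$beta_indirect == 0))
  res <- run_ewas(co$methylation, co$samples, design_spec("model1"))
  expect_gt(min(p.adjust(res$p, "bonferroni")), 0.05)
})

test_that("non-causal CpGs have exactly zero true effects", {
  co <- tiny_cohort()
  null_rows <- !(co$truth$causal | co$truth$causal_smoking)
  expect_true(all(co$truth$beta_total[null_rows] == 0))
  expect_true(all(co$truth$beta_direct[null_rows] == 0))
  expect_true(all(co$truth$beta_smoking[null_rows] == 0))
})

test_that("beta values stay in [0,1] with rare clipping and ids are unique", {
  co <- tiny_cohort()
  expect_true(all(co$methylation >= 0 & co$methylation <= 1))
  expect_lt(co$clip_fraction, 0.01)
  expect_false(any(duplicated(rownames(co$methylation))))
  expect_false(any(duplicated(co$samples$sample_id)))
  expect_equal(colnames(co$methylation), co$samples$sample_id)
})

test_that("the education-smoking correlation hits its target on average", {
  cors <- vapply(1:4, function(s) {
    cfg <- sim_config(n_cohorts = 1, n_samples = 2000, n_cpgs = 10,
                      n_causal = 0, n_smoking_cpgs = 0,
                      effect_range_education = c(0, 0),
                      effect_range_smoking = c(0, 0),
                      mediation_fraction = 0, seed = 100 + s)
    co <- suppressWarnings(generate_cohort(cfg, 1))
    cor(co$samples$education_ridit,
        as.numeric(co$samples$smoking_status == "current"))
  }, numeric(1))
  expect_lt(abs(mean(cors) - (-0.11)), 0.03)
})

test_that("an infeasible correlation target fails naming the constraint", {
  cfg <- tiny_config(education_smoking_corr = -0.95)
  expect_error(suppressWarnings(generate_cohort(cfg, 1)), "not achievable")
})

test_that("cohort demographics follow the configured profile", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 4000, n_cpgs = 10,
                    n_causal = 0, n_smoking_cpgs = 0,
                    effect_range_education = c(0, 0),
                    effect_range_smoking = c(0, 0), seed = 12)
  co <- suppressWarnings(generate_cohort(cfg, 1)) # first profile: NTR-like
  p_never <- mean(co$samples$smoking_status == "never")
  # binomial error around 56.5%
  expect_lt(abs(p_never - 0.565), 3 * sqrt(0.565 * 0.435 / 4000) + 0.01)
  expect_lt(abs(mean(co$samples$sex == "F") - 0.686), 0.03)
  expect_lt(abs(mean(co$samples$education_category == 7) - 0.208), 0.03)
})

test_that("cotinine values are consistent with smoking status", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 3000, n_cpgs = 10,
                    n_causal = 0, n_smoking_cpgs = 0,
                    effect_range_education = c(0, 0),
                    effect_range_smoking = c(0, 0), seed = 14)
  co <- suppressWarnings(generate_cohort(cfg, 1))
  s <- co$samples
  expect_true(all(s$cotinine[s$smoking_status == "current"] >= 15))
  nev <- s[s$smoking_status == "never", ]
  frac_mis <- mean(nev$cotinine >= 15)
  frac_shs <- mean(nev$cotinine >= 1 & nev$cotinine < 15)
  expect_lt(abs(frac_mis - 5 / 591), 0.01)
  expect_lt(abs(frac_shs - 150 / 586), 0.05)
})

test_that("external summary statistics reach their analytic correlation", {
  co <- tiny_cohort()
  tr <- co$truth[co$truth$causal, ]
  exact <- generate_external_sumstats(tr, noise_sd = 0)
  expect_equal(cor(exact$effect, tr$beta_total), 1)
  flip <- generate_external_sumstats(tr, noise_sd = 0, sign_flip = TRUE)
  expect_equal(cor(flip$effect, tr$beta_total), -1)
  # calibrated noise: r = 1/sqrt(1 + s^2/var(beta))
  s <- 0.02
  rs <- vapply(1:20, function(i) {
    ext <- generate_external_sumstats(tr, noise_sd = s, seed = i)
    cor(ext$effect, tr$beta_total)
  }, numeric(1))
  r_expect <- 1 / sqrt(1 + s^2 / var(tr$beta_total))
  expect_lt(abs(mean(rs) - r_expect), 0.04)
})

test_that("expression counts recover configured cis effects and nulls", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 500, n_cpgs = 400,
                    n_causal = 60, n_smoking_cpgs = 0, seed = 18)
  co <- suppressWarnings(generate_cohort(cfg, 1))
  ex <- generate_expression(cfg, co$methylation, co$truth)
  expect_true(all(ex$counts >= 0))
  expect_equal(colnames(ex$counts), colnames(co$methylation))
  pairs <- ex$pairs_truth[c("cpg_id", "transcript_id")]
  est <- eqtm_regression(pairs, ex$counts, co$methylation, co$samples)
  # active pairs recover the -4.5 log2-CPM coefficient within 2 SE
  act <- est[ex$pairs_truth$effect != 0 & est$flag == "ok", ]
  expect_true(mean(abs(act$effect - (-4.5)) < 2 * act$se) >= 0.8)
  # null pairs centred at zero
  nul <- est[ex$pairs_truth$effect == 0 & est$flag == "ok", ]
  expect_lt(abs(mean(nul$effect)), 2 * mean(nul$se) / sqrt(nrow(nul)) * 3)
})

test_that("simulated tables round-trip through the TSV writers", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  paths <- write_sim_cohort(co, dir, prefix = "t")
  m <- read_matrix_tsv(paths[["methylation"]])
  expect_equal(m, co$methylation, tolerance = 1e-12)
  s <- read_sample_sheet(paths[["samples"]])
  expect_equal(s$sample_id, co$samples$sample_id)
  ann <- read_cpg_bed(paths[["annotation"]])
  expect_equal(ann$pos, co$truth$pos) # 0-based BED -> 1-based positions
  expect_equal(ann$cpg_id, co$truth$cpg_id)
})
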