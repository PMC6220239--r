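test_that("fit_site recovers a noiseless linear exposure effect", {
  samples <- flat_samples(80)
  y <- 0.2 + 0.1 * samples$education_ridit
  d <- design_spec("custom", covariates = character(),
                   se_type = "independence")
  res <- fit_site(y, samples, d)
  expect_equal(res$effect, 0.1, tolerance = 1e-10)
  expect_lt(res$se, 1e-8)
  expect_equal(res$n, 80L)
})

test_that("fit_site equals the normal-equations oracle", {
  set.seed(5)
  samples <- flat_samples(50)
  y <- rnorm(50, 0.5, 0.05)
  d <- design_spec("model1", se_type = "independence")
  res <- fit_site(y, samples, d)
  vars <- c("education_ridit", d$covariates)
  df <- dplyr::mutate(samples[vars],
                      dplyr::across(dplyr::where(is.character), factor))
  X <- stats::model.matrix(stats::reformulate(vars), df)
  beta <- normal_equations_oracle(X, y)
  expect_equal(res$effect, unname(beta["education_ridit", 1]),
               tolerance = 1e-10)
  # oracle SE
  e <- y - X %*% beta
  s2 <- sum(e^2) / (nrow(X) - ncol(X))
  se_o <- sqrt(s2 * solve(t(X) %*% X)["education_ridit", "education_ridit"])
  expect_equal(res$se, se_o, tolerance = 1e-10)
})

test_that("degenerate designs fail per site without crashing run_ewas", {
  samples <- flat_samples(60)
  samples$education_ridit <- 0.5 # constant exposure
  d <- design_spec("custom", covariates = "sex", se_type = "independence")
  expect_error(fit_site(rnorm(60, 0.5, 0.02), samples, d), "rank deficient")

  # run_ewas skips all-missing sites and continues
  samples2 <- flat_samples(60)
  m <- matrix(runif(3 * 60, 0.3, 0.7), nrow = 3,
              dimnames = list(c("cg1", "cg2", "cg3"), samples2$sample_id))
  m["cg2", ] <- NA_real_
  res <- run_ewas(m, samples2, d)
  expect_equal(res$cpg_id, c("cg1", "cg3"))
  expect_equal(attr(res, "skipped")$cpg_id, "cg2")
})

test_that("adding an orthogonal covariate leaves the exposure estimate unchanged", {
  set.seed(8)
  samples <- flat_samples(200)
  y <- 0.4 + 0.05 * samples$education_ridit + rnorm(200, 0, 0.03)
  base <- design_spec("custom", covariates = character(),
                      se_type = "independence")
  b0 <- fit_site(y, samples, base)$effect
  # construct a covariate numerically orthogonal to [1, exposure]
  z <- rnorm(200)
  X <- cbind(1, samples$education_ridit)
  z <- z - X %*% solve(crossprod(X), crossprod(X, z))
  samples$ortho <- as.numeric(z)
  b1 <- fit_site(y, samples, design_spec("custom", covariates = "ortho",
                                         se_type = "independence"))$effect
  expect_equal(b0, b1, tolerance = 1e-8)
})

test_that("vectorised run_ewas agrees with per-site fit_site", {
  co <- tiny_cohort()
  d <- design_spec("model1")
  res <- run_ewas(co$methylation, co$samples, d, cohort = "t")
  for (k in c(1, 7, 42)) {
    single <- fit_site(co$methylation[k, ], co$samples, d)
    expect_equal(res$effect[k], single$effect, tolerance = 1e-10)
    expect_equal(res$se[k], single$se, tolerance = 1e-10)
  }
})

test_that("clustered SEs: singleton clusters equal the HC0 sandwich, duplication scales by sqrt(2)", {
  set.seed(13)
  n <- 120
  X <- cbind(1, rnorm(n))
  y <- 0.3 + 0.1 * X[, 2] + rnorm(n, 0, 0.5)
  beta <- qr.coef(qr(X), y)
  e <- matrix(y - X %*% beta, ncol = 1)
  # singletons: the uncorrected estimator is exactly HC0, the default CR1
  # correction reduces to the HC1 factor n/(n-p)
  se_raw <- clustered_se(X, e, cluster = as.character(seq_len(n)),
                         coef_index = 2, df_correction = FALSE)
  a <- solve(crossprod(X))[, 2]
  se_hc0 <- sqrt(sum((as.vector(X %*% a) * e)^2))
  expect_equal(se_raw, se_hc0, tolerance = 1e-10)
  se_solo <- clustered_se(X, e, cluster = as.character(seq_len(n)),
                          coef_index = 2)
  expect_equal(se_solo, se_hc0 * sqrt(n / (n - 2)), tolerance = 1e-10)

  # duplicating every observation as a 2-cluster ~ sqrt(2) x naive SE
  X2 <- rbind(X, X)
  y2 <- c(y, y)
  b2 <- qr.coef(qr(X2), y2)
  e2 <- matrix(y2 - X2 %*% b2, ncol = 1)
  cl <- rep(seq_len(n), 2)
  se_cl <- clustered_se(X2, e2, cluster = as.character(cl), coef_index = 2)
  s2 <- sum(e2^2) / (2 * n - 2)
  se_naive <- sqrt(s2 * solve(crossprod(X2))[2, 2])
  expect_equal(se_cl / se_naive, sqrt(2), tolerance = 0.15)
})

test_that("clustered SEs match sandwich::vcovCL as an independent oracle", {
  skip_if_not_installed("sandwich")
  set.seed(21)
  n <- 150
  fam <- sample(1:50, n, replace = TRUE)
  x <- rnorm(n)
  u <- rnorm(50)[fam]
  y <- 0.2 * x + u + rnorm(n)
  fit <- lm(y ~ x)
  v <- sandwich::vcovCL(fit, cluster = fam, type = "HC1", cadjust = TRUE)
  X <- model.matrix(fit)
  e <- matrix(residuals(fit), ncol = 1)
  se_pkg <- clustered_se(X, e, cluster = as.character(fam), coef_index = 2)
  expect_equal(se_pkg, sqrt(v[2, 2]), tolerance = 1e-8)
})

test_that("clustered SEs exceed independence SEs under familial correlation", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 100, n_cpgs = 80, n_causal = 40,
                    n_smoking_cpgs = 0, effect_range_education = c(0, 0),
                    effect_range_smoking = c(0, 0),
                    twin_config = list(n_mz_pairs = 120, n_dz_pairs = 0,
                                       familial_variance_share = 1,
                                       confound_sd = 0.05),
                    seed = 31)
  tc <- suppressWarnings(generate_twin_cohort(cfg))
  d_cl <- design_spec("custom", covariates = c("sex", "age_at_blood"))
  d_in <- design_spec("custom", covariates = c("sex", "age_at_blood"),
                      se_type = "independence")
  r_cl <- run_ewas(tc$methylation, tc$samples, d_cl)
  r_in <- run_ewas(tc$methylation, tc$samples, d_in)
  causal <- tc$truth$causal[match(r_cl$cpg_id, tc$truth$cpg_id)]
  expect_gt(mean(r_cl$se[causal]), mean(r_in$se[causal]))
})

test_that("exchangeable estimating equations reduce to OLS for singletons", {
  set.seed(17)
  samples <- flat_samples(60)
  y <- 0.4 + 0.03 * samples$education_ridit + rnorm(60, 0, 0.02)
  d_ex <- design_spec("custom", covariates = "sex", se_type = "exchangeable")
  d_in <- design_spec("custom", covariates = "sex", se_type = "independence")
  r_ex <- fit_site(y, samples, d_ex)
  r_in <- fit_site(y, samples, d_in)
  expect_equal(r_ex$effect, r_in$effect, tolerance = 1e-8)
  expect_equal(r_ex$se, r_in$se, tolerance = 1e-8)
})

test_that("type-I error is nominal under the global null", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 800, n_cpgs = 1500,
                    n_causal = 0, n_smoking_cpgs = 0,
                    effect_range_education = c(0, 0),
                    effect_range_smoking = c(0, 0), seed = 23)
  co <- suppressWarnings(generate_cohort(cfg, 1))
  res <- run_ewas(co$methylation, co$samples, design_spec("model1"))
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.015)
})

test_that("subset rules restrict to never smokers and drop cotinine misclassification", {
  co <- tiny_cohort()
  d_nev <- design_spec("model1", subset = "never_smokers")
  res <- run_ewas(co$methylation[1:5, ], co$samples, d_nev)
  expect_equal(unique(res$n), sum(co$samples$smoking_status == "never"))
  d_cln <- design_spec("model1", subset = "never_smokers_cotinine_clean")
  res2 <- run_ewas(co$methylation[1:5, ], co$samples, d_cln)
  clean_n <- sum(co$samples$smoking_status == "never" &
                   co$samples$cotinine < 15)
  expect_equal(unique(res2$n), clean_n)
  expect_lte(unique(res2$n), unique(res$n))
})

test_that("never-smoker analyses are null when smoking is the only methylation cause", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 2000, n_cpgs = 300,
                    n_causal = 0, n_smoking_cpgs = 150,
                    effect_range_education = c(0, 0), seed = 47)
  co <- suppressWarnings(generate_cohort(cfg, 1))
  d <- design_spec("model1", subset = "never_smokers")
  res <- run_ewas(co$methylation, co$samples, d)
  smk <- co$truth$cpg_id[co$truth$causal_smoking]
  r <- res[res$cpg_id %in% smk, ]
  cover <- mean(abs(r$effect) < 1.96 * r$se)
  expect_gte(cover, 0.93)
})
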