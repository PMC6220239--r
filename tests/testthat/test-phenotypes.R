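test_that("ridit scores follow the cumulative-proportion formula", {
  # degenerate: one category -> everyone at 0.5
  one <- tibble::tibble(education_category = rep(3L, 25))
  expect_equal(unique(ridit_transform(one, strata = character())$education_ridit),
               0.5)

  # two categories 50/50 -> 0.25 and 0.75
  two <- tibble::tibble(education_category = rep(c(1L, 2L), each = 10))
  r2 <- ridit_transform(two, strata = character())
  expect_equal(sort(unique(r2$education_ridit)), c(0.25, 0.75))

  # hand-computed four-category case: p = (.1,.2,.3,.4)
  four <- tibble::tibble(education_category = rep(1:4, c(10, 20, 30, 40)))
  r4 <- ridit_transform(four, strata = character())
  expect_equal(sort(unique(r4$education_ridit)), c(0.05, 0.20, 0.45, 0.80))
})

test_that("ridit scoring is mean-0.5 per stratum, order-invariant, monotone", {
  set.seed(7)
  df <- tibble::tibble(
    sex = sample(c("F", "M"), 400, replace = TRUE),
    birth_year = sample(1930:1989, 400, replace = TRUE),
    education_category = sample(1:7, 400, replace = TRUE,
                                prob = c(3, 8, 7, 28, 6, 28, 20)))
  out <- suppressWarnings(ridit_transform(df))
  spec <- ridit_spec(out)
  # weighted mean 0.5 per stratum
  means <- spec |>
    dplyr::group_by(sex, birth_bin) |>
    dplyr::summarise(m = sum(proportion * ridit), .groups = "drop")
  expect_true(all(abs(means$m - 0.5) < 1e-12))
  # monotone in category within stratum
  mono <- spec |>
    dplyr::group_by(sex, birth_bin) |>
    dplyr::summarise(ok = all(diff(ridit) > 0), .groups = "drop")
  expect_true(all(mono$ok))
  # invariant to row shuffling
  perm <- sample(nrow(df))
  out2 <- suppressWarnings(ridit_transform(df[perm, ]))
  expect_equal(out2$education_ridit, out$education_ridit[perm])
})

test_that("small ridit strata merge with a warning", {
  df <- tibble::tibble(
    sex = "F",
    birth_year = c(rep(1950, 40), rep(1962, 3)),
    education_category = sample(1:7, 43, replace = TRUE))
  expect_warning(out <- ridit_transform(df, min_stratum = 10), "merged")
  expect_equal(nrow(dplyr::distinct(ridit_spec(out), sex, birth_bin)), 1L)
})

test_that("pack-years follows (cpd/20) x years with missing propagation", {
  expect_equal(pack_years(20, 10), 10)
  expect_equal(pack_years(10, 6), 3)
  expect_equal(pack_years(0, 40), 0)
  expect_true(is.na(pack_years(NA, 10)))
  expect_error(pack_years(-1, 5), "non-negative")
})

test_that("cotinine classification partitions [0, Inf) at the cut-offs", {
  expect_equal(as.character(classify_cotinine(c(15, 1, 0.5))),
               c("smoker", "second_hand", "unexposed"))
  expect_true(is.na(classify_cotinine(NA_real_)))
  expect_error(classify_cotinine(-0.1), "non-negative")
  # exhaustive and disjoint over a dense grid
  grid <- c(0, 10^seq(-3, 3, length.out = 200), 14.999999, 15, 1 - 1e-12)
  cls <- classify_cotinine(grid)
  expect_false(anyNA(cls))
  expect_equal(as.character(cls), ifelse(grid >= 15, "smoker",
                                         ifelse(grid >= 1, "second_hand",
                                                "unexposed")))
})

test_that("co-twin maternal smoking reconciliation fills, conflicts, symmetric", {
  r <- reconcile_maternal_smoking(
    c("yes", "yes", "unknown", "no", NA),
    c("missing", "no", "unknown", "no", "yes"))
  expect_equal(r$twin1, c("yes", "missing", "missing", "no", "yes"))
  expect_equal(r$twin2, c("yes", "missing", "missing", "no", "yes"))
  # symmetry in twin order
  a <- sample(c("yes", "no", "unknown", "missing"), 50, replace = TRUE)
  b <- sample(c("yes", "no", "unknown", "missing"), 50, replace = TRUE)
  r1 <- reconcile_maternal_smoking(a, b)
  r2 <- reconcile_maternal_smoking(b, a)
  expect_equal(r1$twin1, r2$twin2)
  expect_equal(r1$twin2, r2$twin1)
})

test_that("methylation smoking score is the weighted beta sum", {
  m <- matrix(c(0.6, 0.2, 0.5, 0.1), nrow = 2,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  w <- tibble::tibble(cpg_id = c("cg1", "cg2"), weight = c(1, -1))
  sc <- methylation_smoking_score(m, w)
  expect_equal(sc$smoking_score, c(0.6 - 0.2, 0.5 - 0.1))
  expect_equal(attr(sc, "n_cpgs_used"), 2L)
  # zero weights -> zero scores
  w0 <- dplyr::mutate(w, weight = 0)
  expect_equal(methylation_smoking_score(m, w0)$smoking_score, c(0, 0))
  # empty intersection fails
  wbad <- tibble::tibble(cpg_id = "cgX", weight = 1)
  expect_error(methylation_smoking_score(m, wbad), "no weight CpGs")
})

test_that("smoking score separates current from never smokers on synthetic data", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 600, n_cpgs = 300,
                    n_causal = 0, n_smoking_cpgs = 60,
                    effect_range_education = c(0, 0), seed = 9)
  co <- suppressWarnings(generate_cohort(cfg, 1))
  tr <- co$truth
  weights <- tibble::tibble(cpg_id = tr$cpg_id[tr$causal_smoking],
                            weight = sign(tr$beta_smoking[tr$causal_smoking]))
  sc <- methylation_smoking_score(co$methylation, weights)
  sm <- co$samples$smoking_status[match(sc$sample_id, co$samples$sample_id)]
  cur <- sc$smoking_score[sm == "current"]
  nev <- sc$smoking_score[sm == "never"]
  # AUC by rank comparison
  auc <- mean(outer(cur, nev, ">") + 0.5 * outer(cur, nev, "=="))
  expect_gt(auc, 0.9)
})
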