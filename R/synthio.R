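#' Demographic profiles of the four study cohorts
#'
#' Per-cohort marginals used by the generator: sample size, percent female,
#' age and BMI moments, birth-year range, smoking-status distribution and the
#' 7-level educational-attainment distribution, for four Dutch
#' population-based biobanks (a twin register and three population cohorts).
#' The education categories run from 1 = primary school only to
#' 7 = university.
#'
#' @return A tibble with one row per cohort.
#' @export
cohort_profiles <- function() {
  prof <- tibble::tibble(
    cohort = c("NTR", "LLS", "RS", "LLD"),
    n = c(2172L, 668L, 608L, 704L),
    pct_female = c(68.6, 52.5, 57.7, 57.7) / 100,
    age_mean = c(38.2, 59.1, 68.6, 47.3),
    age_sd = c(12.6, 6.6, 5.6, 12.5),
    bmi_mean = c(24.4, 25.5, 27.7, 25.5),
    bmi_sd = c(4.0, 3.5, 4.2, 4.2),
    birth_min = c(1926L, 1925L, 1930L, 1931L),
    birth_max = c(1989L, 1974L, 1960L, 1987L),
    p_current = c(19.2, 12.7, 9.4, 18.3) / 100,
    p_former = c(24.3, 55.5, 55.3, 35.8) / 100,
    p_never = c(56.5, 31.7, 35.4, 45.3) / 100
  )
  edu <- rbind(
    c(2.7, 7.6, 7.1, 28.2, 5.6, 27.9, 20.8),
    c(3.9, 22.3, 18.3, 19.2, 3.1, 23.7, 9.6),
    c(15.8, 20.7, 15.8, 23.7, 4.1, 17.6, 2.3),
    c(1.1, 8.4, 11.1, 24.3, 9.2, 32.4, 13.5))
  edu <- edu / rowSums(edu)
  colnames(edu) <- paste0("edu", 1:7)
  prof$sample_year <- round(with(prof, (birth_min + birth_max) / 2 + age_mean))
  dplyr::bind_cols(prof, tibble::as_tibble(edu))
}

#' Configuration for the synthetic multi-cohort generator
#'
#' Collects every knob of the generator. Defaults reproduce the study's
#' statistical structure: four cohorts with the [cohort_profiles()]
#' demographics, education effects on methylation of 0.006 to 0.060 per ridit
#' unit with 76\% positive, smoking (current vs never) effects of -0.18 to
#' 0.07, an education / current-smoking correlation of -0.11, and 30\% of the
#' education effect routed through smoking.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_samples Samples per cohort (scalar or vector of `n_cohorts`).
#' @param n_cpgs,n_causal Number of CpGs and of education-causal CpGs.
#' @param n_smoking_cpgs Additional CpGs carrying a smoking effect only.
#' @param effect_range_education Magnitude range of the *total* education
#'   effect on the beta scale, per ridit unit.
#' @param frac_positive Proportion of causal CpGs with a positive education
#'   effect.
#' @param effect_range_smoking Range of current-vs-never smoking effects on
#'   the beta scale, for the smoking-only CpGs.
#' @param mediation_fraction Proportion of each causal education effect
#'   routed through current smoking.
#' @param education_smoking_corr Target correlation between the education
#'   ridit and current smoking.
#' @param noise_sd Residual beta-scale standard deviation.
#' @param covariate_effects Named list of per-CpG coefficient SDs: `age_sd`
#'   (per year), `sex_sd`, `cell_sd` (per percentage point), `plate_sd`,
#'   `row_sd`.
#' @param effect_jitter_sd Between-cohort SD added to the causal education
#'   effects (default 0: homogeneous effects).
#' @param cotinine List with `misclassified_fraction` (self-reported never
#'   smokers with cotinine >= 15 ng/mL) and `second_hand_fraction` (never
#'   smokers with cotinine in `[1, 15)`).
#' @param twin_config List: `n_mz_pairs`, `n_dz_pairs`,
#'   `familial_variance_share` (share of the confounding pathway that is
#'   shared within a pair), `edu_familial_share` (familial share of the
#'   education latent), `confound_sd` (loading of causal CpGs on the
#'   education latent's confounder; 0 disables confounding),
#'   `force_smoking_discordant` (number of MZ pairs forced current/never).
#' @param expression List: `n_transcripts`, `cis_effect` (log2-CPM per
#'   methylation unit at active cis pairs), `prop_cis_active`, `lognoise_sd`,
#'   `dropout`.
#' @param seed Integer master seed; each cohort derives an independent stream
#'   from it, so adding cohorts does not perturb earlier ones.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 4,
                       n_samples = 2000,
                       n_cpgs = 10000,
                       n_causal = 200,
                       n_smoking_cpgs = 500,
                       effect_range_education = c(0.006, 0.060),
                       frac_positive = 0.76,
                       effect_range_smoking = c(-0.18, 0.07),
                       mediation_fraction = 0.3,
                       education_smoking_corr = -0.11,
                       noise_sd = 0.04,
                       covariate_effects = list(),
                       effect_jitter_sd = 0,
                       cotinine = list(),
                       twin_config = list(),
                       expression = list(),
                       seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_samples = as.integer(n_samples),
    n_cpgs = as.integer(n_cpgs),
    n_causal = as.integer(n_causal),
    n_smoking_cpgs = as.integer(n_smoking_cpgs),
    effect_range_education = effect_range_education,
    frac_positive = frac_positive,
    effect_range_smoking = effect_range_smoking,
    mediation_fraction = mediation_fraction,
    education_smoking_corr = education_smoking_corr,
    noise_sd = noise_sd,
    covariate_effects = utils::modifyList(
      list(age_sd = 3e-4, sex_sd = 0.005, cell_sd = 5e-4,
           plate_sd = 0.003, row_sd = 0.002),
      covariate_effects),
    effect_jitter_sd = effect_jitter_sd,
    cotinine = utils::modifyList(
      list(misclassified_fraction = 5 / 591,
           second_hand_fraction = 150 / 586),
      cotinine),
    twin_config = utils::modifyList(
      list(n_mz_pairs = 492L, n_dz_pairs = 247L,
           familial_variance_share = 0.5, edu_familial_share = 0.5,
           confound_sd = 0, force_smoking_discordant = 0L),
      twin_config),
    expression = utils::modifyList(
      list(n_transcripts = 2000L, cis_effect = -4.5, prop_cis_active = 0.5,
           lognoise_sd = 0.3, dropout = 0),
      expression),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  in01 <- function(x) all(x >= 0 & x <= 1)
  stopifnot(
    cfg$n_cohorts >= 1, all(cfg$n_samples >= 1), cfg$n_cpgs >= 1,
    cfg$n_causal >= 0, cfg$n_causal <= cfg$n_cpgs,
    cfg$n_smoking_cpgs >= 0,
    cfg$n_causal + cfg$n_smoking_cpgs <= cfg$n_cpgs,
    length(cfg$effect_range_education) == 2,
    diff(cfg$effect_range_education) >= 0,
    all(cfg$effect_range_education >= 0),
    length(cfg$effect_range_smoking) == 2,
    diff(cfg$effect_range_smoking) >= 0,
    in01(cfg$frac_positive), in01(cfg$mediation_fraction),
    cfg$mediation_fraction < 1,
    abs(cfg$education_smoking_corr) < 1,
    cfg$noise_sd > 0,
    in01(cfg$cotinine$misclassified_fraction),
    in01(cfg$cotinine$second_hand_fraction),
    in01(cfg$twin_config$familial_variance_share),
    in01(cfg$twin_config$edu_familial_share))
  invisible(cfg)
}

# Per-cohort RNG stream derived from the master seed; stays inside 32-bit
# integer range.
cohort_seed <- function(seed, cohort_index) {
  as.integer((as.numeric(seed) * 1009 + cohort_index * 7919 + 1) %% 2147483647)
}

# Study-level ground truth: CpG ids, genomic annotation, which CpGs carry
# education and/or smoking effects, and the per-CpG covariate coefficients.
# Deterministic given the config (fresh stream from the master seed), so
# every cohort sees the same biology.
sim_truth <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  m <- config$n_cpgs
  cpg_id <- sprintf("cpg%06d", seq_len(m))
  chrom <- sample(paste0("chr", 1:22), m, replace = TRUE)
  pos <- sample.int(2e8, m, replace = TRUE)

  causal <- sample.int(m, config$n_causal)
  smoking_only <- sample(setdiff(seq_len(m), causal), config$n_smoking_cpgs)

  beta_total <- numeric(m)
  sgn <- ifelse(stats::runif(config$n_causal) < config$frac_positive, 1, -1)
  beta_total[causal] <- sgn * stats::runif(
    config$n_causal,
    config$effect_range_education[1], config$effect_range_education[2])
  beta_direct <- (1 - config$mediation_fraction) * beta_total

  beta_smoking_extra <- numeric(m)
  beta_smoking_extra[smoking_only] <- stats::runif(
    config$n_smoking_cpgs,
    config$effect_range_smoking[1], config$effect_range_smoking[2])

  ce <- config$covariate_effects
  base <- stats::runif(m, 0.10, 0.90)
  affected <- union(causal, smoking_only)
  base[affected] <- stats::runif(length(affected), 0.25, 0.75)

  tibble::tibble(
    cpg_id = cpg_id, chrom = chrom, pos = pos,
    causal = seq_len(m) %in% causal,
    causal_smoking = seq_len(m) %in% smoking_only,
    beta_total = beta_total,
    beta_direct = beta_direct,
    beta_smoking_extra = beta_smoking_extra,
    base = base,
    age_coef = stats::rnorm(m, 0, ce$age_sd),
    sex_coef = stats::rnorm(m, 0, ce$sex_sd),
    neutrophil_coef = stats::rnorm(m, 0, ce$cell_sd),
    monocyte_coef = stats::rnorm(m, 0, ce$cell_sd),
    eosinophil_coef = stats::rnorm(m, 0, ce$cell_sd)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Calibrate a logistic model P(current | ridit) = plogis(a + b * ridit) to a
# target prevalence and target point-biserial correlation, by nested root
# finding on the expected moments given the realized ridit values.
calibrate_smoking <- function(ridit, p_target, r_target) {
  rbar <- mean(ridit)
  sdr <- stats::sd(ridit)
  if (r_target != 0 && (is.na(sdr) || sdr == 0)) {
    stop("cannot reach a nonzero education-smoking correlation: the ridit ",
         "score is constant", call. = FALSE)
  }
  intercept_for <- function(b) {
    lim <- 40 + abs(b)
    stats::uniroot(function(a) mean(stats::plogis(a + b * ridit)) - p_target,
                   c(-lim, lim), tol = 1e-10)$root
  }
  expected_corr <- function(b) {
    a <- intercept_for(b)
    p <- stats::plogis(a + b * ridit)
    pbar <- mean(p)
    cv <- mean(p * (ridit - rbar))
    cv / (sqrt(pbar * (1 - pbar)) * sdr)
  }
  if (r_target == 0) {
    return(c(a = stats::qlogis(p_target), b = 0))
  }
  lim <- 60
  f_lo <- expected_corr(-lim) - r_target
  f_hi <- expected_corr(lim) - r_target
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(
      "correlation target %.3f is not achievable for prevalence %.3f given ",
      r_target, p_target), "the ridit marginals", call. = FALSE)
  }
  b <- stats::uniroot(function(b) expected_corr(b) - r_target,
                      c(-lim, lim), tol = 1e-8)$root
  c(a = intercept_for(b), b = b)
}

# Shared sample-sheet machinery for one cohort.
draw_demographics <- function(n, profile, cohort_label) {
  sex <- ifelse(stats::runif(n) < profile$pct_female, "F", "M")
  age <- pmin(pmax(stats::rnorm(n, profile$age_mean, profile$age_sd), 18), 95)
  birth_year <- pmin(pmax(round(profile$sample_year - age),
                          profile$birth_min), profile$birth_max)
  age <- profile$sample_year - birth_year
  edu_p <- as.numeric(profile[paste0("edu", 1:7)])
  education_category <- sample.int(7, n, replace = TRUE, prob = edu_p)
  tibble::tibble(
    sample_id = sprintf("%s_%05d", cohort_label, seq_len(n)),
    cohort = cohort_label,
    sex = sex,
    birth_year = as.integer(birth_year),
    age_at_blood = as.numeric(age),
    education_category = education_category,
    bmi = pmin(pmax(stats::rnorm(n, profile$bmi_mean, profile$bmi_sd), 15), 60)
  )
}

draw_smoking <- function(samples, profile, config) {
  n <- nrow(samples)
  ab <- calibrate_smoking(samples$education_ridit, profile$p_current,
                          config$education_smoking_corr)
  p_cur <- stats::plogis(ab["a"] + ab["b"] * samples$education_ridit)
  current <- stats::runif(n) < p_cur
  p_former_given_not <- min(profile$p_former / (1 - profile$p_current), 1)
  former <- !current & stats::runif(n) < p_former_given_not
  status <- ifelse(current, "current", ifelse(former, "former", "never"))

  ever <- status != "never"
  cpd <- ifelse(ever, pmax(1, round(stats::rlnorm(n, log(12), 0.5))), 0)
  yrs <- ifelse(ever,
                pmax(1, round(stats::runif(n, 0.3, 0.9) *
                                pmax(samples$age_at_blood - 16, 1))), 0)
  cot <- config$cotinine
  u <- stats::runif(n)
  cotinine <- ifelse(
    current,
    15 + stats::rlnorm(n, log(135), 0.8),
    ifelse(u < cot$misclassified_fraction,
           15 + stats::rlnorm(n, log(50), 0.5),
           ifelse(u < cot$misclassified_fraction + cot$second_hand_fraction,
                  1 + 13.9 * stats::rbeta(n, 1.2, 4),
                  stats::runif(n, 0.01, 0.99))))

  dplyr::mutate(samples,
                smoking_status = status,
                cigarettes_per_day = cpd,
                years_smoked = yrs,
                pack_years = pack_years(cpd, yrs),
                cotinine = cotinine,
                maternal_smoking = sample(
                  c("yes", "no", "unknown", "missing"), n, replace = TRUE,
                  prob = c(0.08, 0.72, 0.10, 0.10)))
}

draw_cells_and_tech <- function(samples) {
  n <- nrow(samples)
  neut <- pmax(stats::rnorm(n, 55, 8), 1)
  mono <- pmax(stats::rnorm(n, 8, 2), 0.2)
  eos <- pmax(stats::rnorm(n, 2.7, 1.5), 0)
  lymp <- pmax(stats::rnorm(n, 32, 7), 1)
  n_plates <- max(1L, ceiling(n / 96))
  plate <- sample(sprintf("plate%02d", seq_len(n_plates)), n, replace = TRUE)
  arow <- sample(sprintf("r%02d", 1:6), n, replace = TRUE)
  dplyr::mutate(samples,
                neutrophil_pct = neut, monocyte_pct = mono,
                eosinophil_pct = eos, lymphocyte_pct = lymp,
                granulocyte_pct = neut + eos,
                plate = plate, array_row = arow)
}

# Assemble the beta-value matrix from truth + sample sheet. Returns the
# matrix plus the realized clipping fraction.
build_methylation <- function(truth, samples, config, beta_direct,
                              beta_smoking, extra = NULL) {
  m <- nrow(truth)
  n <- nrow(samples)
  ce <- config$covariate_effects
  M <- truth$base + matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)

  idx_e <- which(beta_direct != 0)
  if (length(idx_e)) {
    M[idx_e, ] <- M[idx_e, ] +
      outer(beta_direct[idx_e], samples$education_ridit)
  }
  cur <- as.numeric(samples$smoking_status == "current")
  idx_s <- which(beta_smoking != 0)
  if (length(idx_s)) {
    M[idx_s, ] <- M[idx_s, ] + outer(beta_smoking[idx_s], cur)
  }
  coef_mat <- cbind(truth$age_coef, truth$sex_coef, truth$neutrophil_coef,
                    truth$monocyte_coef, truth$eosinophil_coef)
  cov_mat <- cbind(samples$age_at_blood - 50,
                   as.numeric(samples$sex == "F"),
                   samples$neutrophil_pct - 55,
                   samples$monocyte_pct - 8,
                   samples$eosinophil_pct - 2.7)
  M <- M + tcrossprod(coef_mat, cov_mat)
  plates <- sort(unique(samples$plate))
  pe <- matrix(stats::rnorm(m * length(plates), 0, ce$plate_sd),
               m, length(plates))
  M <- M + pe[, match(samples$plate, plates), drop = FALSE]
  rows <- sort(unique(samples$array_row))
  re <- matrix(stats::rnorm(m * length(rows), 0, ce$row_sd), m, length(rows))
  M <- M + re[, match(samples$array_row, rows), drop = FALSE]
  if (!is.null(extra)) M <- M + extra

  clipped <- sum(M < 0 | M > 1)
  M[M < 0] <- 0
  M[M > 1] <- 1
  dimnames(M) <- list(truth$cpg_id, samples$sample_id)
  list(beta = M, clip_fraction = clipped / length(M))
}

# Route the configured mediated fraction through current smoking: the smoking
# coefficient at causal CpGs is chosen so that, for the realized
# education->smoking slope gamma in this sample, indirect = gamma * beta_smk
# equals mediation_fraction * beta_total exactly.
mediated_smoking_coef <- function(truth, samples, config) {
  beta_smoking <- truth$beta_smoking_extra
  mf <- config$mediation_fraction
  if (mf > 0 && any(truth$beta_direct != 0)) {
    cur <- as.numeric(samples$smoking_status == "current")
    gamma <- stats::cov(cur, samples$education_ridit) /
      stats::var(samples$education_ridit)
    if (!is.finite(gamma) || abs(gamma) < 1e-6) {
      stop("education->smoking path is numerically zero; cannot route the ",
           "configured mediation fraction", call. = FALSE)
    }
    beta_smoking <- beta_smoking +
      truth$beta_direct * (mf / (1 - mf)) / gamma
  }
  list(beta_smoking = beta_smoking,
       gamma = if (exists("gamma", inherits = FALSE)) gamma else NA_real_)
}

#' Generate one synthetic population cohort
#'
#' Draws a sample sheet (demographics, 7-level education, ridit scores,
#' smoking phenotypes with the configured education-smoking correlation,
#' cotinine consistent with status, BMI, blood-cell percentages, plate and
#' array-row labels) and a CpG x sample beta-value matrix
#' `clip(base + beta_edu * ridit + beta_smk * current + covariates + noise,
#' 0, 1)` from the study-level ground truth. Each cohort uses its own RNG
#' stream derived from the master seed.
#'
#' @param config A [sim_config()].
#' @param cohort_index 1-based cohort number; selects the matching
#'   [cohort_profiles()] row (recycled beyond four).
#' @param profile Optional one-row profile tibble overriding the default.
#' @return A list with `samples` (tibble), `methylation` (matrix), `truth`
#'   (per-CpG tibble with the cohort's realized effects: `beta_direct`,
#'   `beta_smoking`, `beta_indirect`, `beta_total`, causal flags) and
#'   `clip_fraction`.
#' @export
generate_cohort <- function(config, cohort_index = 1, profile = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  if (is.null(profile)) {
    profs <- cohort_profiles()
    profile <- profs[(cohort_index - 1) %% nrow(profs) + 1, ]
  }
  n <- config$n_samples[min(cohort_index, length(config$n_samples))]
  set.seed(cohort_seed(config$seed, cohort_index))

  label <- paste0("c", cohort_index, profile$cohort)
  samples <- draw_demographics(n, profile, label)
  samples <- ridit_transform(samples)
  rspec <- ridit_spec(samples)
  samples <- draw_smoking(samples, profile, config)
  samples <- draw_cells_and_tech(samples)
  samples$family_id <- NA_character_
  samples$zygosity <- "none"

  beta_direct <- truth$beta_direct
  if (config$effect_jitter_sd > 0) {
    jit <- stats::rnorm(sum(truth$causal), 0, config$effect_jitter_sd)
    beta_direct[truth$causal] <- beta_direct[truth$causal] + jit
  }
  ms <- mediated_smoking_coef(
    dplyr::mutate(truth, beta_direct = beta_direct), samples, config)
  meth <- build_methylation(truth, samples, config, beta_direct,
                            ms$beta_smoking)

  truth_out <- truth |>
    dplyr::mutate(
      beta_direct = beta_direct,
      beta_smoking = ms$beta_smoking,
      beta_indirect = dplyr::if_else(
        .data$causal, .data$beta_direct *
          config$mediation_fraction / (1 - config$mediation_fraction), 0),
      beta_total = .data$beta_direct + .data$beta_indirect) |>
    dplyr::select(-"beta_smoking_extra")

  list(samples = samples, methylation = meth$beta, truth = truth_out,
       ridit_spec = rspec, clip_fraction = meth$clip_fraction,
       gamma_edu_smoking = ms$gamma)
}

#' Generate a synthetic twin cohort
#'
#' Builds complete MZ and DZ pairs. Each pair shares a familial component
#' fully; the genetic component is shared fully in MZ pairs and at one half
#' in DZ pairs. The education latent loads on the shared component with
#' weight `edu_familial_share`; causal CpGs optionally load on a confounder
#' built from the same latent (`confound_sd`), of which a share
#' `familial_variance_share` is the within-pair shared part — at share 1,
#' within-MZ-pair regressions see none of the confounding.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()], with `family_id`, `zygosity` filled and a
#'   `beta_confound` column in the truth table.
#' @export
generate_twin_cohort <- function(config, profile = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tw <- config$twin_config
  truth <- sim_truth(config)
  if (is.null(profile)) profile <- cohort_profiles()[1, ]
  n_pairs <- tw$n_mz_pairs + tw$n_dz_pairs
  set.seed(cohort_seed(config$seed, 524287))
  if (n_pairs == 0) {
    empty <- draw_demographics(0, profile, "twin")
    return(list(samples = dplyr::mutate(empty,
                                        education_ridit = numeric(0),
                                        smoking_status = character(0),
                                        cigarettes_per_day = numeric(0),
                                        years_smoked = numeric(0),
                                        pack_years = numeric(0),
                                        cotinine = numeric(0),
                                        maternal_smoking = character(0),
                                        neutrophil_pct = numeric(0),
                                        monocyte_pct = numeric(0),
                                        eosinophil_pct = numeric(0),
                                        lymphocyte_pct = numeric(0),
                                        granulocyte_pct = numeric(0),
                                        plate = character(0),
                                        array_row = character(0),
                                        family_id = character(0),
                                        zygosity = character(0)),
                methylation = matrix(numeric(0), nrow = config$n_cpgs,
                                     ncol = 0,
                                     dimnames = list(truth$cpg_id, NULL)),
                truth = truth, clip_fraction = 0))
  }
  n <- 2L * n_pairs
  zyg_pair <- rep(c("MZ", "DZ"), c(tw$n_mz_pairs, tw$n_dz_pairs))
  pair_id <- sprintf("fam%05d", seq_len(n_pairs))

  # shared-vs-unique latents
  c_pair <- stats::rnorm(n_pairs)
  g_shared <- stats::rnorm(n_pairs)
  g_ind <- matrix(stats::rnorm(2 * n_pairs), n_pairs, 2)
  g <- matrix(NA_real_, n_pairs, 2)
  mz <- zyg_pair == "MZ"
  g[mz, ] <- g_shared[mz]
  g[!mz, ] <- sqrt(0.5) * g_shared[!mz] + sqrt(0.5) * g_ind[!mz, ]
  f_twin <- (c_pair + g) / sqrt(2) # n_pairs x 2, var 1

  h <- tw$edu_familial_share
  e_twin <- matrix(stats::rnorm(n), n_pairs, 2)
  latent <- sqrt(h) * f_twin + sqrt(1 - h) * e_twin

  # pair-shared demographics, individual education from the latent
  samples <- draw_demographics(n, profile, "twin")
  pair_of <- rep(seq_len(n_pairs), each = 2)
  member <- rep(1:2, n_pairs)
  samples$sex <- samples$sex[pair_of * 2 - 1]
  samples$birth_year <- samples$birth_year[pair_of * 2 - 1]
  samples$age_at_blood <- samples$age_at_blood[pair_of * 2 - 1]
  samples$family_id <- pair_id[pair_of]
  samples$zygosity <- zyg_pair[pair_of]

  edu_p <- as.numeric(profile[paste0("edu", 1:7)])
  cuts <- stats::qnorm(cumsum(edu_p)[-7])
  lat_vec <- as.vector(t(latent)) # twin1, twin2, twin1, ...
  samples$education_category <- findInterval(lat_vec, cuts) + 1L
  samples <- ridit_transform(samples)
  samples <- draw_smoking(samples, profile, config)
  samples <- draw_cells_and_tech(samples)

  k <- min(tw$force_smoking_discordant, tw$n_mz_pairs)
  if (k > 0) {
    forced <- which(samples$zygosity == "MZ")[seq_len(2 * k)]
    samples$smoking_status[forced] <-
      rep(c("current", "never"), k)
  }

  ms <- mediated_smoking_coef(truth, samples, config)
  confounder <- sqrt(tw$familial_variance_share) * as.vector(t(f_twin)) +
    sqrt(1 - tw$familial_variance_share) * as.vector(t(e_twin))
  beta_confound <- ifelse(truth$causal, tw$confound_sd, 0)
  extra <- if (tw$confound_sd > 0) outer(beta_confound, confounder) else NULL

  meth <- build_methylation(truth, samples, config, truth$beta_direct,
                            ms$beta_smoking, extra = extra)
  truth_out <- truth |>
    dplyr::mutate(
      beta_smoking = ms$beta_smoking,
      beta_confound = beta_confound,
      beta_indirect = dplyr::if_else(
        .data$causal, .data$beta_direct *
          config$mediation_fraction / (1 - config$mediation_fraction), 0),
      beta_total = .data$beta_direct + .data$beta_indirect) |>
    dplyr::select(-"beta_smoking_extra")
  list(samples = samples, methylation = meth$beta, truth = truth_out,
       clip_fraction = meth$clip_fraction, gamma_edu_smoking = ms$gamma)
}

#' Generate synthetic expression counts with designated cis pairs
#'
#' Places transcripts on the genome, half of them within 50 kb of causal
#' CpGs, and draws RNA-seq-like counts whose log2 counts-per-million mean is
#' linear in the paired CpG's methylation for the active cis pairs.
#'
#' @param config A [sim_config()].
#' @param methylation Beta-value matrix from [generate_cohort()].
#' @param truth The matching truth tibble (for CpG positions).
#' @return List with `counts` (transcripts x samples), `annotation`
#'   (`transcript_id`, `chrom`, `start`, `end`) and `pairs_truth`
#'   (`transcript_id`, `cpg_id`, `effect` in log2-CPM per methylation unit).
#' @export
generate_expression <- function(config, methylation, truth) {
  ex <- config$expression
  set.seed(cohort_seed(config$seed, 131071))
  n_tx <- ex$n_transcripts
  n_samp <- ncol(methylation)
  causal_idx <- which(truth$causal)
  n_cis <- min(n_tx %/% 2, length(causal_idx))
  cis_cpg <- if (n_cis > 0) sample(causal_idx, n_cis) else integer(0)

  tx_id <- sprintf("tx%05d", seq_len(n_tx))
  chrom <- character(n_tx)
  start <- integer(n_tx)
  if (n_cis > 0) {
    chrom[seq_len(n_cis)] <- truth$chrom[cis_cpg]
    start[seq_len(n_cis)] <- pmax(
      truth$pos[cis_cpg] + sample(-5e4:5e4, n_cis, replace = TRUE), 1)
  }
  rest <- (n_cis + 1):n_tx
  chrom[rest] <- sample(paste0("chr", 1:22), length(rest), replace = TRUE)
  start[rest] <- sample.int(2e8, length(rest), replace = TRUE)

  effect <- numeric(n_tx)
  if (n_cis > 0) {
    active <- seq_len(n_cis)[stats::runif(n_cis) < ex$prop_cis_active]
    effect[active] <- ex$cis_effect
  }

  base_l2 <- stats::runif(n_tx, 3, 8)
  mu <- matrix(base_l2, n_tx, n_samp)
  if (n_cis > 0) {
    mu[seq_len(n_cis), ] <- mu[seq_len(n_cis), ] +
      effect[seq_len(n_cis)] *
        (methylation[cis_cpg, , drop = FALSE] - 0.5)
  }
  mu <- mu + matrix(stats::rnorm(n_tx * n_samp, 0, ex$lognoise_sd),
                    n_tx, n_samp)
  # scale so the simulated transcripts compose the whole library: their
  # baseline CPMs sum to 1e6, keeping every transcript a small share of the
  # realized library (as in genome-wide RNA-seq)
  scale_cpm <- 1e6 / sum(2^base_l2)
  lib <- round(stats::rlnorm(n_samp, log(1e6), 0.2))
  lambda <- sweep(scale_cpm * 2^mu / 1e6, 2, lib, `*`)
  counts <- matrix(stats::rpois(n_tx * n_samp, lambda), n_tx, n_samp,
                   dimnames = list(tx_id, colnames(methylation)))
  if (ex$dropout > 0) {
    counts[matrix(stats::runif(length(counts)) < ex$dropout,
                  nrow(counts))] <- 0L
  }
  list(
    counts = counts,
    annotation = tibble::tibble(transcript_id = tx_id, chrom = chrom,
                                start = start, end = start + 1000L),
    pairs_truth = tibble::tibble(
      transcript_id = tx_id[seq_len(n_cis)],
      cpg_id = truth$cpg_id[cis_cpg],
      effect = effect[seq_len(n_cis)])
  )
}

#' Generate an external summary-statistics table correlated with truth
#'
#' Adds Gaussian noise (and optionally a sign flip) to the true per-CpG
#' effects, emulating a previously published EWAS of a correlated exposure.
#' With noise of standard deviation \eqn{s} added to effects of variance
#' \eqn{v}, the expected correlation with truth is \eqn{1/\sqrt{1 + s^2/v}}.
#'
#' @param truth Truth tibble from [generate_cohort()].
#' @param noise_sd Noise standard deviation on the effect scale.
#' @param sign_flip Negate the external effects (an anti-correlated
#'   exposure).
#' @param effect_col Column of `truth` used as the underlying effect.
#' @param source Label stored in the `source` column.
#' @param seed Optional seed for the noise draw.
#' @return Tibble `cpg_id`, `effect`, `source`.
#' @export
generate_external_sumstats <- function(truth, noise_sd = 0, sign_flip = FALSE,
                                       effect_col = "beta_total",
                                       source = "external", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- truth[[effect_col]] + stats::rnorm(nrow(truth), 0, noise_sd)
  if (sign_flip) eff <- -eff
  tibble::tibble(cpg_id = truth$cpg_id, effect = eff, source = source)
}
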