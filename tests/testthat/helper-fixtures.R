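# Small configurations and fixtures shared across tests. Everything is
# generated in code; seeds are fixed so expectations are stable.

tiny_config <- function(..., seed = 42) {
  sim_config(n_cohorts = 2, n_samples = 300, n_cpgs = 150, n_causal = 15,
             n_smoking_cpgs = 15, seed = seed, ...)
}

tiny_cohort <- function(cohort_index = 1, config = tiny_config()) {
  suppressWarnings(generate_cohort(config, cohort_index))
}

# Deterministic hand-built sample sheet for unit tests that do not need the
# generator.
flat_samples <- function(n = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    cohort = "test",
    sex = sample(c("F", "M"), n, replace = TRUE),
    birth_year = sample(1940:1980, n, replace = TRUE),
    age_at_blood = runif(n, 25, 70),
    education_category = sample(1:7, n, replace = TRUE),
    education_ridit = runif(n, 0.01, 0.99),
    smoking_status = sample(c("current", "former", "never"), n,
                            replace = TRUE),
    bmi = rnorm(n, 25, 3),
    neutrophil_pct = rnorm(n, 55, 5),
    monocyte_pct = rnorm(n, 8, 1.5),
    eosinophil_pct = rnorm(n, 2.7, 1),
    lymphocyte_pct = rnorm(n, 32, 5),
    plate = sample(c("p1", "p2"), n, replace = TRUE),
    array_row = sample(c("r1", "r2", "r3"), n, replace = TRUE),
    family_id = NA_character_,
    zygosity = "none")
}

# Closed-form least-squares oracle: coefficients via explicit normal
# equations, independent of the package's QR path.
normal_equations_oracle <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}
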