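#' Validate sample sheets and matrices before analysis
#'
#' Report-only schema and range checks: required columns, id uniqueness,
#' beta values inside `[0, 1]`, education categories inside 1-7, ridits in
#' (0, 1), negative pack-years or cotinine, and sample alignment between the
#' sheet and the matrices.
#'
#' @param samples Sample sheet.
#' @param methylation Optional beta matrix.
#' @param expression Optional count matrix.
#' @return Tibble `check`, `n_violations`, `detail`; zero rows means no
#'   violations.
#' @export
validate_inputs <- function(samples, methylation = NULL, expression = NULL) {
  out <- list()
  note <- function(check, n, detail = "") {
    if (n > 0) out[[length(out) + 1]] <<-
        tibble::tibble(check = check, n_violations = as.integer(n),
                       detail = detail)
  }
  if (!"sample_id" %in% names(samples)) {
    note("sample_id_column", 1L, "column missing")
  } else {
    note("sample_id_unique", sum(duplicated(samples$sample_id)),
         "duplicated sample ids")
  }
  if ("education_category" %in% names(samples)) {
    bad <- !is.na(samples$education_category) &
      (samples$education_category < 1 | samples$education_category > 7 |
         samples$education_category != round(samples$education_category))
    note("education_category_range", sum(bad), "outside 1-7")
  }
  if ("education_ridit" %in% names(samples)) {
    bad <- !is.na(samples$education_ridit) &
      (samples$education_ridit <= 0 | samples$education_ridit >= 1)
    note("education_ridit_range", sum(bad), "outside (0,1)")
  }
  for (col in c("pack_years", "cotinine")) {
    if (col %in% names(samples)) {
      note(paste0(col, "_nonnegative"),
           sum(!is.na(samples[[col]]) & samples[[col]] < 0), "negative values")
    }
  }
  if (!is.null(methylation)) {
    bad <- !is.na(methylation) & (methylation < 0 | methylation > 1)
    note("beta_range", sum(bad), "beta values outside [0,1]")
    note("cpg_id_unique", sum(duplicated(rownames(methylation))),
         "duplicated CpG ids")
    if ("sample_id" %in% names(samples)) {
      note("methylation_alignment",
           sum(!colnames(methylation) %in% samples$sample_id),
           "matrix columns missing from sample sheet")
    }
  }
  if (!is.null(expression)) {
    note("counts_nonnegative", sum(expression < 0, na.rm = TRUE),
         "negative counts")
    if ("sample_id" %in% names(samples)) {
      note("expression_alignment",
           sum(!colnames(expression) %in% samples$sample_id),
           "matrix columns missing from sample sheet")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(check = character(), n_violations = integer(),
                          detail = character()))
  }
  dplyr::bind_rows(out)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates the stages end to end on generated data: cohort simulation,
#' ridit scoring (inside the generator), per-cohort EWAS under the requested
#' models, per-cohort bias/inflation correction, fixed-effects meta-analysis
#' with a second bias/inflation correction at the meta level, mediation
#' (model 1 vs model 2), twin-pair discordance regression, comparison with a
#' generated external summary-statistics table, cis eQTM association on
#' generated expression, and the power calculation. Deterministic given the
#' config; a manifest records seeds, sizes and thresholds.
#'
#' @param config A [sim_config()]. Small configs run in seconds.
#' @param models Model tags to fit. Default `c("model1", "model2")`.
#' @param bacon_cohort,bacon_meta Apply the mixture-model correction per
#'   cohort / to the meta z-statistics. Defaults `TRUE` (both fits are kept
#'   in the result).
#' @param mixture_iterations,mixture_burnin Gibbs settings for the
#'   correction fits.
#' @param run_twins,run_expression,run_crossref Stage toggles.
#' @param fwer Family-wise error rate for significance calls.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV and the manifest as JSON.
#' @return Named list: `cohorts` (generated data), `ewas` (per cohort x
#'   model), `bacon_fits`, `meta` (per model), `mediation`, `twin`,
#'   `crossref`, `eqtm`, `power`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         models = c("model1", "model2"),
                         bacon_cohort = TRUE,
                         bacon_meta = TRUE,
                         mixture_iterations = 2000,
                         mixture_burnin = 800,
                         run_twins = TRUE,
                         run_expression = TRUE,
                         run_crossref = TRUE,
                         fwer = 0.05,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohorts <- purrr::map(seq_len(config$n_cohorts),
                        function(i) generate_cohort(config, i))
  names(cohorts) <- purrr::map_chr(cohorts, ~ .x$samples$cohort[1])

  ewas <- list()
  bacon_fits <- list()
  meta <- list()
  for (mod in models) {
    per_cohort <- purrr::imap(cohorts, function(co, nm) {
      res <- run_ewas(co$methylation, co$samples, design_spec(model = mod),
                      cohort = nm)
      if (bacon_cohort) {
        fit <- fit_mixture(res$z, iterations = mixture_iterations,
                           burnin = mixture_burnin,
                           seed = cohort_seed(config$seed, 1e4 + match(nm, names(cohorts))))
        bacon_fits[[paste(mod, nm, sep = ".")]] <<- fit
        res <- bacon_correct(res, fit)
      }
      res
    })
    ewas[[mod]] <- per_cohort
    mt <- fixed_effects_meta(dplyr::bind_rows(per_cohort), fwer = fwer)
    if (bacon_meta) {
      fit <- fit_mixture(mt$z, iterations = mixture_iterations,
                         burnin = mixture_burnin,
                         seed = cohort_seed(config$seed, 2e4 + match(mod, models)))
      bacon_fits[[paste(mod, "meta", sep = ".")]] <- fit
      mt <- bacon_correct(mt, fit)
      thr <- attr(mt, "p_threshold")
      mt$significant <- mt$p < thr
    }
    meta[[mod]] <- mt
  }

  mediation <- if (all(c("model1", "model2") %in% models)) {
    mediate(meta$model1, meta$model2)
  }

  twin <- NULL
  if (run_twins && (config$twin_config$n_mz_pairs +
                      config$twin_config$n_dz_pairs) > 0) {
    tc <- generate_twin_cohort(config)
    pairs <- build_pairs(tc$samples)
    wp <- within_pair_regression(pairs, tc$samples, tc$methylation,
                                 cpg_ids = tc$truth$cpg_id[tc$truth$causal],
                                 adjust_smoking = TRUE)
    twin <- list(cohort = tc, pairs = pairs, within_pair = wp)
  }

  crossref <- NULL
  if (run_crossref && "model1" %in% models) {
    ext <- generate_external_sumstats(
      cohorts[[1]]$truth, noise_sd = 0.01,
      seed = cohort_seed(config$seed, 3e4))
    causal_ids <- cohorts[[1]]$truth$cpg_id[cohorts[[1]]$truth$causal]
    crossref <- list(
      external = ext,
      correlation = correlate_effects(meta$model1, ext,
                                      site_filter = causal_ids))
  }

  eqtm <- NULL
  if (run_expression) {
    co <- cohorts[[1]]
    expr <- generate_expression(config, co$methylation, co$truth)
    counts <- filter_transcripts(expr$counts)
    causal_annot <- dplyr::filter(co$truth, .data$causal)
    pairs <- pair_cis(causal_annot, expr$annotation)
    pairs <- dplyr::filter(pairs, .data$transcript_id %in% rownames(counts))
    est <- eqtm_regression(pairs, counts, co$methylation, co$samples)
    thr <- bonferroni_threshold(sum(est$flag == "ok"), fwer = fwer)
    est$significant <- !is.na(est$p) & est$p < thr
    eqtm <- list(expression = expr, results = est, p_threshold = thr)
  }

  power <- tibble::tibble(
    r_squared = 0.01, alpha = 1e-7, target_power = 0.8,
    required_n = required_n(0.01, alpha = 1e-7, power = 0.8))

  manifest <- tibble::tibble(
    stage = c("simulate", "ewas", "meta", "power"),
    detail = c(
      sprintf("%d cohorts x %s samples, %d CpGs (%d causal), seed %d",
              config$n_cohorts,
              paste(config$n_samples, collapse = "/"),
              config$n_cpgs, config$n_causal, config$seed),
      sprintf("models: %s; bacon per cohort: %s", paste(models, collapse = ","),
              bacon_cohort),
      sprintf("fwer %.3g; bacon at meta: %s", fwer, bacon_meta),
      sprintf("required n = %d", power$required_n)))

  out <- list(cohorts = cohorts, ewas = ewas, bacon_fits = bacon_fits,
              meta = meta, mediation = mediation, twin = twin,
              crossref = crossref, eqtm = eqtm, power = power,
              manifest = manifest, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(out$meta)) {
    readr::write_tsv(out$meta[[mod]],
                     file.path(out_dir, paste0("meta_", mod, ".tsv")))
    for (nm in names(out$ewas[[mod]])) {
      readr::write_tsv(out$ewas[[mod]][[nm]],
                       file.path(out_dir,
                                 paste0("ewas_", mod, "_", nm, ".tsv")))
    }
  }
  if (!is.null(out$mediation)) {
    readr::write_tsv(out$mediation, file.path(out_dir, "mediation.tsv"))
  }
  if (!is.null(out$twin)) {
    readr::write_tsv(out$twin$within_pair,
                     file.path(out_dir, "twin_within_pair.tsv"))
  }
  if (!is.null(out$eqtm)) {
    readr::write_tsv(out$eqtm$results, file.path(out_dir, "eqtm.tsv"))
  }
  glances <- purrr::imap_dfr(out$bacon_fits, function(f, nm) {
    dplyr::mutate(glance(f), fit = nm, .before = 1)
  })
  if (nrow(glances)) {
    readr::write_tsv(glances, file.path(out_dir, "bacon_fits.tsv"))
  }
  readr::write_tsv(out$manifest, file.path(out_dir, "manifest.tsv"))
  jsonlite::write_json(
    list(seed = out$config$seed,
         n_cohorts = out$config$n_cohorts,
         n_cpgs = out$config$n_cpgs,
         stages = out$manifest$detail),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
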