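#' Difference-in-coefficients mediation decomposition
#'
#' Splits the exposure-methylation association at each CpG into a part
#' mediated by smoking and a direct part, by differencing the effect without
#' smoking adjustment (total, model 1) and with it (direct, model 2):
#' indirect = total - direct, proportion mediated = indirect / total. Under
#' linear no-interaction models this coincides with the product-of-
#' coefficients decomposition. The proportion is only reported when |total|
#' exceeds `floor` (ratio blow-up guard) and lies in `[0, 1]` (otherwise a
#' sign-reversal flag is set).
#'
#' @param total_results,direct_results Result tables (e.g. from
#'   [fixed_effects_meta()] or [run_ewas()]) with columns `cpg_id` and
#'   `effect`, fitted without and with smoking adjustment on the same data.
#'   Their CpG sets must match.
#' @param floor Minimum |total| (beta scale) for the proportion to be valid.
#'   Default 0.001.
#' @return Tibble: `cpg_id`, `total`, `direct`, `indirect`, `proportion`,
#'   `flag` (`"ok"`, `"small_total"` or `"sign_reversal"`).
#' @export
#' @examples
#' t1 <- tibble::tibble(cpg_id = "cg1", effect = 0.060)
#' t2 <- tibble::tibble(cpg_id = "cg1", effect = 0.035)
#' mediate(t1, t2)$proportion # ~0.417
mediate <- function(total_results, direct_results, floor = 0.001) {
  stopifnot(all(c("cpg_id", "effect") %in% names(total_results)),
            all(c("cpg_id", "effect") %in% names(direct_results)))
  if (!setequal(total_results$cpg_id, direct_results$cpg_id)) {
    stop("the two result tables cover different CpG sets", call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(total_results, "cpg_id", total = "effect"),
    dplyr::select(direct_results, "cpg_id", direct = "effect"),
    by = "cpg_id")
  out |>
    dplyr::mutate(
      indirect = .data$total - .data$direct,
      proportion = .data$indirect / .data$total,
      flag = dplyr::case_when(
        abs(.data$total) < floor ~ "small_total",
        .data$proportion < 0 | .data$proportion > 1 ~ "sign_reversal",
        TRUE ~ "ok"),
      proportion = dplyr::if_else(.data$flag == "small_total",
                                  NA_real_, .data$proportion))
}

#' Summarise proportions mediated over a CpG set
#'
#' @param records Output of [mediate()].
#' @return One-row tibble: `min`, `max`, `mean`, `median` of the proportion
#'   over records flagged `"ok"`, plus `n_valid` and `n_invalid`. All-`NA`
#'   summaries when no record is valid.
#' @export
attenuation_summary <- function(records) {
  stopifnot(nrow(records) >= 1, "proportion" %in% names(records))
  valid <- records$flag == "ok"
  p <- records$proportion[valid]
  tibble::tibble(
    min = if (length(p)) min(p) else NA_real_,
    max = if (length(p)) max(p) else NA_real_,
    mean = if (length(p)) mean(p) else NA_real_,
    median = if (length(p)) stats::median(p) else NA_real_,
    n_valid = sum(valid),
    n_invalid = sum(!valid)
  )
}

#' Bootstrap confidence intervals for the proportion mediated
#'
#' Resamples samples with replacement, refits the unadjusted and
#' smoking-adjusted site models and recomputes the difference-in-coefficients
#' proportion at each CpG. Point estimates remain those of [mediate()] on the
#' original data; this adds percentile intervals.
#'
#' @param methylation Beta matrix (CpGs x samples).
#' @param samples Sample sheet.
#' @param design_total,design_direct [design_spec()]s without and with
#'   smoking adjustment.
#' @param cpg_ids CpGs to bootstrap (keep this set small).
#' @param n_boot Bootstrap resamples. Default 500.
#' @param seed Seed for resampling.
#' @param conf_level Interval coverage. Default 0.95.
#' @return Tibble `cpg_id`, `proportion`, `conf.low`, `conf.high`.
#' @export
mediate_bootstrap <- function(methylation, samples, design_total,
                              design_direct, cpg_ids, n_boot = 500,
                              seed = 1, conf_level = 0.95) {
  set.seed(seed)
  cpg_ids <- intersect(cpg_ids, rownames(methylation))
  stopifnot(length(cpg_ids) >= 1)
  point <- mediate(
    run_ewas(methylation[cpg_ids, , drop = FALSE], samples, design_total),
    run_ewas(methylation[cpg_ids, , drop = FALSE], samples, design_direct))
  draws <- purrr::map(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(samples), replace = TRUE)
    sam_b <- samples[idx, , drop = FALSE]
    sam_b$sample_id <- sprintf("bs%06d", seq_len(nrow(sam_b)))
    met_b <- methylation[cpg_ids, idx, drop = FALSE]
    colnames(met_b) <- sam_b$sample_id
    med <- tryCatch(
      mediate(run_ewas(met_b, sam_b, design_total),
              run_ewas(met_b, sam_b, design_direct)),
      error = function(e) NULL)
    if (is.null(med)) NULL else dplyr::select(med, "cpg_id", "proportion")
  })
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- dplyr::bind_rows(purrr::compact(draws)) |>
    dplyr::group_by(.data$cpg_id) |>
    dplyr::summarise(conf.low = stats::quantile(.data$proportion, qs[1],
                                                na.rm = TRUE),
                     conf.high = stats::quantile(.data$proportion, qs[2],
                                                 na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(dplyr::select(point, "cpg_id", "proportion"), ci,
                   by = "cpg_id")
}
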