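#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-cohort association results per site with weights
#' \eqn{w_i = 1/SE_i^2}: combined effect \eqn{\sum w_i b_i / \sum w_i},
#' combined SE \eqn{(\sum w_i)^{-1/2}}, z and two-sided p from the normal
#' reference. Cochran's Q is reported per site for heterogeneity diagnostics
#' only; no random-effects model is fitted.
#'
#' @param results A data frame of per-cohort results (rows = site x cohort)
#'   with columns `effect` and `se` (positive), optionally `n`; or a list of
#'   such data frames (bound together).
#' @param id_cols Character vector of columns identifying a site. Default
#'   `"cpg_id"`; eQTM results use `c("cpg_id", "transcript_id")`.
#' @param fwer Family-wise error rate for the Bonferroni significance call
#'   over the realized number of combined sites. Default 0.05.
#'
#' @return A tibble with one row per site: the id columns, `effect`, `se`,
#'   `z`, `p`, `n_cohorts`, `n_total` (if `n` supplied), `q` (Cochran),
#'   `single_cohort` flag, and `significant` (p below the Bonferroni
#'   threshold, attached as attribute `"p_threshold"`).
#' @export
#' @examples
#' res <- tibble::tibble(cpg_id = c("a", "a"), cohort = c("c1", "c2"),
#'                       effect = c(0.1, 0.3), se = c(0.05, 0.1))
#' fixed_effects_meta(res) # effect 0.14, se ~0.0447
fixed_effects_meta <- function(results, id_cols = "cpg_id", fwer = 0.05) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  stopifnot(all(c(id_cols, "effect", "se") %in% names(results)))
  if (any(!is.finite(results$se)) || any(results$se <= 0)) {
    stop("all standard errors must be finite and > 0", call. = FALSE)
  }
  has_n <- "n" %in% names(results)

  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      .w = sum(1 / .data$se^2),
      .b = sum(.data$effect / .data$se^2) / .w,
      q = sum(((.data$effect - .b) / .data$se)^2),
      n_cohorts = dplyr::n(),
      n_total = if (has_n) sum(.data$n) else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      effect = .data$.b,
      se = 1 / sqrt(.data$.w),
      z = .data$effect / .data$se,
      p = 2 * stats::pnorm(-abs(.data$z)),
      single_cohort = .data$n_cohorts == 1L
    ) |>
    dplyr::select(-".w", -".b") |>
    dplyr::relocate(dplyr::all_of(id_cols), "effect", "se", "z", "p")

  thr <- bonferroni_threshold(nrow(out), fwer = fwer)
  out$significant <- out$p < thr
  attr(out, "p_threshold") <- thr
  class(out) <- c("ewas_meta", class(out))
  out
}

#' Bonferroni per-test significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param fwer Family-wise error rate to control. Default 0.05.
#' @return `fwer / n_tests`, unrounded.
#' @export
#' @examples
#' signif(bonferroni_threshold(410746), 2) # 1.2e-07
bonferroni_threshold <- function(n_tests, fwer = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a single count >= 1", call. = FALSE)
  }
  fwer / n_tests
}

#' Power of a one-degree-of-freedom linear association
#'
#' Power to detect a single predictor explaining a fraction `r_squared` of
#' outcome variance in a linear model, at two-sided level `alpha` and sample
#' size `n`. The default method uses the noncentral-F distribution with
#' effect size \eqn{f^2 = R^2/(1 - R^2)} and noncentrality \eqn{f^2 n}
#' (numerator df 1, denominator df `n - 2`). `method = "fisher_z"` uses the
#' normal approximation to the Fisher z-transformed correlation.
#'
#' @param r_squared Variance explained, in (0, 1).
#' @param n Sample size (>= 4).
#' @param alpha Two-sided type-I error rate.
#' @param method `"ncf"` (noncentral F, default) or `"fisher_z"`.
#' @return Power in (0, 1), vectorised over `n`.
#' @export
power_at_n <- function(r_squared, n, alpha = 0.05, method = c("ncf", "fisher_z")) {
  method <- match.arg(method)
  check_power_args(r_squared, alpha)
  stopifnot(all(n >= 4))
  if (method == "ncf") {
    f2 <- r_squared / (1 - r_squared)
    v <- n - 2
    1 - stats::pf(stats::qf(1 - alpha, 1, v), 1, v, ncp = f2 * n)
  } else {
    za <- stats::qnorm(1 - alpha / 2)
    delta <- atanh(sqrt(r_squared)) * sqrt(n - 3)
    stats::pnorm(delta - za) + stats::pnorm(-delta - za)
  }
}

#' Smallest sample size reaching a target power
#'
#' Inverse of [power_at_n()]: the smallest integer `n` with power at least
#' `power`. Power is strictly increasing in `n`, so the search brackets
#' geometrically and bisects.
#'
#' @inheritParams power_at_n
#' @param power Target power in (0, 1).
#' @return Smallest integer sample size.
#' @export
#' @examples
#' required_n(0.01, alpha = 1e-7, power = 0.8) # 3781 never smokers
required_n <- function(r_squared, alpha = 0.05, power = 0.8,
                       method = c("ncf", "fisher_z")) {
  method <- match.arg(method)
  check_power_args(r_squared, alpha)
  stopifnot(power > 0, power < 1)
  lo <- 4L
  hi <- 8L
  while (power_at_n(r_squared, hi, alpha, method) < power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e9) stop("required sample size exceeds 1e9", call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_at_n(r_squared, mid, alpha, method) >= power) hi <- mid else lo <- mid
  }
  hi
}

check_power_args <- function(r_squared, alpha) {
  if (length(r_squared) != 1L || is.na(r_squared) ||
      r_squared <= 0 || r_squared >= 1) {
    stop("r_squared must be a single value in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
}
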