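#' Build the twin-pair table from a sample sheet
#'
#' Keeps complete twin pairs (exactly two members per family with MZ or DZ
#' zygosity), orders the two members deterministically by sample id (so
#' within-pair difference signs are reproducible) and assigns the smoking
#' concordance stratum: `discordant` (current vs never), `concordant_current`,
#' `concordant_never`, or `other`.
#'
#' @param samples Sample sheet with `family_id` and `zygosity` columns.
#' @return Tibble with one row per pair: `pair_id`, `zygosity`, `sample_id_1`,
#'   `sample_id_2`, `smoking_stratum`. Incomplete families are recorded in
#'   the attribute `"excluded"`.
#' @export
build_pairs <- function(samples) {
  stopifnot(all(c("family_id", "zygosity", "sample_id") %in% names(samples)))
  tw <- samples |>
    dplyr::filter(!is.na(.data$family_id), .data$zygosity %in% c("MZ", "DZ"))
  sizes <- dplyr::count(tw, .data$family_id)
  if (any(sizes$n > 2)) {
    stop("families with more than 2 members: ",
         paste(sizes$family_id[sizes$n > 2], collapse = ", "), call. = FALSE)
  }
  excluded <- sizes$family_id[sizes$n != 2]
  tw <- tw |>
    dplyr::filter(!.data$family_id %in% excluded) |>
    dplyr::arrange(.data$family_id, .data$sample_id)

  pairs <- tw |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      zygosity = .data$zygosity[1],
      sample_id_1 = .data$sample_id[1],
      sample_id_2 = .data$sample_id[2],
      smoking_stratum = smoking_stratum(.data$smoking_status[1],
                                        .data$smoking_status[2]),
      .groups = "drop") |>
    dplyr::rename(pair_id = "family_id")
  attr(pairs, "excluded") <- excluded
  pairs
}

smoking_stratum <- function(s1, s2) {
  if (is.na(s1) || is.na(s2)) return("other")
  both <- sort(c(s1, s2))
  if (s1 == "current" && s2 == "current") return("concordant_current")
  if (s1 == "never" && s2 == "never") return("concordant_never")
  if (identical(both, c("current", "never"))) return("discordant")
  "other"
}

# Within-pair differences (twin 1 minus twin 2) for the exposure, selected
# CpGs, and optional numeric covariates. Smoking is coded never=0, former=1,
# current=2 before differencing (a repository convention).
pair_differences <- function(pairs, samples, methylation, cpg_ids,
                             exposure = "education_ridit") {
  i1 <- match(pairs$sample_id_1, samples$sample_id)
  i2 <- match(pairs$sample_id_2, samples$sample_id)
  if (anyNA(i1) || anyNA(i2)) {
    stop("pair members missing from the sample sheet", call. = FALSE)
  }
  smoke_num <- function(s) c(never = 0, former = 1, current = 2)[s]
  d_exposure <- samples[[exposure]][i1] - samples[[exposure]][i2]
  d_smoking <- as.numeric(smoke_num(samples$smoking_status[i1]) -
                            smoke_num(samples$smoking_status[i2]))
  m1 <- match(pairs$sample_id_1, colnames(methylation))
  m2 <- match(pairs$sample_id_2, colnames(methylation))
  d_meth <- methylation[cpg_ids, m1, drop = FALSE] -
    methylation[cpg_ids, m2, drop = FALSE]
  list(d_exposure = d_exposure, d_smoking = d_smoking, d_meth = d_meth)
}

#' Within-twin-pair discordance regression
#'
#' Regresses the within-pair methylation difference on the within-pair
#' exposure (ridit) difference at each CpG, with an intercept by default
#' (allowing birth-order-like asymmetries) and optional adjustment for the
#' within-pair difference in a numeric smoking coding (never=0, former=1,
#' current=2). Shared familial and (in MZ pairs) genetic confounding cancels
#' in the differences, so the slope estimates the direct within-family
#' effect.
#'
#' @param pairs Pair table from [build_pairs()], optionally filtered to a
#'   zygosity or smoking stratum.
#' @param samples Sample sheet covering the pair members.
#' @param methylation Beta matrix (CpGs x samples).
#' @param cpg_ids CpGs to analyse. Default: all rows of `methylation`.
#' @param adjust_smoking Include the smoking difference as covariate.
#' @param intercept Include an intercept. Default `TRUE`.
#' @param min_pairs Minimum pairs with a nonzero exposure difference.
#' @return Tibble `cpg_id`, `effect`, `se`, `z`, `p`, `n_pairs`.
#' @export
within_pair_regression <- function(pairs, samples, methylation,
                                   cpg_ids = rownames(methylation),
                                   adjust_smoking = FALSE,
                                   intercept = TRUE,
                                   min_pairs = 10) {
  stopifnot(nrow(pairs) > 0)
  d <- pair_differences(pairs, samples, methylation, cpg_ids)
  nz <- sum(d$d_exposure != 0, na.rm = TRUE)
  if (nz == 0) {
    stop("all within-pair exposure differences are zero in this stratum",
         call. = FALSE)
  }
  if (nz < min_pairs) {
    stop("only ", nz, " pairs with nonzero exposure difference (< ",
         min_pairs, ")", call. = FALSE)
  }
  X <- cbind(if (intercept) rep(1, nrow(pairs)),
             d_exposure = d$d_exposure,
             if (adjust_smoking) d$d_smoking)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  Y <- t(d$d_meth[, ok, drop = FALSE])
  j <- if (intercept) 2L else 1L
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("degenerate within-pair design", call. = FALSE)
  coefs <- qr.coef(qrx, Y)
  eff <- if (is.matrix(coefs)) coefs[j, ] else coefs[j]
  E <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(as.matrix(E)^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  z <- eff / se
  tibble::tibble(cpg_id = cpg_ids, effect = unname(eff), se = unname(se),
                 z = unname(z), p = 2 * stats::pnorm(-abs(z)),
                 n_pairs = nrow(X))
}

#' Ratio of within-pair to population effect sizes
#'
#' Matches within-pair and population result tables by CpG and reports the
#' per-CpG ratio (within / population) together with the set summary (mean
#' and median ratio, correlation of the two effect vectors). Ratios where
#' the population effect is below `floor` are flagged and excluded from the
#' summary.
#'
#' @param within,population Result tables with `cpg_id` and `effect`.
#' @param floor Minimum |population effect| for a valid ratio.
#' @return List with `ratios` (tibble `cpg_id`, `within`, `population`,
#'   `ratio`, `flag`) and `summary` (one-row tibble `mean_ratio`,
#'   `median_ratio`, `effect_correlation`, `n`).
#' @export
within_vs_population_ratio <- function(within, population, floor = 0.001) {
  ratios <- dplyr::inner_join(
    dplyr::select(within, "cpg_id", within = "effect"),
    dplyr::select(population, "cpg_id", population = "effect"),
    by = "cpg_id") |>
    dplyr::mutate(
      ratio = .data$within / .data$population,
      flag = dplyr::if_else(abs(.data$population) < floor,
                            "small_population_effect", "ok"),
      ratio = dplyr::if_else(.data$flag == "ok", .data$ratio, NA_real_))
  ok <- ratios$flag == "ok"
  summary <- tibble::tibble(
    mean_ratio = mean(ratios$ratio[ok]),
    median_ratio = stats::median(ratios$ratio[ok]),
    effect_correlation = if (sum(ok) >= 3) {
      stats::cor(ratios$within[ok], ratios$population[ok])
    } else {
      NA_real_
    },
    n = sum(ok))
  list(ratios = ratios, summary = summary)
}
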