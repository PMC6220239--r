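#' Ridit-transform an ordinal exposure within strata
#'
#' Converts an ordinal exposure (by default the 7-level educational-attainment
#' category) into ridit scores: the cumulative proportion of the stratum below
#' a category plus half the proportion within it,
#' \eqn{R_k = \sum_{j<k} p_j + p_k/2}. Ridits are relative ranks on (0, 1)
#' with stratum mean exactly 0.5, so they standardise the exposure for
#' between-stratum differences (here: sex and birth cohort) by construction.
#'
#' @param samples A data frame with one row per sample. Must contain the
#'   ordinal column named by `category`; stratification additionally uses
#'   `sex` and `birth_year` when present.
#' @param category Name of the ordinal column. Values must be positive
#'   integers (levels need not be contiguous).
#' @param strata Character vector of stratum keys. Default `c("sex",
#'   "birth_year")`; `birth_year` is binned into `birth_bin_width`-year bins.
#'   Use `character()` to score all samples as one stratum.
#' @param birth_bin_width Width of the birth-year bins, years. Default 10
#'   (decade bins).
#' @param min_stratum Minimum stratum size. Smaller strata are merged with the
#'   adjacent birth-year bin (warning emitted); merging never crosses sex.
#' @param new_col Name of the ridit column added to `samples`.
#'
#' @return `samples` with the ridit column added. The per-stratum scoring
#'   table (category proportions and ridit values) is attached as attribute
#'   `"ridit_spec"` and can be retrieved with [ridit_spec()].
#' @export
#' @examples
#' df <- tibble::tibble(education_category = rep(1:4, c(10, 20, 30, 40)))
#' out <- ridit_transform(df, strata = character())
#' unique(out$education_ridit) # 0.05 0.20 0.45 0.80
ridit_transform <- function(samples,
                            category = "education_category",
                            strata = c("sex", "birth_year"),
                            birth_bin_width = 10,
                            min_stratum = 10,
                            new_col = "education_ridit") {
  stopifnot(is.data.frame(samples))
  if (!category %in% names(samples)) {
    stop("column '", category, "' not found in `samples`", call. = FALSE)
  }
  cat_vals <- samples[[category]]
  if (anyNA(cat_vals)) {
    stop("missing values in '", category, "'; drop or impute them first",
         call. = FALSE)
  }
  if (!all(cat_vals == round(cat_vals)) || any(cat_vals < 1)) {
    stop("'", category, "' must contain positive integer levels", call. = FALSE)
  }

  strata <- intersect(strata, names(samples))
  key_sex <- if ("sex" %in% strata) as.character(samples$sex) else "all"
  key_bin <- if ("birth_year" %in% strata) {
    floor(samples$birth_year / birth_bin_width) * birth_bin_width
  } else {
    0
  }
  bins <- merge_small_strata(key_sex, key_bin, min_stratum)

  df <- tibble::tibble(
    .row = seq_len(nrow(samples)),
    .sex = key_sex,
    .bin = bins,
    .cat = as.integer(cat_vals)
  )
  spec <- df |>
    dplyr::count(.data$.sex, .data$.bin, .data$.cat, name = "n") |>
    dplyr::group_by(.data$.sex, .data$.bin) |>
    dplyr::arrange(.data$.cat, .by_group = TRUE) |>
    dplyr::mutate(
      p = .data$n / sum(.data$n),
      ridit = cumsum(.data$p) - .data$p / 2
    ) |>
    dplyr::ungroup()

  df <- dplyr::left_join(df, spec, by = c(".sex", ".bin", ".cat"))
  samples[[new_col]] <- df$ridit[order(df$.row)]

  spec_out <- spec |>
    dplyr::rename(sex = ".sex", birth_bin = ".bin", category = ".cat",
                  proportion = "p")
  attr(samples, "ridit_spec") <- spec_out
  samples
}

#' @rdname ridit_transform
#' @param x An object returned by [ridit_transform()].
#' @export
ridit_spec <- function(x) attr(x, "ridit_spec")

# Merge sex x birth-bin strata below `min_stratum` into the nearest birth bin
# of the same sex (iterative; collapses to one bin per sex if needed).
merge_small_strata <- function(key_sex, key_bin, min_stratum) {
  bin <- as.numeric(key_bin)
  for (s in unique(key_sex)) {
    idx <- key_sex == s
    repeat {
      tab <- table(bin[idx])
      if (length(tab) <= 1L) break
      small <- names(tab)[tab < min_stratum]
      if (length(small) == 0L) break
      b <- as.numeric(small[1L])
      others <- as.numeric(names(tab)[names(tab) != small[1L]])
      nearest <- others[which.min(abs(others - b))]
      warning(sprintf(
        "stratum (sex=%s, birth bin=%s) has %d < %d samples; merged into bin %s",
        s, small[1L], tab[[small[1L]]], min_stratum, nearest), call. = FALSE)
      bin[idx & bin == b] <- nearest
    }
  }
  bin
}

#' Cumulative smoking dose in pack-years
#'
#' Pack-years = (cigarettes per day / 20) x years smoked. Missing values
#' propagate; negative inputs are an error.
#'
#' @param cigarettes_per_day,years_smoked Non-negative numeric vectors
#'   (recycled to common length).
#' @return Numeric vector of pack-years.
#' @export
#' @examples
#' pack_years(20, 10) # 10
pack_years <- function(cigarettes_per_day, years_smoked) {
  if (any(cigarettes_per_day < 0, na.rm = TRUE) ||
      any(years_smoked < 0, na.rm = TRUE)) {
    stop("cigarettes_per_day and years_smoked must be non-negative",
         call. = FALSE)
  }
  (cigarettes_per_day / 20) * years_smoked
}

#' Classify plasma cotinine into smoke-exposure groups
#'
#' Cut-offs: cotinine >= 15 ng/mL indicates active smoking, 1 <= cotinine < 15
#' second-hand exposure, < 1 no current exposure. The three groups partition
#' `[0, Inf)`; both boundaries belong to the upper group.
#'
#' @param cotinine Numeric vector, plasma cotinine in ng/mL (non-negative;
#'   `NA` allowed and propagated).
#' @return Factor with levels `smoker`, `second_hand`, `unexposed`.
#' @export
#' @examples
#' classify_cotinine(c(15, 1, 0.5)) # smoker, second_hand, unexposed
classify_cotinine <- function(cotinine) {
  if (any(cotinine < 0, na.rm = TRUE)) {
    stop("cotinine must be non-negative", call. = FALSE)
  }
  out <- ifelse(cotinine >= 15, "smoker",
                ifelse(cotinine >= 1, "second_hand", "unexposed"))
  factor(out, levels = c("smoker", "second_hand", "unexposed"))
}

#' Reconcile maternal-smoking reports between co-twins
#'
#' Twins report on the same pregnancy, so a definite answer ("yes"/"no") from
#' one twin fills the other's "unknown"/"missing". Conflicting definite
#' answers set both to missing; two indefinite answers stay missing. The rule
#' is symmetric in twin order.
#'
#' @param answer_twin1,answer_twin2 Character vectors with values in
#'   `c("yes", "no", "unknown", "missing")`; `NA` is treated as `"missing"`.
#' @return A tibble with columns `twin1` and `twin2` holding the resolved
#'   answers (`"yes"`, `"no"` or `"missing"`).
#' @export
#' @examples
#' reconcile_maternal_smoking("yes", "missing") # both "yes"
reconcile_maternal_smoking <- function(answer_twin1, answer_twin2) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "missing"
    bad <- setdiff(unique(x), c("yes", "no", "unknown", "missing"))
    if (length(bad)) {
      stop("invalid maternal smoking answers: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    x
  }
  a <- norm(answer_twin1)
  b <- norm(answer_twin2)
  definite <- function(x) x %in% c("yes", "no")
  res_a <- res_b <- rep("missing", length(a))
  both_def <- definite(a) & definite(b)
  agree <- both_def & a == b
  res_a[agree] <- a[agree]
  res_b[agree] <- b[agree]
  # conflicting definite answers stay "missing"
  only_a <- definite(a) & !definite(b)
  res_a[only_a] <- a[only_a]
  res_b[only_a] <- a[only_a]
  only_b <- definite(b) & !definite(a)
  res_a[only_b] <- b[only_b]
  res_b[only_b] <- b[only_b]
  tibble::tibble(twin1 = res_a, twin2 = res_b)
}

#' Weighted methylation-based smoking score
#'
#' Per-sample weighted sum of beta values at CpGs previously reported to be
#' associated with smoking, \eqn{score_i = \sum_k w_k m_{ki}}, using the
#' supplied weight table. Raw beta values are used by default; set
#' `standardize = TRUE` to z-score each CpG across samples first.
#'
#' @param methylation Numeric matrix of beta values, CpGs in rows (rownames =
#'   CpG ids), samples in columns (colnames = sample ids).
#' @param weights Data frame with columns `cpg_id` and `weight`.
#' @param standardize Z-score each CpG across samples before weighting.
#'   Default `FALSE`.
#' @return Tibble with columns `sample_id` and `smoking_score`; the number of
#'   weight CpGs found in the matrix is attached as attribute `"n_cpgs_used"`.
#' @export
methylation_smoking_score <- function(methylation, weights,
                                      standardize = FALSE) {
  stopifnot(is.matrix(methylation),
            all(c("cpg_id", "weight") %in% names(weights)))
  common <- intersect(weights$cpg_id, rownames(methylation))
  if (length(common) == 0L) {
    stop("no weight CpGs found in the methylation matrix", call. = FALSE)
  }
  w <- weights$weight[match(common, weights$cpg_id)]
  m <- methylation[common, , drop = FALSE]
  if (standardize) {
    m <- t(scale(t(m)))
    m[is.nan(m)] <- 0 # constant CpGs carry no information
  }
  score <- as.numeric(crossprod(m, w))
  out <- tibble::tibble(sample_id = colnames(methylation),
                        smoking_score = score)
  attr(out, "n_cpgs_used") <- length(common)
  out
}
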