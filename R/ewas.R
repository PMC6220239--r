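#' Specify a site-wise association model
#'
#' Defines the covariate model, subset rule and variance estimator for a
#' site-wise EWAS of methylation beta values on an exposure. Three standard
#' models are provided: `model1` adjusts for sex, age, array row, bisulphite
#' plate and white-blood-cell percentages; `model2` adds smoking status;
#' `model3` adds smoking status and BMI. Cell-count covariates may differ per
#' cohort (some cohorts record monocytes + granulocytes instead of the
#' three-part differential); pass the cohort's list via `covariates`.
#'
#' @param model `"model1"`, `"model2"` or `"model3"` (covariate supersets, in
#'   that order), or `"custom"` to use `covariates` exactly as given.
#' @param exposure Name of the exposure column. Default `"education_ridit"`.
#' @param covariates Base covariate columns for `model1`. Default
#'   `c("sex", "age_at_blood", "array_row", "plate", "neutrophil_pct",
#'   "monocyte_pct", "eosinophil_pct")`.
#' @param extra Additional adjuster columns appended to any model (e.g.
#'   `"pack_years"`, a methylation smoking score, a reference-CpG beta).
#' @param subset `NULL` (all samples), the keyword `"never_smokers"`
#'   (`smoking_status == "never"`), `"never_smokers_cotinine_clean"`
#'   (additionally drops never smokers with cotinine >= 15 ng/mL), or a
#'   predicate `function(samples)` returning a logical vector.
#' @param cluster Column holding family identifiers for clustered inference;
#'   samples with missing ids are treated as their own singleton clusters.
#' @param se_type `"clustered"` (CR1 cluster-robust sandwich on OLS, default;
#'   when no family id is repeated it reduces to the model-based OLS
#'   standard error), `"independence"` (model-based OLS), or `"exchangeable"`
#'   (estimating equations with an exchangeable working correlation;
#'   per-site only, slower).
#' @param n_min Minimum complete cases per site. Default 30.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(model = c("model1", "model2", "model3", "custom"),
                        exposure = "education_ridit",
                        covariates = c("sex", "age_at_blood", "array_row",
                                       "plate", "neutrophil_pct",
                                       "monocyte_pct", "eosinophil_pct"),
                        extra = character(),
                        subset = NULL,
                        cluster = "family_id",
                        se_type = c("clustered", "independence", "exchangeable"),
                        n_min = 30) {
  model <- match.arg(model)
  se_type <- match.arg(se_type)
  covs <- covariates
  if (model %in% c("model2", "model3")) covs <- union(covs, "smoking_status")
  if (model == "model3") covs <- union(covs, "bmi")
  covs <- union(covs, extra)
  structure(
    list(model = model, exposure = exposure, covariates = covs,
         subset = subset, cluster = cluster, se_type = se_type, n_min = n_min),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("EWAS design (", x$model, ")\n", sep = "")
  cat("  exposure:  ", x$exposure, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  se_type:   ", x$se_type,
      if (x$se_type != "independence") paste0(" (cluster = ", x$cluster, ")"),
      "\n", sep = "")
  invisible(x)
}

apply_subset <- function(samples, subset) {
  if (is.null(subset)) return(rep(TRUE, nrow(samples)))
  if (is.function(subset)) return(subset(samples))
  if (identical(subset, "never_smokers")) {
    return(samples$smoking_status == "never")
  }
  if (identical(subset, "never_smokers_cotinine_clean")) {
    keep <- samples$smoking_status == "never"
    if ("cotinine" %in% names(samples)) {
      keep <- keep & !(!is.na(samples$cotinine) & samples$cotinine >= 15)
    }
    return(keep)
  }
  stop("unknown subset rule: ", subset, call. = FALSE)
}

# Build the model matrix for a design on a sample sheet. Returns the matrix,
# the rows used (complete cases), and the exposure column index.
build_design_matrix <- function(samples, design) {
  vars <- c(design$exposure, design$covariates)
  missing_cols <- setdiff(vars, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks design columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- samples[vars]
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.character), factor))
  complete <- stats::complete.cases(df)
  mm <- stats::model.matrix(stats::reformulate(vars), df[complete, , drop = FALSE])
  j <- match(design$exposure, colnames(mm))
  if (is.na(j)) {
    stop("exposure column lost in model matrix (is it a factor?)", call. = FALSE)
  }
  list(X = mm, rows = which(complete), exposure_index = j)
}

check_full_rank <- function(X) {
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (constant exposure or collinear ",
         "covariates)", call. = FALSE)
  }
}

#' Site-wise association of one methylation vector with the exposure
#'
#' Ordinary least-squares fit of a single site's beta values on the exposure
#' and covariates of a [design_spec()], with the standard error chosen by the
#' design (`independence`, cluster-robust `clustered`, or `exchangeable`
#' estimating equations). Rows with missing data are dropped listwise.
#'
#' @param y Numeric vector of beta values, aligned with the rows of `samples`.
#' @param samples Sample sheet (one row per sample).
#' @param design A [design_spec()].
#' @return One-row tibble with `effect`, `se`, `z`, `p`, `n`.
#' @export
fit_site <- function(y, samples, design = design_spec()) {
  stopifnot(length(y) == nrow(samples))
  keep <- apply_subset(samples, design$subset)
  keep[is.na(keep)] <- FALSE
  samples <- samples[keep, , drop = FALSE]
  y <- y[keep]

  ok <- !is.na(y)
  samples <- samples[ok, , drop = FALSE]
  y <- y[ok]
  dm <- build_design_matrix(samples, design)
  X <- dm$X
  y <- y[dm$rows]
  n <- nrow(X)
  if (n < design$n_min) {
    stop("only ", n, " complete cases (< n_min = ", design$n_min, ")",
         call. = FALSE)
  }
  check_full_rank(X)
  cl <- site_clusters(samples[dm$rows, , drop = FALSE], design)

  if (design$se_type == "exchangeable") {
    fit <- gee_exchangeable(X, y, cl, dm$exposure_index)
    eff <- fit$effect
    se <- fit$se
  } else {
    qrx <- qr(X)
    coefs <- qr.coef(qrx, y)
    eff <- coefs[dm$exposure_index]
    res <- y - as.vector(X %*% coefs)
    xtx_inv <- chol2inv(qr.R(qrx))
    if (design$se_type == "independence" || !any(duplicated(cl))) {
      # no clustering structure: the model-based OLS SE is the estimator
      sigma2 <- sum(res^2) / (n - ncol(X))
      se <- sqrt(sigma2 * xtx_inv[dm$exposure_index, dm$exposure_index])
    } else {
      se <- clustered_se(X, matrix(res, ncol = 1), cl,
                         coef_index = dm$exposure_index,
                         xtx_inv = xtx_inv)
    }
  }
  z <- eff / se
  tibble::tibble(effect = unname(eff), se = unname(se), z = unname(z),
                 p = 2 * stats::pnorm(-abs(z)), n = n)
}

site_clusters <- function(samples, design) {
  if (design$se_type == "independence") return(seq_len(nrow(samples)))
  cl <- if (!is.null(design$cluster) && design$cluster %in% names(samples)) {
    as.character(samples[[design$cluster]])
  } else {
    rep(NA_character_, nrow(samples))
  }
  solo <- is.na(cl) | cl == ""
  cl[solo] <- paste0(".singleton", seq_len(sum(solo)))
  cl
}

#' Cluster-robust sandwich standard errors for OLS coefficients
#'
#' Sandwich estimator \eqn{\widehat{var}(\hat\beta_j) = c\, a^\top
#' \left[\sum_g (X_g^\top e_g)(X_g^\top e_g)^\top\right] a} with \eqn{a} the
#' j-th column of \eqn{(X^\top X)^{-1}} and, by default, the CR1
#' finite-sample factor \eqn{c = \frac{G}{G-1}\frac{n-1}{n-p}} (the
#' OLS residuals are shrunk by the hat matrix; without the factor the
#' estimator is anti-conservative in finite samples). With every cluster a
#' singleton and `df_correction = FALSE` this is the HC0
#' heteroskedasticity-robust independence estimator. Vectorised over many
#' outcomes sharing one design matrix.
#'
#' @param X Model matrix (n x p).
#' @param residuals Matrix of OLS residuals, n rows, one column per outcome.
#' @param cluster Cluster labels, length n.
#' @param coef_index Column of `X` whose SE is required.
#' @param xtx_inv Optional precomputed \eqn{(X^\top X)^{-1}}.
#' @param df_correction Apply the CR1 factor. Default `TRUE`.
#' @return Numeric vector of standard errors, one per outcome column.
#' @export
clustered_se <- function(X, residuals, cluster, coef_index,
                         xtx_inv = chol2inv(chol(crossprod(X))),
                         df_correction = TRUE) {
  stopifnot(nrow(X) == nrow(residuals), length(cluster) == nrow(X))
  a <- xtx_inv[, coef_index]
  s <- as.vector(X %*% a)
  h <- residuals * s
  u <- rowsum(h, group = cluster, reorder = FALSE)
  v <- colSums(u^2)
  if (df_correction) {
    n <- nrow(X)
    g <- nrow(u)
    if (g > 1 && n > ncol(X)) {
      v <- v * (g / (g - 1)) * ((n - 1) / (n - ncol(X)))
    }
  }
  sqrt(v)
}

# One-step estimating-equation fit with exchangeable working correlation:
# moment estimate of the within-cluster correlation from OLS residuals, then
# GLS with the analytic exchangeable inverse and model-based covariance.
gee_exchangeable <- function(X, y, cluster, coef_index, iter = 2) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- qr.coef(qr(X), y)
  groups <- split(seq_len(n), cluster)
  for (k in seq_len(iter)) {
    res <- y - as.vector(X %*% beta)
    sigma2 <- sum(res^2) / (n - p)
    num <- 0
    den <- 0
    for (idx in groups) {
      m <- length(idx)
      if (m > 1) {
        e <- res[idx]
        num <- num + (sum(e)^2 - sum(e^2))
        den <- den + m * (m - 1)
      }
    }
    rho <- if (den > 0) max(min(num / den / sigma2, 0.99), -0.99) else 0
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (idx in groups) {
      m <- length(idx)
      Xg <- X[idx, , drop = FALSE]
      yg <- y[idx]
      # exchangeable inverse: (I - rho/(1+(m-1)rho) J) / (1-rho), up to sigma2
      cj <- rho / (1 + (m - 1) * rho)
      XtV <- (t(Xg) - cj * outer(colSums(Xg), rep(1, m))) / (1 - rho)
      A <- A + XtV %*% Xg
      b <- b + XtV %*% yg
    }
    beta <- solve(A, b)
  }
  vcov <- sigma2 * solve(A)
  list(effect = beta[coef_index], se = sqrt(vcov[coef_index, coef_index]))
}

#' Run a site-wise EWAS over a methylation matrix
#'
#' Fits the [design_spec()] model at every CpG of a beta-value matrix for one
#' cohort. Sites without missing values share a single design factorisation
#' (the normal-equations solution is computed for all sites at once); sites
#' with missing beta values fall back to [fit_site()]. Sites that fail
#' (too few complete cases, degenerate design) are skipped and recorded in
#' the attribute `"skipped"`.
#'
#' @param methylation Numeric matrix, CpGs x samples, beta values in `[0, 1]`
#'   (rownames = CpG ids, colnames = sample ids).
#' @param samples Sample sheet with a `sample_id` column matching the matrix
#'   columns.
#' @param design A [design_spec()].
#' @param cohort Cohort label stored in the result. Default `"cohort1"`.
#' @return Tibble with one row per retained CpG: `cpg_id`, `cohort`, `model`,
#'   `effect`, `se`, `z`, `p`, `n`.
#' @export
run_ewas <- function(methylation, samples, design = design_spec(),
                     cohort = "cohort1") {
  stopifnot(is.matrix(methylation), "sample_id" %in% names(samples))
  common <- intersect(colnames(methylation), samples$sample_id)
  if (length(common) == 0L) {
    stop("no overlapping samples between methylation matrix and sample sheet",
         call. = FALSE)
  }
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  methylation <- methylation[, common, drop = FALSE]

  keep <- apply_subset(samples, design$subset)
  keep[is.na(keep)] <- FALSE
  samples <- samples[keep, , drop = FALSE]
  methylation <- methylation[, keep, drop = FALSE]
  if (nrow(samples) == 0L) stop("subset rule removed all samples", call. = FALSE)

  strip <- design
  strip$subset <- NULL # already applied

  dm <- build_design_matrix(samples, strip)
  check_full_rank(dm$X)
  use <- dm$rows
  X <- dm$X
  n <- nrow(X)
  if (n < design$n_min) {
    stop("only ", n, " complete covariate cases (< n_min)", call. = FALSE)
  }
  Y <- t(methylation[, use, drop = FALSE])

  complete_site <- !matrixStats_colAnyNA(Y)
  skipped <- tibble::tibble(cpg_id = character(), reason = character())

  results <- NULL
  if (any(complete_site) && design$se_type != "exchangeable") {
    Yc <- Y[, complete_site, drop = FALSE]
    qrx <- qr(X)
    coefs <- qr.coef(qrx, Yc)
    eff <- coefs[dm$exposure_index, ]
    E <- Yc - X %*% coefs
    xtx_inv <- chol2inv(qr.R(qrx))
    cl <- if (design$se_type == "clustered") {
      site_clusters(samples[use, , drop = FALSE], strip)
    }
    if (design$se_type == "independence" || !any(duplicated(cl))) {
      sigma2 <- colSums(E^2) / (n - ncol(X))
      se <- sqrt(sigma2 * xtx_inv[dm$exposure_index, dm$exposure_index])
    } else {
      se <- clustered_se(X, E, cl, dm$exposure_index, xtx_inv = xtx_inv)
    }
    z <- eff / se
    results <- tibble::tibble(
      cpg_id = colnames(Yc), cohort = cohort, model = design$model,
      effect = unname(eff), se = unname(se), z = unname(z),
      p = 2 * stats::pnorm(-abs(z)), n = n)
  }

  slow_sites <- which(!complete_site | design$se_type == "exchangeable")
  if (length(slow_sites)) {
    slow <- purrr::map(slow_sites, function(k) {
      res <- tryCatch(
        fit_site(Y[, k], samples[use, , drop = FALSE], strip),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped <<- dplyr::bind_rows(
          skipped, tibble::tibble(cpg_id = colnames(Y)[k], reason = res))
        NULL
      } else {
        dplyr::mutate(res, cpg_id = colnames(Y)[k], cohort = cohort,
                      model = design$model, .before = 1)
      }
    })
    results <- dplyr::bind_rows(results, purrr::compact(slow))
  }
  results <- results[order(match(results$cpg_id, rownames(methylation))), ]
  attr(results, "skipped") <- skipped
  results
}

# anyNA per column without depending on matrixStats
matrixStats_colAnyNA <- function(Y) colSums(is.na(Y)) > 0L
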