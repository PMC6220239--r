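#' Estimate bias and inflation of a set of test statistics
#'
#' Fits a three-component Gaussian mixture to a genome-wide vector of
#' z-statistics by Gibbs sampling. The centre component (ordering constraint
#' \eqn{\mu_1 \le \mu_0 \le \mu_2} in every draw) is taken as the empirical
#' null; its mean is the *bias* and its standard deviation the *inflation* of
#' the statistics. Unlike genomic control, the outer components absorb true
#' signal, so the null estimate is not distorted by a non-trivial fraction of
#' real associations.
#'
#' Priors are conjugate and weakly informative by default: Dirichlet(1,1,1)
#' on the proportions, normal(`mu_mean`, `mu_sd`\eqn{^2}) on the means
#' (truncated to the ordering), inverse-gamma(`sigma_shape`, `sigma_rate`) on
#' the variances. Point estimates are posterior medians of the retained
#' draws.
#'
#' @param z Numeric vector of z-statistics (finite; a warning is issued below
#'   1000 values, where the empirical null is weakly identified).
#' @param iterations,burnin Total Gibbs iterations and number discarded.
#'   Defaults 5000 and 2000.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called so
#'   the chain is reproducible. Otherwise the current R RNG state is used.
#' @param priors Named list overriding any of `mu_mean` (length 3:
#'   null, left, right), `mu_sd`, `sigma_shape`, `sigma_rate`, `dirichlet`.
#'
#' @return An object of class `bacon_fit`: a list with `bias`, `inflation`,
#'   `estimates` (per-component posterior medians), `chain` (retained draws),
#'   `rhat` (split-chain diagnostic for the null mean and sd), `converged`,
#'   and the sampler settings. Use [generics::tidy()] / [generics::glance()]
#'   for tabular summaries and [bacon_correct()] to apply the correction.
#' @export
fit_mixture <- function(z, iterations = 5000, burnin = 2000, seed = NULL,
                        priors = list()) {
  if (!is.numeric(z) || length(z) == 0L) {
    stop("z must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(z))) {
    stop("z contains non-finite values", call. = FALSE)
  }
  if (length(z) < 1000L) {
    warning("fewer than 1000 statistics; bias/inflation estimates will be noisy",
            call. = FALSE)
  }
  stopifnot(iterations > burnin, burnin >= 0)
  pr <- utils::modifyList(
    list(mu_mean = c(0, -3, 3), mu_sd = 10,
         sigma_shape = 2, sigma_rate = 1, dirichlet = c(1, 1, 1)),
    priors)
  if (!is.null(seed)) set.seed(seed)

  chain <- gibbs_mixture_chain(as.numeric(z), as.integer(iterations),
                               as.integer(burnin),
                               pr$mu_mean, rep(pr$mu_sd, length.out = 3),
                               pr$sigma_shape, pr$sigma_rate, pr$dirichlet)
  colnames(chain) <- c("pi0", "pi1", "pi2", "mu0", "mu1", "mu2",
                       "sigma0", "sigma1", "sigma2")

  med <- apply(chain, 2, stats::median)
  rhat <- c(mu0 = split_rhat(chain[, "mu0"]),
            sigma0 = split_rhat(chain[, "sigma0"]))
  converged <- all(is.finite(rhat)) && max(rhat) < 1.1
  if (!converged) {
    warning("split-chain diagnostic above 1.1; consider more iterations",
            call. = FALSE)
  }

  estimates <- tibble::tibble(
    component = c("null", "left", "right"),
    proportion = med[c("pi0", "pi1", "pi2")],
    mean = med[c("mu0", "mu1", "mu2")],
    sd = med[c("sigma0", "sigma1", "sigma2")]
  )
  structure(
    list(bias = unname(med["mu0"]),
         inflation = unname(med["sigma0"]),
         estimates = estimates,
         chain = chain,
         rhat = rhat,
         converged = converged,
         n = length(z),
         settings = list(iterations = iterations, burnin = burnin,
                         seed = seed, priors = pr),
         z = as.numeric(z)),
    class = "bacon_fit")
}

# Split-chain potential scale reduction on one parameter's retained draws.
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(colMeans(halves))
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.bacon_fit <- function(x, ...) {
  cat("Three-component Gaussian mixture fit (", x$n, " statistics)\n", sep = "")
  cat(sprintf("  bias      %.4f\n  inflation %.4f\n", x$bias, x$inflation))
  cat(sprintf("  chain: %d iterations, %d burn-in; converged: %s\n",
              x$settings$iterations, x$settings$burnin, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_mixture
#' @param x,.x A `bacon_fit` object.
#' @param ... Unused.
#' @export
tidy.bacon_fit <- function(x, ...) {
  ci <- apply(x$chain, 2, stats::quantile, probs = c(0.025, 0.975))
  long <- tibble::tibble(
    term = colnames(x$chain),
    estimate = apply(x$chain, 2, stats::median),
    conf.low = ci[1, ],
    conf.high = ci[2, ]
  )
  long
}

#' @rdname fit_mixture
#' @export
glance.bacon_fit <- function(x, ...) {
  tibble::tibble(
    bias = x$bias,
    inflation = x$inflation,
    lambda_gc = qq_summary(x$z)$lambda,
    n = x$n,
    iterations = x$settings$iterations,
    converged = x$converged
  )
}

#' Correct association results for estimated bias and inflation
#'
#' Applies the empirical-null correction from a [fit_mixture()] fit to a
#' result table: \eqn{z' = (z - bias)/inflation}, \eqn{SE' = SE \cdot
#' inflation}, \eqn{effect' = effect - bias \cdot SE}, with two-sided p from
#' the normal reference on \eqn{z'}.
#'
#' @param results Data frame with columns `effect`, `se`, `z` (recomputed as
#'   `effect/se` when absent).
#' @param fit A `bacon_fit`, or a list with elements `bias` and `inflation`.
#' @return `results` with corrected `effect`, `se`, `z`, `p`; the correction
#'   applied is recorded in attribute `"correction"`.
#' @export
bacon_correct <- function(results, fit) {
  stopifnot(is.data.frame(results), all(c("effect", "se") %in% names(results)))
  bias <- fit$bias
  inflation <- fit$inflation
  if (!is.finite(inflation) || inflation <= 0) {
    stop("inflation estimate must be > 0", call. = FALSE)
  }
  z <- if ("z" %in% names(results)) results$z else results$effect / results$se
  results$effect <- results$effect - bias * results$se
  results$se <- results$se * inflation
  results$z <- (z - bias) / inflation
  results$p <- 2 * stats::pnorm(-abs(results$z))
  attr(results, "correction") <- c(bias = bias, inflation = inflation)
  results
}

#' Genomic-control summary of a statistics vector
#'
#' The classical genomic-control factor \eqn{\lambda =
#' median(z^2)/0.4549364} (the null median of a 1-df chi-square) together
#' with a quantile table, as a cruder companion diagnostic to
#' [fit_mixture()].
#'
#' @param z Numeric vector of z-statistics.
#' @param probs Probabilities for the quantile table.
#' @return A list with elements `lambda` and `quantiles` (a tibble).
#' @export
qq_summary <- function(z, probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(z) > 0)
  list(
    lambda = stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, df = 1),
    quantiles = tibble::tibble(
      prob = probs,
      z = unname(stats::quantile(z, probs = probs, na.rm = TRUE))
    )
  )
}

#' Plot a mixture fit over the statistic histogram
#'
#' Histogram of the fitted z-statistics overlaid with the posterior-median
#' mixture density and its three components.
#'
#' @param object A `bacon_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bacon_fit <- function(object, bins = 100, ...) {
  est <- object$estimates
  grid <- seq(min(object$z), max(object$z), length.out = 512)
  comp <- purrr::pmap_dfr(est, function(component, proportion, mean, sd) {
    tibble::tibble(z = grid, component = component,
                   density = proportion * stats::dnorm(grid, mean, sd))
  })
  total <- comp |>
    dplyr::group_by(.data$z) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop") |>
    dplyr::mutate(component = "mixture")
  ggplot2::ggplot(tibble::tibble(z = object$z), ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey70") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density, colour = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(y = .data$density), linewidth = 0.9) +
    ggplot2::labs(x = "z-statistic", y = "density", colour = "component",
                  title = sprintf("bias = %.3f, inflation = %.3f",
                                  object$bias, object$inflation)) +
    ggplot2::theme_minimal()
}
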