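#' Log2 counts-per-million
#'
#' \eqn{\log_2((count + 0.5) / (lib + 1) \times 10^6)} with library sizes
#' taken as column sums; the half-count offset keeps zeros finite.
#'
#' @param counts Non-negative count matrix (transcripts x samples).
#' @return Matrix of log2-CPM values with the same dimnames.
#' @export
log_cpm <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be > 0", call. = FALSE)
  t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
}

#' Filter transcripts by detection and variability
#'
#' Applies the two filters in fixed order: first keep transcripts detected
#' (count > 0) in at least `min_detect` of samples, then drop the
#' `drop_bottom_variability` least variable of the survivors (variance of
#' log2-CPM; ties broken by transcript order so exactly
#' `ceiling(fraction x kept)` are removed).
#'
#' @param counts Count matrix (transcripts x samples, rownames = ids).
#' @param min_detect Minimum detection fraction. Default 0.01.
#' @param drop_bottom_variability Fraction of least-variable transcripts
#'   removed after the detection filter. Default 0.01.
#' @return Filtered count matrix; removed ids and reasons in attribute
#'   `"removed"`.
#' @export
filter_transcripts <- function(counts, min_detect = 0.01,
                               drop_bottom_variability = 0.01) {
  stopifnot(is.matrix(counts), nrow(counts) > 0)
  detect <- rowMeans(counts > 0) >= min_detect
  removed <- tibble::tibble(transcript_id = rownames(counts)[!detect],
                            reason = "low_detection")
  kept <- counts[detect, , drop = FALSE]
  if (nrow(kept) == 0) stop("all transcripts removed by filters", call. = FALSE)
  n_drop <- ceiling(drop_bottom_variability * nrow(kept))
  if (n_drop > 0 && n_drop < nrow(kept)) {
    v <- apply(log_cpm(kept), 1, stats::var)
    drop_idx <- order(v, seq_along(v))[seq_len(n_drop)]
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      transcript_id = rownames(kept)[drop_idx], reason = "low_variability"))
    kept <- kept[-drop_idx, , drop = FALSE]
  }
  if (nrow(kept) == 0) stop("all transcripts removed by filters", call. = FALSE)
  attr(kept, "removed") <- removed
  kept
}

#' Enumerate cis CpG-transcript pairs
#'
#' All (CpG, transcript) pairs whose distance from the CpG position to the
#' transcript start (configurable to the nearest transcript edge) is at most
#' `window` bases on the same chromosome (closed interval). CpGs with no
#' eligible transcript are dropped and counted.
#'
#' @param cpgs Annotation tibble `cpg_id`, `chrom`, `pos` (1-based).
#' @param transcripts Annotation tibble `transcript_id`, `chrom`, `start`,
#'   optionally `end`.
#' @param window Window in bases. Default 100 kb.
#' @param anchor `"start"` (default) or `"body"` (nearest edge of
#'   `[start, end]`).
#' @return Tibble `cpg_id`, `transcript_id`, `distance`; the number of CpGs
#'   with zero eligible transcripts is attribute `"n_cpgs_dropped"`.
#' @export
pair_cis <- function(cpgs, transcripts, window = 1e5,
                     anchor = c("start", "body")) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(cpgs)),
            all(c("transcript_id", "chrom", "start") %in% names(transcripts)))
  lev <- union(cpgs$chrom, transcripts$chrom) # shared seqlevels
  gr_cpg <- GenomicRanges::GRanges(
    factor(cpgs$chrom, levels = lev),
    IRanges::IRanges(cpgs$pos, width = 1))
  tx_start <- transcripts$start
  tx_end <- if (anchor == "body" && "end" %in% names(transcripts)) {
    transcripts$end
  } else {
    tx_start
  }
  gr_tx <- GenomicRanges::GRanges(
    factor(transcripts$chrom, levels = lev),
    IRanges::IRanges(pmax(tx_start - window, 1), tx_end + window))
  hits <- GenomicRanges::findOverlaps(gr_cpg, gr_tx, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- if (anchor == "start") {
    abs(cpgs$pos[qi] - tx_start[si])
  } else {
    pmax(pmax(tx_start[si] - cpgs$pos[qi], cpgs$pos[qi] - tx_end[si]), 0)
  }
  out <- tibble::tibble(
    cpg_id = cpgs$cpg_id[qi],
    transcript_id = transcripts$transcript_id[si],
    distance = as.integer(dist)) |>
    dplyr::arrange(.data$cpg_id, .data$distance)
  attr(out, "n_cpgs_dropped") <- sum(!cpgs$cpg_id %in% out$cpg_id)
  out
}

#' Per-pair cis methylation-expression regression
#'
#' For each cis pair, ordinary least squares of the transcript's log2-CPM on
#' the CpG's methylation beta value plus observed covariates (default: age,
#' sex, monocyte, lymphocyte and neutrophil percentages). Degenerate pairs
#' (constant methylation or collinear design) are flagged and skipped, the
#' run continues. Per-cohort results can be combined with
#' [fixed_effects_meta()] using `id_cols = c("cpg_id", "transcript_id")`.
#'
#' @param pairs Pair table from [pair_cis()].
#' @param counts Count matrix (transcripts x samples).
#' @param methylation Beta matrix (CpGs x samples).
#' @param samples Sample sheet with `sample_id` and the covariate columns.
#' @param covariates Covariate columns. Default
#'   `c("age_at_blood", "sex", "monocyte_pct", "lymphocyte_pct",
#'   "neutrophil_pct")`.
#' @return `pairs` with `effect` (log2-CPM per methylation unit), `se`, `z`,
#'   `p`, `n`, `flag` (`"ok"` or `"degenerate"`) added.
#' @export
eqtm_regression <- function(pairs, counts, methylation, samples,
                            covariates = c("age_at_blood", "sex",
                                           "monocyte_pct", "lymphocyte_pct",
                                           "neutrophil_pct")) {
  common <- Reduce(intersect, list(colnames(counts), colnames(methylation),
                                   samples$sample_id))
  if (length(common) < 10) {
    stop("fewer than 10 samples shared across matrices", call. = FALSE)
  }
  samples <- samples[match(common, samples$sample_id), , drop = FALSE]
  lcpm <- log_cpm(counts[, common, drop = FALSE])
  meth <- methylation[, common, drop = FALSE]

  covs <- samples[covariates]
  covs <- dplyr::mutate(covs, dplyr::across(dplyr::where(is.character), factor))
  Z <- stats::model.matrix(stats::reformulate(covariates), covs)

  res <- purrr::pmap_dfr(
    pairs[c("cpg_id", "transcript_id")],
    function(cpg_id, transcript_id) {
      m <- meth[cpg_id, ]
      y <- lcpm[transcript_id, ]
      X <- cbind(methylation = m, Z)
      ok <- stats::complete.cases(X) & !is.na(y)
      X <- X[ok, , drop = FALSE]
      y <- y[ok]
      qrx <- qr(X)
      if (nrow(X) <= ncol(X) || qrx$rank < ncol(X)) {
        return(tibble::tibble(effect = NA_real_, se = NA_real_, z = NA_real_,
                              p = NA_real_, n = nrow(X), flag = "degenerate"))
      }
      coefs <- qr.coef(qrx, y)
      e <- y - as.vector(X %*% coefs)
      sigma2 <- sum(e^2) / (nrow(X) - ncol(X))
      se <- sqrt(sigma2 * chol2inv(qr.R(qrx))[1, 1])
      z <- coefs[1] / se
      tibble::tibble(effect = unname(coefs[1]), se = se, z = unname(z),
                     p = 2 * stats::pnorm(-abs(z)), n = nrow(X), flag = "ok")
    })
  dplyr::bind_cols(pairs, res)
}
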