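#' Correlate internal effect sizes with an external EWAS
#'
#' Pearson correlation between the effect sizes of this meta-analysis and an
#' external summary-statistics table (beta or group difference, as supplied:
#' no rescaling), over the CpGs present in both — typically the external
#' study's significant set. Symmetric in the two tables and invariant to row
#' order.
#'
#' @param internal Result table with `cpg_id` and `effect`.
#' @param external Summary-statistics table with `cpg_id` and `effect`.
#' @param site_filter Optional character vector of CpG ids to restrict the
#'   comparison to (e.g. the external study's significant sites).
#' @return One-row tibble `r`, `p`, `n_matched`.
#' @export
correlate_effects <- function(internal, external, site_filter = NULL) {
  a <- dplyr::select(internal, "cpg_id", effect_internal = "effect")
  b <- dplyr::select(external, "cpg_id", effect_external = "effect")
  if (!is.null(site_filter)) b <- dplyr::filter(b, .data$cpg_id %in% site_filter)
  m <- dplyr::inner_join(a, b, by = "cpg_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) {
    stop("only ", nrow(m), " matched sites (need >= 3); internal = ",
         nrow(a), ", external after filter = ", nrow(b), call. = FALSE)
  }
  ct <- stats::cor.test(m$effect_internal, m$effect_external)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n_matched = nrow(m))
}

#' Exclusive region counts for a Venn diagram of significant-site sets
#'
#' @param sets Named list (>= 2 elements) of character vectors of CpG ids.
#' @return Tibble with one row per non-empty membership pattern: `region`
#'   (set names joined by `&`), `count` (ids exclusively in that region).
#'   Counts sum to the size of the union.
#' @export
venn_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  ids <- unique(unlist(sets))
  membership <- vapply(sets, function(s) ids %in% s,
                       logical(length(ids)))
  membership <- matrix(membership, nrow = length(ids),
                       dimnames = list(NULL, names(sets)))
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(p) {
    sum(apply(membership, 1, function(row) all(row == p)))
  })
  tibble::tibble(
    region = apply(patterns, 1, function(p) {
      paste(names(sets)[as.logical(p)], collapse = "&")
    }),
    count = as.integer(counts))
}

#' Flag CpGs proximal to associated GWAS SNPs
#'
#' A CpG is flagged when at least one SNP with association p-value below
#' `p_thresh` lies within `window` bases on the same chromosome
#' (closed interval, both directions: |pos_cpg - pos_snp| <= window).
#'
#' @param cpgs Annotation tibble `cpg_id`, `chrom`, `pos` (1-based).
#' @param snps SNP tibble `snp_id`, `chrom`, `pos` (1-based), `p`.
#' @param window Distance threshold in bases. Default 500 kb.
#' @param p_thresh SNP p-value threshold. Default 1e-4.
#' @return Tibble `cpg_id`, `proximal` (logical); the number flagged is
#'   attached as attribute `"n_proximal"`. An empty SNP table after the p
#'   filter yields all-`FALSE` flags with a warning.
#' @export
gwas_proximity <- function(cpgs, snps, window = 5e5, p_thresh = 1e-4) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(cpgs)),
            all(c("chrom", "pos", "p") %in% names(snps)))
  snps <- dplyr::filter(snps, .data$p < p_thresh)
  flag <- rep(FALSE, nrow(cpgs))
  if (nrow(snps) == 0) {
    warning("no SNPs pass the p-value filter; all proximity flags FALSE",
            call. = FALSE)
  } else {
    lev <- union(cpgs$chrom, snps$chrom) # shared seqlevels
    gr_cpg <- GenomicRanges::GRanges(
      factor(cpgs$chrom, levels = lev),
      IRanges::IRanges(cpgs$pos, width = 1))
    gr_snp <- GenomicRanges::GRanges(
      factor(snps$chrom, levels = lev),
      IRanges::IRanges(pmax(snps$pos - window, 1), snps$pos + window))
    hits <- GenomicRanges::findOverlaps(gr_cpg, gr_snp, ignore.strand = TRUE)
    flag[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  out <- tibble::tibble(cpg_id = cpgs$cpg_id, proximal = flag)
  attr(out, "n_proximal") <- sum(flag)
  out
}
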