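#' Read and write the package's tabular formats
#'
#' All tables are tab-delimited UTF-8 with a header row and '.' decimal.
#' Matrices (methylation betas, expression counts) are written with the
#' feature id as first column (`cpg_id` / `transcript_id`), samples as the
#' remaining columns. CpG annotation is exchanged as BED-like text (0-based
#' half-open start) and converted to 1-based positions on read.
#'
#' @param path File path.
#' @param x Object to write.
#' @name eduwas_io
NULL

#' @rdname eduwas_io
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname eduwas_io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname eduwas_io
#' @param id_col Name of the feature-id column. Default `"cpg_id"`.
#' @export
read_matrix_tsv <- function(path, id_col = "cpg_id") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- df[[id_col]]
  m <- as.matrix(df[setdiff(names(df), id_col)])
  rownames(m) <- ids
  m
}

#' @rdname eduwas_io
#' @export
write_matrix_tsv <- function(x, path, id_col = "cpg_id") {
  df <- tibble::as_tibble(x, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname eduwas_io
#' @export
read_cpg_bed <- function(path) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "cpg_id"),
                        show_col_types = FALSE, progress = FALSE)
  tibble::tibble(cpg_id = df$cpg_id, chrom = df$chrom,
                 pos = df$start + 1L) # 0-based half-open -> 1-based
}

#' @rdname eduwas_io
#' @param annotation Tibble `cpg_id`, `chrom`, `pos` (1-based).
#' @export
write_cpg_bed <- function(annotation, path) {
  bed <- tibble::tibble(chrom = annotation$chrom,
                        start = annotation$pos - 1L,
                        end = annotation$pos,
                        cpg_id = annotation$cpg_id)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write one simulated cohort to a directory
#'
#' Writes the sample sheet, beta matrix, truth table and BED-like CpG
#' annotation (plus expression counts and transcript annotation when
#' present) as TSV files under `dir`.
#'
#' @param cohort List from [generate_cohort()] or [generate_twin_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param expression Optional list from [generate_expression()].
#' @return Invisibly, the paths written.
#' @export
write_sim_cohort <- function(cohort, dir, prefix = "cohort",
                             expression = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, paste0(prefix, "_samples.tsv")),
    methylation = file.path(dir, paste0(prefix, "_methylation.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    annotation = file.path(dir, paste0(prefix, "_cpgs.bed")))
  write_sample_sheet(cohort$samples, paths["samples"])
  write_matrix_tsv(cohort$methylation, paths["methylation"])
  readr::write_tsv(cohort$truth, paths["truth"])
  write_cpg_bed(cohort$truth, paths["annotation"])
  if (!is.null(expression)) {
    paths["expression"] <- file.path(dir, paste0(prefix, "_expression.tsv"))
    paths["tx_annotation"] <- file.path(dir, paste0(prefix, "_transcripts.tsv"))
    write_matrix_tsv(expression$counts, paths["expression"],
                     id_col = "transcript_id")
    readr::write_tsv(expression$annotation, paths["tx_annotation"])
  }
  invisible(paths)
}
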