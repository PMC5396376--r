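# Readers and writers for the plain-text formats used across the package.
# All in-memory coordinates are 0-based half-open; conversions to 1-based
# dialects (bismark coverage) happen only here, at the I/O boundary.

#' Read a bismark-style CpG coverage file
#'
#' Expects the six-column bismark coverage dialect (no header): chrom,
#' start (1-based), end (1-based inclusive), methylation percentage,
#' count methylated, count unmethylated. Positions are converted to 0-based.
#'
#' @param path File path.
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble with columns `chrom`, `pos` (0-based position of the C),
#'   `count_methylated`, `count_unmethylated`, `sample_id`.
#' @export
read_bismark_cov <- function(path, sample_id) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "meth_pct", "count_methylated",
                  "count_unmethylated"),
    col_types = "ciiddd", progress = FALSE
  )
  tibble(
    chrom = df$chrom,
    pos = df$start - 1L,
    count_methylated = as.integer(df$count_methylated),
    count_unmethylated = as.integer(df$count_unmethylated),
    sample_id = sample_id
  )
}

#' Write CpG records as bismark-style coverage files, one per sample
#'
#' @param cpgs Tibble of CpG records (`chrom`, `pos`, `count_methylated`,
#'   `count_unmethylated`, `sample_id`).
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_bismark_cov <- function(cpgs, dir) {
  assert_cols(cpgs, c("chrom", "pos", "count_methylated", "count_unmethylated",
                      "sample_id"), "cpgs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(cpgs, cpgs$sample_id), function(s) {
    path <- file.path(dir, paste0(s$sample_id[1], ".cov"))
    cov <- s$count_methylated + s$count_unmethylated
    out <- tibble(
      chrom = s$chrom, start = s$pos + 1L, end = s$pos + 1L,
      meth_pct = 100 * s$count_methylated / cov,
      count_methylated = s$count_methylated,
      count_unmethylated = s$count_unmethylated
    )
    readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read a BED file (0-based, half-open)
#'
#' Reads the first three to six columns of a BED file into a tibble; extra
#' columns beyond the sixth are ignored.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  names_all <- c("chrom", "start", "end", "name", "score", "strand")
  n_use <- min(ncol, 6L)
  df <- readr::read_tsv(
    path, col_names = names_all[seq_len(n_use)],
    col_types = substr("ciicdc", 1, n_use), progress = FALSE
  )
  as_tibble(df)
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param df Tibble with at least `chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` columns are written in BED order when present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  assert_intervals(df)
  std <- c("chrom", "start", "end", "name", "score", "strand")
  present <- std %in% names(df)
  # BED columns are positional: keep the maximal present prefix
  n_keep <- if (all(present)) 6L else min(which(!present)) - 1L
  keep <- std[seq_len(n_keep)]
  readr::write_tsv(df[keep], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet] (as returned by
#'   [sim_genome()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read / write a long-format qPCR Ct table
#'
#' Long TSV with header columns `assay_id`, `sample_id`, `ct`, `detected`,
#' `quality`; missing Ct values are written as `NA`.
#'
#' @param path File path.
#' @return `read_ct_table()`: a tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, col_types = "ccdld", progress = FALSE)
}

#' @rdname read_ct_table
#' @param ct Tibble of Ct records.
#' @export
write_ct_table <- function(ct, path) {
  assert_cols(ct, c("assay_id", "sample_id", "ct", "detected", "quality"), "ct")
  readr::write_tsv(ct, path, progress = FALSE)
  invisible(path)
}

#' Read / write a TSV matrix with an id column and sample columns
#'
#' Used for count matrices, TPM matrices and wide Ct matrices.
#'
#' @param path File path.
#' @param id Name of the identifier column (first column).
#' @return `read_matrix_tsv()`: a tibble whose first column is `id`.
#' @export
read_matrix_tsv <- function(path, id = "gene_id") {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  names(df)[1] <- id
  df
}

#' @rdname read_matrix_tsv
#' @param df Tibble to write.
#' @export
write_matrix_tsv <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
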