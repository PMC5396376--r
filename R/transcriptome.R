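# Expression utilities: TPM conversion, sequential gene filtering, DEG
# thresholding with fold-change bins, pi-value ranking, DEG persistence and
# correlation-distance hierarchical clustering.

#' Convert a count matrix to TPM
#'
#' `rate = count / length` per gene, scaled so each sample column sums to one
#' million.
#'
#' @param counts Tibble whose first column is `gene_id` followed by one
#'   numeric column per sample.
#' @param gene_lengths Tibble with `gene_id` and `length` (bp, > 0).
#' @return Tibble of the same shape with TPM values.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  assert_cols(counts, "gene_id", "counts")
  assert_cols(gene_lengths, c("gene_id", "length"), "gene_lengths")
  len <- gene_lengths$length[match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(len)) abort("gene length missing for some genes")
  if (any(len <= 0)) abort("gene lengths must be > 0")
  sample_cols <- setdiff(names(counts), "gene_id")
  out <- counts
  for (s in sample_cols) {
    rate <- counts[[s]] / len
    out[[s]] <- 1e6 * rate / sum(rate)
  }
  out
}

#' Sequential expression filters on a TPM matrix
#'
#' Three filters applied in order: (1) drop genes of short-noncoding
#' biotypes; (2) keep genes with at least `min_tpm` TPM in at least
#' `min_samples` samples (both boundaries inclusive); (3) drop the
#' `drop_low_variability_fraction` least-variable remaining genes, where
#' variability is the standard deviation of `log2(tpm + 1)` across samples
#' (ties broken deterministically by gene id).
#'
#' @param tpm TPM tibble (`gene_id` + sample columns).
#' @param biotypes Tibble with `gene_id`, `biotype` covering every gene.
#' @param short_noncoding_labels Biotype labels removed in step 1.
#' @param min_tpm,min_samples Expression filter thresholds (defaults 5 and 3).
#' @param drop_low_variability_fraction Fraction of lowest-variability genes
#'   dropped in step 3 (default 0.2; the count dropped is
#'   `floor(fraction * n)`).
#' @return Tibble of retained `gene_id`s with their `variability`.
#' @export
filter_genes <- function(tpm, biotypes,
                         short_noncoding_labels = c("miRNA", "snoRNA",
                                                    "snRNA", "misc_RNA"),
                         min_tpm = 5, min_samples = 3,
                         drop_low_variability_fraction = 0.2) {
  assert_cols(tpm, "gene_id", "tpm")
  assert_cols(biotypes, c("gene_id", "biotype"), "biotypes")
  bt <- biotypes$biotype[match(tpm$gene_id, biotypes$gene_id)]
  if (anyNA(bt)) abort("biotype missing for some genes")
  mat <- as.matrix(tpm[setdiff(names(tpm), "gene_id")])
  rownames(mat) <- tpm$gene_id

  mat <- mat[!(bt %in% short_noncoding_labels), , drop = FALSE]
  expressed <- rowSums(mat >= min_tpm) >= min_samples
  mat <- mat[expressed, , drop = FALSE]

  variability <- apply(log2(mat + 1), 1, sd)
  n_drop <- floor(drop_low_variability_fraction * nrow(mat))
  ord <- order(variability, rownames(mat))
  keep <- sort(ord[seq_len(nrow(mat)) > n_drop])
  tibble(gene_id = rownames(mat)[keep], variability = variability[keep])
}

#' Call differentially expressed genes from a contrast table
#'
#' A gene is `up` when `log2fc > lfc_threshold` and `p < p_threshold`,
#' `down` symmetrically (strict inequalities), otherwise `ns`. Significant
#' genes are also binned by absolute fold-change.
#'
#' @param de_table Tibble with `gene_id`, `log2fc`, `p` (and optionally `q`).
#' @param lfc_threshold,p_threshold Strict thresholds (defaults 1 and 0.01).
#' @param bins Increasing |log2FC| bin edges; default `(1, 2], (2, 4], > 4`.
#' @param use_q Threshold on `q` instead of raw `p` (default `FALSE`).
#' @return The input with added `deg_status` and `lfc_bin` columns.
#' @export
deg_call <- function(de_table, lfc_threshold = 1, p_threshold = 0.01,
                     bins = c(1, 2, 4, Inf), use_q = FALSE) {
  assert_cols(de_table, c("gene_id", "log2fc", "p"), "de_table")
  pval <- if (use_q) de_table$q else de_table$p
  if (anyNA(pval)) {
    warn(sprintf("%d gene(s) with missing p-values reported as ns",
                 sum(is.na(pval))))
  }
  sig <- !is.na(pval) & pval < p_threshold &
    abs(de_table$log2fc) > lfc_threshold
  status <- ifelse(sig & de_table$log2fc > 0, "up",
                   ifelse(sig, "down", "ns"))
  lfc_bin <- ifelse(sig, as.character(cut(abs(de_table$log2fc), bins)),
                    NA_character_)
  mutate(de_table, deg_status = status, lfc_bin = lfc_bin)
}

#' Rank genes by pi-value
#'
#' `pi = -log10(q) * log2fc`, combining significance with effect direction
#' and magnitude; genes are returned sorted by decreasing pi, ready for
#' preranked enrichment tools. Zero q-values are clamped to the smallest
#' positive q observed so ranks are preserved without infinities.
#'
#' @param de_table Tibble with `gene_id`, `log2fc`, `q`.
#' @return Tibble with `gene_id`, `log2fc`, `q`, `pi`, sorted by `pi`
#'   descending.
#' @export
pi_rank <- function(de_table) {
  assert_cols(de_table, c("gene_id", "log2fc", "q"), "de_table")
  q <- de_table$q
  if (any(q < 0 | q > 1, na.rm = TRUE)) abort("q-values must lie in [0, 1]")
  pos_min <- suppressWarnings(min(q[q > 0], na.rm = TRUE))
  if (!is.finite(pos_min)) pos_min <- .Machine$double.xmin
  pi_val <- -log10(pmax(q, pos_min)) * de_table$log2fc
  de_table |>
    mutate(pi = pi_val) |>
    arrange(dplyr::desc(.data$pi)) |>
    select("gene_id", "log2fc", "q", "pi")
}

#' DEG persistence between two timepoints
#'
#' Fraction of genes called `up` at the first timepoint still `up` at the
#' second (and analogously for `down`), plus the full fate partition
#' (persisted / switched / dropped out).
#'
#' @param deg_t1,deg_t2 Tibbles with `gene_id`, `deg_status` on the same gene
#'   universe (see [deg_call()]).
#' @return List: `fractions` (tibble `direction`, `n_t1`, `n_persist`,
#'   `persistence`; `persistence` is `NA` for an empty t1 set) and `fates`
#'   (tibble `gene_id`, `status_t1`, `status_t2`, `fate`).
#' @export
deg_persistence <- function(deg_t1, deg_t2) {
  assert_cols(deg_t1, c("gene_id", "deg_status"), "deg_t1")
  assert_cols(deg_t2, c("gene_id", "deg_status"), "deg_t2")
  if (!setequal(deg_t1$gene_id, deg_t2$gene_id)) {
    abort("the two timepoints must share one gene universe")
  }
  joined <- inner_join(
    select(deg_t1, "gene_id", status_t1 = "deg_status"),
    select(deg_t2, "gene_id", status_t2 = "deg_status"),
    by = "gene_id"
  )
  fates <- joined |>
    filter(.data$status_t1 != "ns") |>
    mutate(fate = dplyr::case_when(
      .data$status_t1 == .data$status_t2 ~ "persisted",
      .data$status_t2 == "ns" ~ "dropped",
      TRUE ~ "switched"
    ))
  fractions <- purrr::map_dfr(c("up", "down"), function(dir) {
    t1 <- fates[fates$status_t1 == dir, ]
    n1 <- nrow(t1)
    np <- sum(t1$fate == "persisted")
    tibble(direction = dir, n_t1 = n1, n_persist = np,
           persistence = if (n1 == 0) NA_real_ else np / n1)
  })
  list(fractions = fractions, fates = fates)
}

#' Hierarchical clustering on 1 - Spearman correlation
#'
#' Unsupervised average-linkage (UPGMA) clustering with the distance
#' `1 - rho` (Spearman, average ranks for ties). Leaf order is made
#' deterministic: at every merge, the subtree containing the smallest
#' original item index goes left.
#'
#' @param mat Numeric matrix or tibble of observations; items to cluster are
#'   columns when `axis = "cols"` (default) or rows when `axis = "rows"`.
#' @param axis `"cols"` or `"rows"`.
#' @return An object of class `exit_clust`: list with `dist` (the distance
#'   matrix), `hclust` (the reordered [stats::hclust] tree) and `leaf_order`
#'   (character vector of item labels).
#' @export
correlation_cluster <- function(mat, axis = c("cols", "rows")) {
  axis <- match.arg(axis)
  if (is.data.frame(mat)) {
    if ("gene_id" %in% names(mat)) {
      ids <- mat$gene_id
      mat <- as.matrix(mat[setdiff(names(mat), "gene_id")])
      rownames(mat) <- ids
    } else {
      mat <- as.matrix(mat)
    }
  }
  if (axis == "rows") mat <- t(mat)
  if (ncol(mat) < 2) abort("at least 2 items are required")
  if (nrow(mat) < 3) abort("at least 3 observations per item are required")
  zero_var <- apply(mat, 2, function(x) sd(x) == 0)
  if (any(zero_var)) {
    abort(sprintf("zero-variance item(s): %s",
                  paste(colnames(mat)[zero_var], collapse = ", ")))
  }
  rho <- cor(mat, method = "spearman")
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "average")
  hc <- reorder_min_leaf(hc)
  structure(list(dist = as.matrix(1 - rho), hclust = hc,
                 leaf_order = hc$labels[hc$order]),
            class = "exit_clust")
}

# deterministic leaf order: subtree holding the smaller minimum original
# item index goes left at every merge
reorder_min_leaf <- function(hc) {
  n_merge <- nrow(hc$merge)
  min_leaf <- numeric(n_merge)
  node_min <- function(v) if (v < 0) -v else min_leaf[v]
  for (i in seq_len(n_merge)) {
    l <- node_min(hc$merge[i, 1]); r <- node_min(hc$merge[i, 2])
    if (r < l) hc$merge[i, ] <- hc$merge[i, c(2, 1)]
    min_leaf[i] <- min(l, r)
  }
  order <- integer(0)
  walk <- function(v) {
    if (v < 0) return(-v)
    c(walk(hc$merge[v, 1]), walk(hc$merge[v, 2]))
  }
  hc$order <- walk(n_merge)
  hc
}

#' @export
print.exit_clust <- function(x, ...) {
  cat(sprintf("Spearman-distance UPGMA clustering of %d items\n",
              length(x$leaf_order)))
  cat("leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the merge tree of a correlation clustering
#'
#' @param x An `exit_clust` object.
#' @param ... Unused.
#' @return Tibble with one row per merge: `merge`, `left`, `right` (negative
#'   values are leaves), `height`.
#' @export
tidy.exit_clust <- function(x, ...) {
  tibble(merge = seq_len(nrow(x$hclust$merge)),
         left = x$hclust$merge[, 1],
         right = x$hclust$merge[, 2],
         height = x$hclust$height)
}

#' @rdname tidy.exit_clust
#' @return `glance()`: one-row tibble with `n_items`, `min_height`,
#'   `max_height`.
#' @export
glance.exit_clust <- function(x, ...) {
  tibble(n_items = length(x$leaf_order),
         min_height = min(x$hclust$height),
         max_height = max(x$hclust$height))
}
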