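# Genomic-region classes: interval extension/merging, CpG density promoter
# classification, tile annotation with precedence, per-class methylation
# dynamics, and metagene profiles over gene bodies with flanks.

#' Default precedence of genomic region classes
#'
#' Ordered labels used by [annotate_tiles()] when a tile overlaps several
#' classes; earlier labels win. `"other"` is the implicit fallback.
#' @return Character vector.
#' @export
region_precedence <- function() {
  c("CGI", "canyon", "HCP", "LCP", "enhancer", "TE", "exon", "intron")
}

#' Extend intervals symmetrically and merge overlaps
#'
#' Pads each interval by `pad` bp on both sides, clips to chromosome bounds,
#' and merges any resulting overlaps (used e.g. to extend enhancer
#' coordinates by 1 kb).
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param pad Padding in bp (>= 0).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return Tibble of merged, clipped intervals sorted by position.
#' @export
extend_intervals <- function(intervals, pad = 1000, chrom_lengths) {
  assert_intervals(intervals)
  assert_scalar_number(pad, "pad", 0)
  padded <- intervals |>
    mutate(start = pmax(0, .data$start - pad),
           end = pmin(unname(chrom_lengths[.data$chrom]), .data$end + pad))
  gr <- GenomicRanges::reduce(intervals_to_granges(padded))
  granges_to_intervals(gr)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_intervals <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = GenomicRanges::end(gr)) |>
    arrange(.data$chrom, .data$start)
}

#' CpG observed/expected ratio of a sequence
#'
#' `ratio = (N_CpG * L) / (N_C * N_G)`, where `N_CpG` counts `CG`
#' dinucleotides, and `N` bases are excluded from all counts with the
#' effective length reduced accordingly. Returns 0 when the sequence contains
#' no C or no G.
#'
#' @param sequence Character vector of A/C/G/T/N sequences (case
#'   insensitive), or a [Biostrings::DNAStringSet].
#' @return Numeric vector of ratios.
#' @examples
#' cpg_obs_exp("CGCGCG")  # 2.0
#' @export
cpg_obs_exp <- function(sequence) {
  if (methods::is(sequence, "DNAStringSet") ||
      methods::is(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  s <- toupper(sequence)
  if (any(grepl("[^ACGTN]", s))) {
    abort("sequences may contain only A, C, G, T or N")
  }
  n_c <- stringr::str_count(s, stringr::fixed("C"))
  n_g <- stringr::str_count(s, stringr::fixed("G"))
  n_n <- stringr::str_count(s, stringr::fixed("N"))
  len <- nchar(s) - n_n
  # a CG pair cannot span an N, so counting on the raw string is exact
  n_cg <- stringr::str_count(s, "(?=CG)")
  ifelse(n_c * n_g == 0, 0, (n_cg * len) / (n_c * n_g))
}

#' Split promoter windows into high- and low-CpG classes
#'
#' Promoters with CpG observed/expected ratio strictly above `threshold` are
#' high-CpG promoters (HCP); the rest, including the boundary, are low-CpG
#' promoters (LCP).
#'
#' @param promoters Promoter window tibble from [extract_promoters()] (needs
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param threshold Ratio boundary (default 0.29).
#' @return The input with added `cpg_ratio` and `promoter_class` columns.
#' @export
split_promoters_hcp_lcp <- function(promoters, genome, threshold = 0.29) {
  assert_intervals(promoters, "promoters")
  seqs <- if ("seq" %in% names(promoters)) {
    promoters$seq
  } else {
    fetch_sequences(promoters, genome)
  }
  ratio <- cpg_obs_exp(seqs)
  promoters |>
    mutate(cpg_ratio = ratio,
           promoter_class = if_else(ratio > threshold, "HCP", "LCP"))
}

fetch_sequences <- function(df, genome) {
  bad <- setdiff(unique(df$chrom), names(genome))
  if (length(bad) > 0) {
    abort(sprintf("chromosome(s) absent from genome: %s",
                  paste(bad, collapse = ", ")))
  }
  lens <- Biostrings::width(genome)[match(df$chrom, names(genome))]
  if (any(df$start < 0 | df$end > lens)) {
    abort("interval outside genome bounds")
  }
  vapply(seq_len(nrow(df)), function(i) {
    as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                    start = df$start[i] + 1,
                                    end = df$end[i]))
  }, character(1))
}

#' Assign each tile to a genomic region class
#'
#' A tile overlapping at least one bp of a class belongs to that class;
#' multi-class overlaps are resolved by `precedence` (earlier label wins);
#' tiles overlapping nothing are labelled `"other"`.
#'
#' @param tiles Tibble with `chrom`, `start`, `end`.
#' @param region_classes Tibble with `label`, `chrom`, `start`, `end`.
#' @param precedence Ordered character vector covering every label present in
#'   `region_classes`.
#' @return The input tiles with an added `label` column.
#' @export
annotate_tiles <- function(tiles, region_classes,
                           precedence = region_precedence()) {
  assert_intervals(tiles, "tiles")
  assert_cols(region_classes, c("label", "chrom", "start", "end"),
              "region_classes")
  unknown <- setdiff(unique(region_classes$label), precedence)
  if (length(unknown) > 0) {
    abort(sprintf("label(s) not covered by `precedence`: %s",
                  paste(unknown, collapse = ", ")))
  }
  tile_gr <- intervals_to_granges(tiles)
  label <- rep("other", nrow(tiles))
  assigned <- rep(FALSE, nrow(tiles))
  for (lab in precedence) {
    cls <- filter(region_classes, .data$label == lab)
    if (nrow(cls) == 0) next
    hit <- IRanges::overlapsAny(tile_gr, intervals_to_granges(cls))
    take <- hit & !assigned
    label[take] <- lab
    assigned <- assigned | hit
  }
  mutate(tiles, label = label)
}

#' Per-region-class methylation change between two timepoints
#'
#' One Delta entry (later minus earlier methylation, percentage points) per
#' labelled tile, plus the `"genome"` aggregate over all tiles, with summary
#' quantiles per label.
#'
#' @param tiles_t1,tiles_t2 Pooled tile tibbles on the same tile universe
#'   (see [pool_tiles()]).
#' @param labels Character vector of per-tile labels (same order as the tile
#'   tibbles) or a labelled tile tibble from [annotate_tiles()].
#' @return List: `deltas` (tibble `label`, `chrom`, `start`, `end`, `delta`,
#'   including the `"genome"` rows) and `summary` (tibble `label`, `n`,
#'   `median`, `q25`, `q75`, `frac_gt20`).
#' @export
region_delta_distribution <- function(tiles_t1, tiles_t2, labels) {
  if (is.data.frame(labels)) {
    key1 <- paste(tiles_t1$chrom, tiles_t1$start)
    labels <- labels$label[match(key1, paste(labels$chrom, labels$start))]
  }
  if (nrow(tiles_t1) != nrow(tiles_t2) ||
      any(tiles_t1$start != tiles_t2$start)) {
    abort("tile universes must match between timepoints")
  }
  if (length(labels) != nrow(tiles_t1)) {
    abort("`labels` must have one entry per tile")
  }
  base <- tibble(label = labels, chrom = tiles_t1$chrom,
                 start = tiles_t1$start, end = tiles_t1$end,
                 delta = tiles_t2$meth_pct - tiles_t1$meth_pct)
  deltas <- bind_rows(base, mutate(base, label = "genome"))
  summary <- deltas |>
    group_by(.data$label) |>
    summarise(n = n(),
              median = median(.data$delta),
              q25 = quantile(.data$delta, 0.25, names = FALSE),
              q75 = quantile(.data$delta, 0.75, names = FALSE),
              frac_gt20 = mean(abs(.data$delta) > 20), .groups = "drop")
  list(deltas = deltas, summary = summary)
}

#' Metagene methylation profile over gene bodies and flanks
#'
#' Gene bodies are length-normalised into `body_bins` bins; upstream and
#' downstream flanks of `flank` bp use `flank_bins` fixed-width bins each.
#' Minus-strand genes are reversed so bins always run 5' to 3'. Each bin
#' value is the coverage-weighted mean methylation percentage of all CpGs
#' mapping to it across genes; bins receiving no CpG are `NA`, never zero.
#' Genes shorter than `body_bins` bp are excluded (and counted in the
#' `n_excluded` attribute).
#'
#' @param cpgs Tibble of CpG records (pooled over the samples of interest).
#' @param genes Gene tibble with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (typically protein-coding genes only).
#' @param flank Flank width in bp (default 10000).
#' @param body_bins,flank_bins Bin counts (defaults 40 and 20).
#' @return Tibble with `bin` (1-based, 5' upstream first), `zone`
#'   (`upstream` / `body` / `downstream`), `meth_pct`, `coverage` (total
#'   reads informing the bin).
#' @export
metagene_profile <- function(cpgs, genes, flank = 10000, body_bins = 40,
                             flank_bins = 20) {
  assert_cols(genes, c("gene_id", "chrom", "strand", "start", "end"), "genes")
  assert_scalar_number(flank, "flank", 0)
  short <- genes$end - genes$start < body_bins
  if (any(short)) {
    message(sprintf("%d gene(s) shorter than %d bp excluded from the profile",
                    sum(short), body_bins))
  }
  genes <- genes[!short, ]
  total_bins <- 2 * flank_bins + body_bins
  w <- flank / flank_bins
  acc_meth <- numeric(total_bins)
  acc_cov <- numeric(total_bins)
  cpg_by_chrom <- split(cpgs, cpgs$chrom)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cc <- cpg_by_chrom[[g$chrom]]
    if (is.null(cc)) next
    inwin <- cc$pos >= g$start - flank & cc$pos < g$end + flank
    if (!any(inwin)) next
    cc <- cc[inwin, ]
    body_len <- g$end - g$start
    bin <- integer(nrow(cc))
    up <- cc$pos < g$start
    down <- cc$pos >= g$end
    body <- !up & !down
    bin[up] <- floor((cc$pos[up] - (g$start - flank)) / w)
    bin[body] <- flank_bins +
      pmin(floor((cc$pos[body] - g$start) / body_len * body_bins),
           body_bins - 1)
    bin[down] <- flank_bins + body_bins +
      pmin(floor((cc$pos[down] - g$end) / w), flank_bins - 1)
    if (g$strand == "-") bin <- total_bins - 1 - bin
    cov <- cc$count_methylated + cc$count_unmethylated
    acc_meth <- acc_meth + unname(tapply_sum(cc$count_methylated, bin, total_bins))
    acc_cov <- acc_cov + unname(tapply_sum(cov, bin, total_bins))
  }
  tibble(
    bin = seq_len(total_bins),
    zone = rep(c("upstream", "body", "downstream"),
               c(flank_bins, body_bins, flank_bins)),
    meth_pct = ifelse(acc_cov > 0, 100 * acc_meth / acc_cov, NA_real_),
    coverage = acc_cov
  )
}

# sum x by 0-based bin index into a fixed-length vector
tapply_sum <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(x, bin)
  out[as.integer(rownames(agg)) + 1] <- agg[, 1]
  out
}
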