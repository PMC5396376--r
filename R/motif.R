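# Bipartite E-box motif analysis: promoter window extraction, paired
# half-site scanning with a bounded gap on both strands, and one-sided exact
# enrichment among DEG promoters versus a genome-wide promoter background.

#' Named bipartite motif presets
#'
#' Two published parameterisations of the paired Zeb2 half-site search:
#' `"methods"` — two `YACCTG` half-sites at most 40 bp apart; and
#' `"results-fig2d"` — `CACCTG` plus `CACCT` at most 45 bp apart. The presets
#' differ in the source material itself, so both ship and neither is
#' "corrected" toward the other.
#'
#' @param preset `"methods"` (default) or `"results-fig2d"`.
#' @return List with `motif_a`, `motif_b`, `max_gap`.
#' @export
motif_preset <- function(preset = c("methods", "results-fig2d")) {
  preset <- match.arg(preset)
  switch(preset,
    "methods" = list(motif_a = "YACCTG", motif_b = "YACCTG", max_gap = 40),
    "results-fig2d" = list(motif_a = "CACCTG", motif_b = "CACCT",
                           max_gap = 45)
  )
}

#' Extract promoter windows around transcription start sites
#'
#' Windows `[TSS - flank, TSS + flank)` in genome coordinates (regardless of
#' strand), clipped at chromosome ends; sequences are returned as plus-strand
#' text.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `strand`, `tss`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param flank Half-width in bp (default 2000).
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `clipped` (logical) and `seq`.
#' @export
extract_promoters <- function(genes, genome, flank = 2000) {
  assert_cols(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  bad <- setdiff(unique(genes$chrom), names(genome))
  if (length(bad) > 0) {
    offenders <- genes$gene_id[genes$chrom %in% bad]
    abort(sprintf("unknown chromosome for gene(s): %s",
                  paste(utils::head(offenders, 5), collapse = ", ")))
  }
  lens <- Biostrings::width(genome)[match(genes$chrom, names(genome))]
  out <- genes |>
    mutate(start = pmax(0, .data$tss - flank),
           end = pmin(lens, .data$tss + flank),
           clipped = .data$start != .data$tss - flank |
             .data$end != .data$tss + flank) |>
    select("gene_id", "chrom", "strand", "start", "end", "clipped")
  if (any(out$clipped)) {
    message(sprintf("%d promoter window(s) clipped at chromosome ends",
                    sum(out$clipped)))
  }
  out$seq <- fetch_sequences(out, genome)
  out
}

#' Scan a sequence for bipartite half-site pairs
#'
#' Finds all ordered pairs of IUPAC half-site occurrences on the same strand
#' with a non-negative gap (end of the first half-site to start of the
#' second) of at most `max_gap` bp — i.e. half-sites never overlap. When the
#' two motifs differ, either may come first and both orders are counted once
#' each. Minus-strand pairs are found by scanning the reverse complement and
#' reported in plus-strand coordinates (the coordinates of each half-site
#' interval; "first" means 5'-most on the hit's own strand).
#'
#' @param sequence A single sequence (character or [Biostrings::DNAString]).
#' @param motif_a,motif_b IUPAC half-site patterns (default `YACCTG` twice).
#' @param max_gap Maximum gap in bp (default 40).
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @return Tibble of hits sorted by `first_start`: `first_start`,
#'   `first_end`, `second_start`, `second_end` (0-based half-open,
#'   plus-strand), `gap`, `strand`, `first_motif`, `second_motif`.
#' @examples
#' scan_bipartite("CACCTGAAAACACCTG")
#' @export
scan_bipartite <- function(sequence, motif_a = "YACCTG", motif_b = "YACCTG",
                           max_gap = 40, both_strands = TRUE) {
  assert_scalar_number(max_gap, "max_gap", 0)
  for (m in c(motif_a, motif_b)) {
    if (grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                     collapse = "")), toupper(m))) {
      abort(sprintf("invalid IUPAC symbol in motif '%s'", m))
    }
  }
  subject <- if (methods::is(sequence, "DNAString")) sequence else {
    Biostrings::DNAString(toupper(as.character(sequence)))
  }
  plus <- pair_halfsites(subject, motif_a, motif_b, max_gap)
  plus$strand <- rep("+", nrow(plus))
  hits <- plus
  if (both_strands) {
    L <- length(subject)
    minus <- pair_halfsites(Biostrings::reverseComplement(subject),
                            motif_a, motif_b, max_gap)
    if (nrow(minus) > 0) {
      # map each half-site interval back to plus-strand coordinates
      flip <- function(start, end) list(start = L - end, end = L - start)
      f <- flip(minus$first_start, minus$first_end)
      s <- flip(minus$second_start, minus$second_end)
      minus$first_start <- f$start; minus$first_end <- f$end
      minus$second_start <- s$start; minus$second_end <- s$end
    }
    minus$strand <- rep("-", nrow(minus))
    hits <- bind_rows(plus, minus)
  }
  hits |>
    select("first_start", "first_end", "second_start", "second_end",
           "gap", "strand", "first_motif", "second_motif") |>
    arrange(.data$first_start, .data$second_start, .data$strand)
}

# all ordered (a-then-b) pairs on one strand, plus (b-then-a) when motifs
# differ; coordinates 0-based half-open on the scanned strand
pair_halfsites <- function(subject, motif_a, motif_b, max_gap) {
  occ <- function(motif) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                  fixed = FALSE)
    tibble(start = Biostrings::start(m) - 1, end = Biostrings::end(m),
           match = as.character(m))
  }
  occ_a <- occ(motif_a)
  same <- identical(toupper(motif_a), toupper(motif_b))
  occ_b <- if (same) occ_a else occ(motif_b)
  pair <- function(first, second) {
    if (nrow(first) == 0 || nrow(second) == 0) return(empty_hits())
    idx <- tidyr::expand_grid(i = seq_len(nrow(first)),
                              j = seq_len(nrow(second)))
    gap <- second$start[idx$j] - first$end[idx$i]
    keep <- gap >= 0 & gap <= max_gap
    tibble(first_start = first$start[idx$i][keep],
           first_end = first$end[idx$i][keep],
           second_start = second$start[idx$j][keep],
           second_end = second$end[idx$j][keep],
           gap = gap[keep],
           first_motif = first$match[idx$i][keep],
           second_motif = second$match[idx$j][keep])
  }
  out <- pair(occ_a, occ_b)
  if (!same) out <- bind_rows(out, pair(occ_b, occ_a))
  out
}

empty_hits <- function() {
  tibble(first_start = integer(0), first_end = integer(0),
         second_start = integer(0), second_end = integer(0),
         gap = integer(0), first_motif = character(0),
         second_motif = character(0))
}

#' Per-promoter bipartite hit table
#'
#' Scans every promoter sequence and reports, per gene, the number of
#' bipartite hits and a presence flag (at least one hit) — the unit used by
#' the enrichment test.
#'
#' @param promoters Promoter tibble from [extract_promoters()] (needs
#'   `gene_id` and `seq`).
#' @param motif_a,motif_b,max_gap,both_strands Scan parameters, see
#'   [scan_bipartite()]; pass a preset via `!!!motif_preset(...)` semantics
#'   by supplying its elements.
#' @return Tibble with `gene_id`, `n_hits`, `has_hit`.
#' @export
promoter_hit_table <- function(promoters, motif_a = "YACCTG",
                               motif_b = "YACCTG", max_gap = 40,
                               both_strands = TRUE) {
  assert_cols(promoters, c("gene_id", "seq"), "promoters")
  n_hits <- vapply(promoters$seq, function(s) {
    nrow(scan_bipartite(s, motif_a, motif_b, max_gap, both_strands))
  }, numeric(1), USE.NAMES = FALSE)
  tibble(gene_id = promoters$gene_id, n_hits = n_hits, has_hit = n_hits > 0)
}

#' One-sided exact enrichment of motif-bearing promoters
#'
#' One-sided Fisher's exact (hypergeometric tail) test comparing the fraction
#' of foreground promoters carrying at least one bipartite hit with the
#' background fraction. The odds ratio uses the Haldane correction when any
#' cell is zero.
#'
#' @param k_fg,n_fg Motif-positive and total foreground promoters.
#' @param k_bg,n_bg Motif-positive and total background promoters.
#' @param alternative `"over"` (enrichment) or `"under"` (depletion).
#' @return One-row tibble: `k_fg`, `n_fg`, `k_bg`, `n_bg`, `odds_ratio`,
#'   `p_over`, `p_under`.
#' @export
fisher_enrichment <- function(k_fg, n_fg, k_bg, n_bg,
                              alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  if (any(c(k_fg, n_fg, k_bg, n_bg) < 0)) abort("counts must be non-negative")
  if (k_fg > n_fg || k_bg > n_bg) abort("hits cannot exceed totals")
  if (n_fg < 1 || n_bg < 1) abort("totals must be >= 1")
  a <- k_fg; b <- n_fg - k_fg; c <- k_bg; d <- n_bg - k_bg
  res <- tibble(
    k_fg = k_fg, n_fg = n_fg, k_bg = k_bg, n_bg = n_bg,
    odds_ratio = odds_ratio_2x2(a, b, c, d),
    p_over = fisher_test_2x2(a, b, c, d, "greater"),
    p_under = fisher_test_2x2(a, b, c, d, "less")
  )
  res$p <- if (alternative == "over") res$p_over else res$p_under
  res$alternative <- alternative
  res
}

#' Motif enrichment report for DEG partitions
#'
#' Tests over-representation among upregulated DEG promoters,
#' under-representation among downregulated ones, and over-representation in
#' the full DEG set, each against the genome-wide promoter background (which
#' includes the foreground genes).
#'
#' @param deg_status Tibble with `gene_id` and `deg_status` in
#'   `{up, down, ns}` (see [deg_call()]).
#' @param hit_table Per-gene hit table from [promoter_hit_table()] covering
#'   the whole background.
#' @return Tibble with one row per partition (`up`, `down`, `all`):
#'   enrichment counts, odds ratio and one-sided p-values. Empty partitions
#'   are omitted with a warning.
#' @export
deg_motif_report <- function(deg_status, hit_table) {
  assert_cols(deg_status, c("gene_id", "deg_status"), "deg_status")
  assert_cols(hit_table, c("gene_id", "has_hit"), "hit_table")
  missing <- setdiff(deg_status$gene_id, hit_table$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("DEG id(s) missing from hit table: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  k_bg <- sum(hit_table$has_hit)
  n_bg <- nrow(hit_table)
  partitions <- list(
    up = list(ids = deg_status$gene_id[deg_status$deg_status == "up"],
              alternative = "over"),
    down = list(ids = deg_status$gene_id[deg_status$deg_status == "down"],
                alternative = "under"),
    all = list(ids = deg_status$gene_id[deg_status$deg_status != "ns"],
               alternative = "over")
  )
  rows <- purrr::imap(partitions, function(part, name) {
    if (length(part$ids) == 0) {
      warn(sprintf("no genes in DEG partition '%s'; result omitted", name))
      return(NULL)
    }
    sub <- hit_table$has_hit[hit_table$gene_id %in% part$ids]
    res <- fisher_enrichment(sum(sub), length(sub), k_bg, n_bg,
                             part$alternative)
    mutate(res, partition = name, .before = 1)
  })
  bind_rows(rows)
}
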