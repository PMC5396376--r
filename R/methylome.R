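# Tile-based RRBS analytics: CpG filtering, common-site intersection,
# 5%-bin histograms, 400 bp tiling, pooled-count DMR calling and temporal
# gain/loss accounting.

#' Filter CpG records by depth and extreme coverage
#'
#' Removes records below a minimum sequencing depth, then — per sample —
#' removes records whose coverage lies strictly above the `1 - fraction`
#' empirical quantile (type 7) of the remaining coverages, discarding
#' PCR-duplicated/repetitive outlier sites.
#'
#' @param cpgs Tibble of CpG records (`chrom`, `pos`, `count_methylated`,
#'   `count_unmethylated`, `sample_id`).
#' @param min_depth Minimum total reads per CpG (default 5).
#' @param top_coverage_fraction Fraction of highest-coverage sites removed
#'   per sample (default 0.001, i.e. the top 0.1%); must lie in `[0, 0.5)`.
#' @return Filtered tibble, with attributes `n_removed_depth` and
#'   `n_removed_top` recording the removal counts.
#' @export
filter_cpgs <- function(cpgs, min_depth = 5, top_coverage_fraction = 0.001) {
  assert_cols(cpgs, c("chrom", "pos", "count_methylated",
                      "count_unmethylated", "sample_id"), "cpgs")
  assert_scalar_number(min_depth, "min_depth", 1)
  assert_scalar_number(top_coverage_fraction, "top_coverage_fraction",
                       0, 0.5, strict_upper = TRUE)
  if (nrow(cpgs) == 0) {
    warn("no CpG records to filter")
    return(cpgs)
  }
  coverage <- cpgs$count_methylated + cpgs$count_unmethylated
  deep <- coverage >= min_depth
  kept <- cpgs[deep, ]
  cov_kept <- coverage[deep]
  keep2 <- unlist(lapply(split(seq_len(nrow(kept)), kept$sample_id),
    function(i) {
      cut <- quantile(cov_kept[i], 1 - top_coverage_fraction, type = 7,
                      names = FALSE)
      i[cov_kept[i] <= cut]
    }), use.names = FALSE)
  out <- kept[sort(keep2), ]
  attr(out, "n_removed_depth") <- sum(!deep)
  attr(out, "n_removed_top") <- nrow(kept) - nrow(out)
  out
}

#' Restrict CpG records to sites covered in every sample
#'
#' @param cpgs Tibble of CpG records from two or more samples.
#' @return Tibble containing only `(chrom, pos)` sites present in all
#'   samples, sorted by sample, chromosome and position.
#' @export
intersect_common_cpgs <- function(cpgs) {
  assert_cols(cpgs, c("chrom", "pos", "sample_id"), "cpgs")
  n_samples <- dplyr::n_distinct(cpgs$sample_id)
  if (n_samples < 2) abort("at least 2 samples are required")
  common <- cpgs |>
    distinct(.data$sample_id, .data$chrom, .data$pos) |>
    count(.data$chrom, .data$pos) |>
    filter(.data$n == n_samples) |>
    select("chrom", "pos")
  if (nrow(common) == 0) warn("no CpG sites are common to all samples")
  cpgs |>
    semi_join(common, by = c("chrom", "pos")) |>
    arrange(.data$sample_id, .data$chrom, .data$pos)
}

#' Per-site methylation histogram
#'
#' Counts CpG sites into fixed-width methylation-percentage bins
#' `[0, w), [w, 2w), ..., [100 - w, 100]`; the last bin is closed so fully
#' methylated sites are counted.
#'
#' @param cpgs Tibble of CpG records for one sample (or one pooled set).
#' @param bin_width Bin width in percent; must divide 100 (default 5).
#' @return Tibble with `bin_start`, `bin_end`, `n`.
#' @export
methylation_histogram <- function(cpgs, bin_width = 5) {
  assert_cols(cpgs, c("count_methylated", "count_unmethylated"), "cpgs")
  if (100 %% bin_width != 0) abort("`bin_width` must divide 100")
  n_bins <- as.integer(100 / bin_width)
  coverage <- cpgs$count_methylated + cpgs$count_unmethylated
  pct <- 100 * cpgs$count_methylated / coverage
  bin <- pmin(floor(pct / bin_width), n_bins - 1)
  counts <- tabulate(bin + 1, nbins = n_bins)
  tibble(bin_start = (seq_len(n_bins) - 1) * bin_width,
         bin_end = seq_len(n_bins) * bin_width,
         n = counts)
}

#' Pool CpG records into fixed, anchored tiles
#'
#' Non-overlapping windows of `tile_size` bp anchored at coordinate 0 on each
#' chromosome. A tile is emitted only when it contains at least `min_cpgs`
#' distinct CpG sites. Tile methylation is coverage-weighted:
#' `100 * sum(meth) / (sum(meth) + sum(unmeth))`, never the mean of per-site
#' percentages. Records should already be restricted to common sites (see
#' [intersect_common_cpgs()]) so tiles are comparable across samples.
#'
#' @param cpgs Tibble of CpG records (one or more samples).
#' @param tile_size Window width in bp (default 400).
#' @param min_cpgs Minimum distinct CpG sites per tile (default 3).
#' @return Tibble with one row per sample x tile: `sample_id`, `chrom`,
#'   `start`, `end`, `n_cpgs`, `meth`, `unmeth`, `meth_pct`.
#' @export
tile_methylation <- function(cpgs, tile_size = 400, min_cpgs = 3) {
  assert_cols(cpgs, c("chrom", "pos", "count_methylated",
                      "count_unmethylated", "sample_id"), "cpgs")
  cpgs |>
    mutate(start = (.data$pos %/% tile_size) * tile_size) |>
    group_by(.data$sample_id, .data$chrom, .data$start) |>
    summarise(n_cpgs = dplyr::n_distinct(.data$pos),
              meth = sum(.data$count_methylated),
              unmeth = sum(.data$count_unmethylated), .groups = "drop") |>
    filter(.data$n_cpgs >= min_cpgs) |>
    mutate(end = .data$start + tile_size,
           meth_pct = 100 * .data$meth / (.data$meth + .data$unmeth)) |>
    select("sample_id", "chrom", "start", "end", "n_cpgs", "meth", "unmeth",
           "meth_pct") |>
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Pool per-sample tiles into one group
#'
#' Sums methylated/unmethylated counts across the given samples per tile.
#' Only tiles present in every selected sample are kept, so pooled tile sets
#' from a common-site universe stay coordinate-matched across groups.
#'
#' @param tiles Output of [tile_methylation()].
#' @param samples Sample ids to pool (default: all samples present).
#' @return Tibble with `chrom`, `start`, `end`, `n_cpgs`, `meth`, `unmeth`,
#'   `meth_pct`.
#' @export
pool_tiles <- function(tiles, samples = unique(tiles$sample_id)) {
  sel <- filter(tiles, .data$sample_id %in% samples)
  n_s <- length(unique(sel$sample_id))
  sel |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(n_present = n(), n_cpgs = max(.data$n_cpgs),
              meth = sum(.data$meth), unmeth = sum(.data$unmeth),
              .groups = "drop") |>
    filter(.data$n_present == n_s) |>
    mutate(meth_pct = 100 * .data$meth / (.data$meth + .data$unmeth)) |>
    select("chrom", "start", "end", "n_cpgs", "meth", "unmeth", "meth_pct") |>
    arrange(.data$chrom, .data$start)
}

#' Call differentially methylated tiles between two groups
#'
#' Per tile, a two-sided Fisher's exact test on the pooled 2x2 read-count
#' table `[meth_A, unmeth_A; meth_B, unmeth_B]`, Benjamini-Hochberg adjusted
#' across all tested tiles. A tile is a DMR when the methylation difference
#' exceeds `diff_threshold` percentage points *and* `q < q_threshold`:
#' `hyper` when group B is more methylated than group A, `hypo` when less.
#'
#' @param tiles_a,tiles_b Pooled tile tibbles (see [pool_tiles()]) on an
#'   identical tile universe.
#' @param diff_threshold Minimum |methylation difference| in percentage
#'   points (default 20).
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @return Tibble with `chrom`, `start`, `end`, `n_cpgs`, `meth_pct_a`,
#'   `meth_pct_b`, `meth_diff` (B - A, percentage points), `p`, `q`,
#'   `status` in `{hyper, hypo, not_significant}`.
#' @export
call_dmrs <- function(tiles_a, tiles_b, diff_threshold = 20,
                      q_threshold = 0.05) {
  for (t in list(tiles_a, tiles_b)) {
    assert_cols(t, c("chrom", "start", "end", "meth", "unmeth", "meth_pct"),
                "tiles")
  }
  key_a <- paste(tiles_a$chrom, tiles_a$start, tiles_a$end)
  key_b <- paste(tiles_b$chrom, tiles_b$start, tiles_b$end)
  if (length(key_a) != length(key_b) || any(key_a != key_b)) {
    bad <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    if (length(bad) == 0) bad <- "(ordering differs)"
    abort(sprintf("tile universes differ between groups; first mismatch: %s",
                  bad[1]))
  }
  p <- fisher_test_2x2(tiles_a$meth, tiles_a$unmeth,
                       tiles_b$meth, tiles_b$unmeth, "two.sided")
  q <- p.adjust(p, method = "BH")
  diff <- tiles_b$meth_pct - tiles_a$meth_pct
  status <- dplyr::case_when(
    abs(diff) > diff_threshold & q < q_threshold & diff > 0 ~ "hyper",
    abs(diff) > diff_threshold & q < q_threshold & diff < 0 ~ "hypo",
    TRUE ~ "not_significant"
  )
  tibble(chrom = tiles_a$chrom, start = tiles_a$start, end = tiles_a$end,
         n_cpgs = tiles_a$n_cpgs,
         meth_pct_a = tiles_a$meth_pct, meth_pct_b = tiles_b$meth_pct,
         meth_diff = diff, p = p, q = q, status = status)
}

#' Classify temporal methylation changes into gain / loss / stable
#'
#' Interprets DMR calls between two timepoints of one condition (earlier
#' timepoint as group A, later as group B): `hyper` tiles gained methylation
#' over time, `hypo` tiles lost it, the rest are stable. Percentages are
#' relative to all tested tiles.
#'
#' @param dmrs DMR call tibble from [call_dmrs()].
#' @param label Optional label attached to the summary (e.g. `"Ctrl d0->d4"`).
#' @return List: `tiles` (the input plus a `temporal_class` column) and
#'   `summary` (tibble `label`, `class`, `n`, `pct`).
#' @export
classify_temporal <- function(dmrs, label = NA_character_) {
  assert_cols(dmrs, c("chrom", "start", "end", "status"), "dmrs")
  tiles <- dmrs |>
    mutate(temporal_class = dplyr::case_when(
      .data$status == "hyper" ~ "gain",
      .data$status == "hypo" ~ "loss",
      TRUE ~ "stable"
    ))
  summary <- tibble(class = c("gain", "loss", "stable")) |>
    mutate(label = label,
           n = vapply(.data$class,
                      function(cl) sum(tiles$temporal_class == cl),
                      numeric(1)),
           pct = 100 * .data$n / nrow(tiles)) |>
    select("label", "class", "n", "pct")
  list(tiles = tiles, summary = summary)
}

#' Recovery statistics of DMR calls against planted truth
#'
#' Sensitivity is the fraction of planted tiles, *among those present in the
#' tested tile universe*, called with the expected status (tiles removed by
#' the depth/common-site filters cannot be called and are reported in
#' `n_untested`). The empirical false-discovery rate is the fraction of
#' called tiles that were not planted.
#'
#' @param dmrs DMR call tibble from [call_dmrs()].
#' @param truth Planted-truth tibble with `chrom`, `start` (tile
#'   coordinates), e.g. the `planted_dmrs` component of [sim_methylome()]
#'   filtered to one direction.
#' @param status Expected call status of the planted tiles (`"hypo"` or
#'   `"hyper"`).
#' @return One-row tibble: `n_planted`, `n_untested`, `n_called`,
#'   `n_recovered`, `sensitivity`, `fdr`.
#' @export
dmr_recovery <- function(dmrs, truth, status = c("hypo", "hyper")) {
  status <- match.arg(status)
  tested_key <- paste(dmrs$chrom, dmrs$start)
  truth_key <- paste(truth$chrom, truth$start)
  called_key <- tested_key[dmrs$status == status]
  testable <- truth_key[truth_key %in% tested_key]
  n_rec <- sum(testable %in% called_key)
  tibble(
    n_planted = length(truth_key),
    n_untested = length(truth_key) - length(testable),
    n_called = length(called_key),
    n_recovered = n_rec,
    sensitivity = if (length(testable) == 0) NA_real_ else {
      n_rec / length(testable)
    },
    fdr = if (length(called_key) == 0) 0 else {
      mean(!(called_key %in% truth_key))
    }
  )
}

#' Trajectories of acquired methylation: maintained or lost
#'
#' For every tile that significantly gained methylation between the first two
#' timepoints, reports its pooled methylation at the middle and late
#' timepoint and flags it `lost` when methylation at the late timepoint drops
#' more than `diff_threshold` percentage points below the middle one —
#' distinguishing acquisition-then-maintenance from acquisition-then-loss.
#'
#' @param dmrs_gain DMR calls for the early-to-middle comparison
#'   ([call_dmrs()] with the earlier timepoint as group A).
#' @param tiles_mid,tiles_late Pooled tiles at the middle and late timepoint
#'   of the same condition (same tile universe).
#' @param diff_threshold Drop (percentage points) beyond which acquired
#'   methylation counts as lost (default 20).
#' @return Tibble with one row per gained tile: coordinates, `meth_mid`,
#'   `meth_late`, `drop` and logical `lost`.
#' @export
maintained_acquisition <- function(dmrs_gain, tiles_mid, tiles_late,
                                   diff_threshold = 20) {
  gained <- filter(dmrs_gain, .data$status == "hyper")
  key <- c("chrom", "start", "end")
  out <- gained |>
    select(dplyr::all_of(key)) |>
    inner_join(select(tiles_mid, dplyr::all_of(key), meth_mid = "meth_pct"),
               by = key) |>
    inner_join(select(tiles_late, dplyr::all_of(key), meth_late = "meth_pct"),
               by = key) |>
    mutate(drop = .data$meth_mid - .data$meth_late,
           lost = .data$drop > diff_threshold)
  if (nrow(out) != nrow(gained)) {
    abort("gained tiles missing from the mid/late tile universe")
  }
  out
}
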