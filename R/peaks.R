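# ChIP peak proximity analysis at demethylated regions: closest-region
# assignment, signed distance profiles, and a within-chromosome permutation
# null for the enrichment ratio.

interval_midpoint <- function(df) floor((df$start + df$end) / 2)

#' Assign each peak to its closest region
#'
#' Distances run from the peak anchor to the region midpoint (signed:
#' negative = peak upstream of the region on plus coordinates). The anchor is
#' the narrowPeak summit (`start + summit`) when a `summit` column is
#' present, otherwise the interval midpoint. Ties are broken toward the
#' lower-coordinate region. Peaks on chromosomes without any region get a
#' missing distance.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end` (optional
#'   `summit` offset column).
#' @param regions Non-empty tibble with `chrom`, `start`, `end` and
#'   optionally `region_id`.
#' @return Tibble with `peak_id`, `chrom`, `anchor`, `region_id`,
#'   `distance` (bp, `NA` when no region shares the chromosome).
#' @export
assign_peaks <- function(peaks, regions) {
  assert_intervals(peaks, "peaks")
  assert_intervals(regions, "regions")
  if (nrow(regions) == 0) abort("`regions` must be non-empty")
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  }
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("region%05d", seq_len(nrow(regions)))
  }
  anchor <- if ("summit" %in% names(peaks)) {
    peaks$start + peaks$summit
  } else {
    interval_midpoint(peaks)
  }
  out <- tibble(peak_id = peaks$peak_id, chrom = peaks$chrom,
                anchor = anchor, region_id = NA_character_,
                distance = NA_real_)
  for (ch in unique(peaks$chrom)) {
    reg <- regions[regions$chrom == ch, ]
    pk <- which(peaks$chrom == ch)
    if (nrow(reg) == 0) next
    # sort region midpoints; for equal midpoints keep the lower-coordinate
    # region first so which.min-style ties resolve to it
    reg <- reg[order(interval_midpoint(reg), reg$start), ]
    mids <- interval_midpoint(reg)
    a <- anchor[pk]
    right <- findInterval(a, mids) + 1L          # first midpoint >= anchor...
    left <- pmin(pmax(right - 1L, 1L), length(mids))
    right <- pmin(right, length(mids))
    d_left <- abs(a - mids[left])
    d_right <- abs(a - mids[right])
    # tie (equidistant) -> lower-coordinate region, i.e. the left one
    use_left <- d_left <= d_right
    pick <- ifelse(use_left, left, right)
    # among regions sharing the winning midpoint, take the lowest-coordinate
    pick <- match(mids[pick], mids)
    out$region_id[pk] <- reg$region_id[pick]
    out$distance[pk] <- a - mids[pick]
  }
  n_na <- sum(is.na(out$distance))
  if (n_na > 0) {
    message(sprintf("%d peak(s) on chromosomes without regions left unassigned",
                    n_na))
  }
  out
}

#' Signed-distance profile of peak assignments
#'
#' Histogram of signed peak-to-region distances within `[-window, window)`,
#' in fixed-width bins; peaks outside the window (or unassigned) are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param assignments Output of [assign_peaks()].
#' @param window Half-width in bp (default 10000).
#' @param bin Bin width in bp; must divide `2 * window` (default 500).
#' @return Tibble with `bin_start`, `bin_end` (signed bp) and `n`; attribute
#'   `n_excluded`.
#' @export
distance_profile <- function(assignments, window = 10000, bin = 500) {
  assert_cols(assignments, "distance", "assignments")
  if ((2 * window) %% bin != 0) abort("`bin` must divide 2 * window")
  d <- assignments$distance
  inwin <- !is.na(d) & d >= -window & d < window
  n_bins <- as.integer(2 * window / bin)
  idx <- floor((d[inwin] + window) / bin)
  counts <- tabulate(idx + 1, nbins = n_bins)
  out <- tibble(bin_start = -window + (seq_len(n_bins) - 1) * bin,
                bin_end = -window + seq_len(n_bins) * bin,
                n = counts)
  attr(out, "n_excluded") <- sum(!inwin)
  out
}

#' Permutation null and enrichment ratio for a peak distance profile
#'
#' Each permutation re-places every peak anchor uniformly on its own
#' chromosome (preserving per-chromosome peak counts), re-assigns peaks to
#' the closest region and recomputes the profile. Reports the per-bin
#' permutation mean, a 95% envelope (2.5/97.5 percentiles) and the
#' enrichment ratio observed / mean, with the mean floored at one pseudo
#' count.
#'
#' @param peaks,regions As in [assign_peaks()].
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window,bin Profile parameters, see [distance_profile()].
#' @param n_perm Number of permutations (>= 20; default 200).
#' @param seed Integer seed for the permutations.
#' @return Tibble with `bin_start`, `bin_end`, `observed`, `perm_mean`,
#'   `lower`, `upper`, `ratio`, `outside_envelope`.
#' @export
permutation_background <- function(peaks, regions, chrom_lengths,
                                   window = 10000, bin = 500,
                                   n_perm = 200, seed) {
  if (n_perm < 20) abort("`n_perm` must be >= 20")
  observed <- distance_profile(assign_peaks(peaks, regions), window, bin)
  with_sim_seed(seed, {
    perm_counts <- vapply(seq_len(n_perm), function(i) {
      shuffled <- peaks
      mid <- vapply(shuffled$chrom, function(ch) {
        sample.int(chrom_lengths[[ch]], 1) - 1
      }, numeric(1))
      width <- shuffled$end - shuffled$start
      shuffled$start <- mid
      shuffled$end <- mid + pmax(width, 1)
      if ("summit" %in% names(shuffled)) shuffled$summit <- 0
      distance_profile(assign_peaks(shuffled, regions), window, bin)$n
    }, numeric(nrow(observed)))
    perm_mean <- rowMeans(perm_counts)
    lower <- apply(perm_counts, 1, quantile, probs = 0.025, names = FALSE)
    upper <- apply(perm_counts, 1, quantile, probs = 0.975, names = FALSE)
    obs_n <- observed$n
    tibble(bin_start = observed$bin_start, bin_end = observed$bin_end,
           observed = obs_n, perm_mean = perm_mean,
           lower = lower, upper = upper,
           ratio = obs_n / pmax(perm_mean, 1),
           outside_envelope = obs_n < lower | obs_n > upper)
  })
}
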