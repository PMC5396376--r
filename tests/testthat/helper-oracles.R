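# Independent oracles used across the suite. These deliberately share no code
# with the package implementation: regex + quadratic loops for motif scans,
# explicit dhyper tail sums for exact tests, a literal UPGMA loop, and
# all-pairs scans for interval assignment.

iupac_regex <- function(motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(motif), "")[[1]]
  paste0(vapply(chars, function(ch) {
    letters <- map[[ch]]
    if (nchar(letters) == 1) letters else sprintf("[%s]", letters)
  }, character(1)), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTYR", "TGCARY", toupper(s)), "")[[1]]),
        collapse = "")
}

find_matches <- function(s, motif) {
  m <- gregexpr(sprintf("(?=%s)", iupac_regex(motif)), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# quadratic brute-force bipartite pair enumeration with the same reporting
# convention as scan_bipartite (plus-strand coordinates, "first" = 5'-most on
# the hit's strand)
oracle_scan <- function(seq, motif_a, motif_b, max_gap, both_strands = TRUE) {
  seq <- toupper(seq)
  len_a <- nchar(motif_a); len_b <- nchar(motif_b)
  same <- identical(toupper(motif_a), toupper(motif_b))
  one_strand <- function(s) {
    oa <- find_matches(s, motif_a); ob <- find_matches(s, motif_b)
    rows <- list()
    add_pairs <- function(firsts, len1, seconds, len2) {
      for (i in firsts) for (j in seconds) {
        gap <- j - (i + len1)
        if (gap >= 0 && gap <= max_gap) {
          rows[[length(rows) + 1]] <<- c(i, i + len1, j, j + len2, gap)
        }
      }
    }
    add_pairs(oa, len_a, ob, len_b)
    if (!same) add_pairs(ob, len_b, oa, len_a)
    if (length(rows) == 0) {
      matrix(numeric(0), ncol = 5)
    } else do.call(rbind, rows)
  }
  plus <- one_strand(seq)
  out <- if (nrow(plus) > 0) {
    data.frame(first_start = plus[, 1], first_end = plus[, 2],
               second_start = plus[, 3], second_end = plus[, 4],
               gap = plus[, 5], strand = "+")
  } else NULL
  if (both_strands) {
    L <- nchar(seq)
    minus <- one_strand(revcomp_chr(seq))
    if (nrow(minus) > 0) {
      out <- rbind(out, data.frame(
        first_start = L - minus[, 2], first_end = L - minus[, 1],
        second_start = L - minus[, 4], second_end = L - minus[, 3],
        gap = minus[, 5], strand = "-"))
    }
  }
  if (is.null(out)) {
    out <- data.frame(first_start = numeric(0), first_end = numeric(0),
                      second_start = numeric(0), second_end = numeric(0),
                      gap = numeric(0), strand = character(0))
  }
  out[order(out$first_start, out$second_start, out$strand), , drop = FALSE]
}

hit_keys <- function(df) {
  sort(paste(df$first_start, df$first_end, df$second_start, df$second_end,
             df$gap, df$strand))
}

# explicit upper-tail sum P(X >= a), X ~ Hypergeom
oracle_tail_greater <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  hi <- min(k, m)
  if (a > hi) return(0)
  sum(dhyper(a:hi, m, n, k))
}

oracle_tail_less <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n)
  sum(dhyper(lo:a, m, n, k))
}

# literal UPGMA: repeatedly merge the closest pair with size-weighted
# average distances; returns sorted merge heights
oracle_upgma_heights <- function(D) {
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  diag(Dm) <- Inf
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- Dm[active, active, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, Dm[i, j])
    for (k in setdiff(active, c(i, j))) {
      v <- (sizes[i] * Dm[i, k] + sizes[j] * Dm[j, k]) / (sizes[i] + sizes[j])
      Dm[i, k] <- v; Dm[k, i] <- v
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# all-pairs overlap labelling with precedence (vectorized over regions only)
oracle_annotate <- function(tiles, regions, precedence) {
  prec <- match(regions$label, precedence)
  out <- character(nrow(tiles))
  for (t in seq_len(nrow(tiles))) {
    hit <- regions$chrom == tiles$chrom[t] &
      regions$start < tiles$end[t] & tiles$start[t] < regions$end
    out[t] <- if (any(hit)) precedence[min(prec[hit])] else "other"
  }
  out
}

# all-pairs nearest region by midpoint, tie to the lowest-coordinate region
oracle_assign <- function(peaks, regions) {
  p_mid <- floor((peaks$start + peaks$end) / 2)
  r_mid <- floor((regions$start + regions$end) / 2)
  region_id <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    same <- which(regions$chrom == peaks$chrom[i])
    if (length(same) == 0) next
    dd <- abs(p_mid[i] - r_mid[same])
    best <- same[dd == min(dd)]
    pick <- best[which.min(regions$start[best])]
    region_id[i] <- regions$region_id[pick]
    distance[i] <- p_mid[i] - r_mid[pick]
  }
  data.frame(region_id = region_id, distance = distance)
}

# random DNA of given length and GC
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# full synthetic-methylome pipeline: filter, intersect, tile, and a pooled
# tile getter per condition/timepoint
run_methylome_pipeline <- function(sim) {
  cp <- intersect_common_cpgs(filter_cpgs(sim$cpgs))
  tl <- tile_methylation(cp)
  pool <- function(cond, tp) {
    ids <- sim$design$sample_id[sim$design$condition == cond &
                                  sim$design$timepoint == tp]
    pool_tiles(tl, ids)
  }
  list(tiles = tl, pool = pool)
}
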