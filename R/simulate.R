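# Synthetic-data generators with exported ground truth.
#
# Every generator is a pure function of its parameters and `seed`: calling it
# twice with the same arguments yields identical output, and the caller's RNG
# state is left untouched.

#' Build a sample design table
#'
#' @param conditions Character vector of condition labels.
#' @param timepoints Numeric vector of timepoints (days).
#' @param n_rep Replicates per condition/timepoint cell.
#' @return Tibble with `sample_id`, `condition`, `timepoint`, `replicate`.
#' @examples
#' sim_design()
#' @export
sim_design <- function(conditions = c("Ctrl", "KO"),
                       timepoints = c(0, 4, 6), n_rep = 2) {
  if (n_rep < 1) abort("`n_rep` must be >= 1")
  des <- tidyr::expand_grid(condition = conditions, timepoint = timepoints,
                            replicate = seq_len(n_rep))
  des |>
    mutate(sample_id = sprintf("%s_d%g_r%d", .data$condition,
                               .data$timepoint, .data$replicate)) |>
    select("sample_id", "condition", "timepoint", "replicate")
}

#' Simulate a genome of i.i.d. bases
#'
#' Bases are drawn independently with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param chrom_lengths Named numeric vector: chromosome name -> length (bp).
#' @param gc_fraction Target GC content in (0, 1); 0 and 1 are allowed as
#'   degenerate compositions.
#' @param seed Integer seed; fixed seed gives a byte-identical genome.
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' g <- sim_genome(c(chr1 = 10000), gc_fraction = 0.5, seed = 1)
#' @export
sim_genome <- function(chrom_lengths, gc_fraction = 0.5, seed) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector")
  }
  bad <- names(chrom_lengths)[chrom_lengths <= 0]
  if (length(bad) > 0) {
    abort(sprintf("non-positive length for chromosome(s): %s",
                  paste(bad, collapse = ", ")))
  }
  assert_scalar_number(gc_fraction, "gc_fraction", 0, 1)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_sim_seed(seed, {
    seqs <- vapply(chrom_lengths, function(len) {
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate a gene annotation and genomic region classes
#'
#' Places non-overlapping genes uniformly on the declared chromosomes, draws
#' biotypes from `biotype_mix`, nests exons inside gene bodies, and builds
#' small region sets for the classes used downstream (enhancers, CpG islands,
#' methylation canyons, transposable elements).
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param biotype_mix Named probabilities over biotypes.
#' @param gene_length Two-element range of gene body lengths (bp).
#' @param seed Integer seed.
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end`, `n_exons`, `biotype`), `exons` (tibble of exon
#'   intervals), `regions` (tibble: `region_id`, `label`, `chrom`, `start`,
#'   `end`) and `chrom_lengths`.
#' @export
sim_annotation <- function(n_genes, chrom_lengths,
                           biotype_mix = c(protein_coding = 0.8,
                                           lincRNA = 0.1, miRNA = 0.1),
                           gene_length = c(2000, 8000), seed) {
  if (n_genes < 1) abort("`n_genes` must be >= 1")
  if (abs(sum(biotype_mix) - 1) > 1e-8) {
    abort("`biotype_mix` probabilities must sum to 1")
  }
  with_sim_seed(seed, {
    # apportion genes to chromosomes by length, then tile each chromosome
    # into equal slots so genes never overlap
    weights <- chrom_lengths / sum(chrom_lengths)
    n_per <- as.vector(stats::rmultinom(1, n_genes, weights))
    genes <- purrr::map2_dfr(names(chrom_lengths), seq_along(chrom_lengths),
      function(chrom, i) {
        n <- n_per[i]
        if (n == 0) return(tibble())
        len <- chrom_lengths[[i]]
        slot <- floor(len / n)
        max_len <- min(gene_length[2], slot)
        if (max_len < max(200, gene_length[1] / 4)) {
          abort(sprintf(
            "chromosome %s (%d bp) cannot fit %d genes of ~%d bp",
            chrom, as.integer(len), n, as.integer(gene_length[1])))
        }
        glen <- round(runif(n, min(gene_length[1], max_len), max_len))
        offset <- vapply(slot - glen, function(m) {
          if (m <= 0) 0 else sample.int(m, 1) - 1
        }, numeric(1))
        start <- (seq_len(n) - 1) * slot + offset
        tibble(chrom = chrom, start = start, end = start + glen)
      })
    n <- nrow(genes)
    genes <- genes |>
      mutate(
        gene_id = sprintf("gene%04d", seq_len(n)),
        strand = sample(c("+", "-"), n, replace = TRUE),
        tss = if_else(.data$strand == "+", .data$start, .data$end - 1),
        biotype = sample(names(biotype_mix), n, replace = TRUE,
                         prob = biotype_mix)
      )
    exons <- purrr::pmap_dfr(
      genes[, c("gene_id", "chrom", "start", "end")],
      function(gene_id, chrom, start, end) {
        n_ex <- sample(1:4, 1)
        # 2*n_ex - 2 internal cuts -> alternating exon/intron segments that
        # start and end with an exon
        cuts <- if (n_ex == 1) numeric(0) else {
          sort(sample(seq(start + 1, end - 1), 2 * n_ex - 2))
        }
        bounds <- c(start, cuts, end)
        keep <- seq(1, length(bounds) - 1, by = 2)
        tibble(gene_id = gene_id, chrom = chrom,
               start = bounds[keep], end = bounds[keep + 1],
               exon_number = seq_along(keep))
      })
    ex_n <- dplyr::count(exons, .data$gene_id)
    genes$n_exons <- ex_n$n[match(genes$gene_id, ex_n$gene_id)]
    regions <- sim_region_classes(genes, chrom_lengths)
    list(genes = select(genes, "gene_id", "chrom", "strand", "tss",
                        "start", "end", "n_exons", "biotype"),
         exons = exons, regions = regions, chrom_lengths = chrom_lengths)
  })
}

# region classes anchored on the gene set: CGIs at a subset of promoters,
# enhancers intergenic, canyons large and sparse, TEs short and scattered
sim_region_classes <- function(genes, chrom_lengths) {
  n <- nrow(genes)
  cgi_genes <- genes[seq_len(max(1, floor(n * 0.3))), ]
  cgi <- tibble(label = "CGI", chrom = cgi_genes$chrom,
                start = pmax(0, cgi_genes$tss - 300),
                end = cgi_genes$tss + 300)
  rand_regions <- function(label, count, width) {
    chroms <- sample(names(chrom_lengths), count, replace = TRUE,
                     prob = chrom_lengths / sum(chrom_lengths))
    start <- vapply(chroms, function(ch) {
      sample.int(max(1, chrom_lengths[[ch]] - width), 1) - 1
    }, numeric(1))
    tibble(label = label, chrom = chroms, start = start, end = start + width)
  }
  regions <- bind_rows(
    cgi,
    rand_regions("enhancer", max(2, floor(n / 2)), 500),
    rand_regions("canyon", max(2, floor(n / 10)), 5000),
    rand_regions("TE", max(2, n), 300)
  )
  regions <- regions |>
    mutate(end = pmin(.data$end,
                      unname(chrom_lengths[.data$chrom])),
           region_id = sprintf("%s_%04d", .data$label, row_number()))
  select(regions, "region_id", "label", "chrom", "start", "end")
}

#' Simulate a temporal RRBS methylome with planted DMRs
#'
#' Generates per-sample CpG coverage records over a tiled synthetic
#' chromosome, following the study design of two conditions (control and
#' knockout) across three timepoints. Per-tile baseline methylation is drawn
#' from a bimodal Beta mixture (hypomethylated mode `Beta(1, 9)`,
#' hypermethylated mode `Beta(9, 1)`). A fraction of tiles undergoes a
#' developmental gain of methylation between the first and second timepoint
#' in *both* conditions; methylation is then stable to the last timepoint in
#' the control, while the knockout loses methylation at `n_loss` planted
#' tiles (drawn from the gained set, so acquisition-then-loss trajectories
#' are testable) and gains at `n_gain` planted tiles. Coverage per CpG is
#' truncated negative binomial (minimum one read) and methylated counts are
#' binomial in the tile's probability.
#'
#' @param design Design tibble from [sim_design()]; needs exactly two
#'   conditions and at least two timepoints. The first condition is treated
#'   as control, the last timepoint as the perturbation timepoint.
#' @param n_tiles Number of 400 bp tiles on the synthetic chromosome.
#' @param tile_size Tile width in bp.
#' @param cpgs_per_tile Two-element integer range of CpG count per tile.
#' @param depth_mean Mean sequencing depth per CpG.
#' @param nb_size Negative-binomial size (over-dispersion) of coverage.
#' @param baseline_hypo_frac Mixture weight of the hypomethylated mode.
#' @param dev_gain_frac Fraction of eligible tiles gaining methylation
#'   between the first two timepoints.
#' @param dev_gain Developmental gain in percentage points.
#' @param n_loss,loss_delta Number of planted knockout loss tiles and their
#'   shift in percentage points (negative).
#' @param n_gain,gain_delta Number of planted knockout gain tiles and shift.
#' @param region_labels Optional character vector (length `n_tiles`) of
#'   region-class labels; tiles labelled `"canyon"` or `"CGI"` get strongly
#'   hypomethylated baselines and resist the developmental gain.
#' @param diff_threshold DMR caller threshold used only to check that planted
#'   deltas are well-posed (|delta| >= threshold + 5).
#' @param seed Integer seed.
#' @return A list: `cpgs` (long tibble of CpG records across samples),
#'   `tiles` (tile coordinates with `tile_id`, baseline and per-cell
#'   probabilities), `truth` (list of `planted_dmrs`, `dev_gain_tiles`),
#'   `design`, `chrom_lengths`.
#' @export
sim_methylome <- function(design = sim_design(), n_tiles = 2000,
                          tile_size = 400, cpgs_per_tile = c(3, 8),
                          depth_mean = 20, nb_size = 4,
                          baseline_hypo_frac = 0.6,
                          dev_gain_frac = 0.35, dev_gain = 30,
                          n_loss = 100, loss_delta = -30,
                          n_gain = 0, gain_delta = 30,
                          region_labels = NULL, diff_threshold = 20, seed) {
  assert_scalar_number(depth_mean, "depth_mean", 1)
  conditions <- unique(design$condition)
  timepoints <- sort(unique(design$timepoint))
  if (length(conditions) != 2 || length(timepoints) < 2) {
    abort("`design` must have exactly 2 conditions and >= 2 timepoints")
  }
  for (delta in c(loss_delta, gain_delta)) {
    if (abs(delta) < diff_threshold + 5) {
      warn(sprintf(
        "planted delta %g is within 5 points of the caller threshold %g; recovery tests may be ill-posed",
        delta, diff_threshold))
    }
  }
  t0 <- timepoints[1]; t_mid <- timepoints[2]; t_last <- timepoints[length(timepoints)]
  ctrl <- conditions[1]; ko <- conditions[2]
  chrom <- "chrS"
  chrom_lengths <- c(chrS = n_tiles * tile_size)

  with_sim_seed(seed, {
    resist <- if (!is.null(region_labels)) {
      region_labels %in% c("canyon", "CGI")
    } else rep(FALSE, n_tiles)
    p0 <- ifelse(runif(n_tiles) < baseline_hypo_frac,
                 rbeta(n_tiles, 1, 9), rbeta(n_tiles, 9, 1))
    p0[resist] <- rbeta(sum(resist), 1, 19)
    # the developmental gain is planted only where it can fully manifest
    # (well-posed truth: realized delta stays >= the caller threshold + 5)
    eligible <- !resist & p0 <= 1 - (dev_gain + 5) / 100
    n_dev <- round(dev_gain_frac * n_tiles)
    if (n_dev > sum(eligible)) {
      abort("not enough hypomethylated tiles to plant the developmental gain")
    }
    dev <- rep(FALSE, n_tiles)
    dev[sample(which(eligible), n_dev)] <- TRUE
    clip <- function(p) pmin(pmax(p, 0.01), 0.99)
    p_mid <- clip(p0 + dev * dev_gain / 100)

    gained <- which(dev)
    if (n_loss > length(gained)) {
      abort(sprintf("n_loss = %d exceeds the %d tiles available in the gained set",
                    n_loss, length(gained)))
    }
    loss_tiles <- sort(sample(gained, n_loss))
    gain_pool <- setdiff(which(p_mid < 0.5), loss_tiles)
    if (n_gain > length(gain_pool)) abort("n_gain exceeds available low-methylation tiles")
    gain_tiles <- sort(sample(gain_pool, n_gain))

    p_last_ctrl <- p_mid
    p_last_ko <- p_mid
    p_last_ko[loss_tiles] <- clip(p_mid[loss_tiles] + loss_delta / 100)
    p_last_ko[gain_tiles] <- clip(p_mid[gain_tiles] + gain_delta / 100)

    p_cell <- function(cond, tp) {
      if (tp == t0) return(p0)
      if (tp < t_last) return(p_mid)
      if (cond == ctrl) p_last_ctrl else p_last_ko
    }

    n_cpg <- sample(cpgs_per_tile[1]:cpgs_per_tile[2], n_tiles, replace = TRUE)
    tile_start <- (seq_len(n_tiles) - 1) * tile_size
    pos <- unlist(purrr::map2(tile_start, n_cpg, function(s, k) {
      sort(sample(s:(s + tile_size - 2), k))
    }))
    tile_of <- rep(seq_len(n_tiles), n_cpg)
    n_sites <- length(pos)

    cpgs <- purrr::pmap_dfr(design, function(sample_id, condition, timepoint,
                                             replicate) {
      p <- p_cell(condition, timepoint)[tile_of]
      coverage <- pmax(rnbinom(n_sites, size = nb_size, mu = depth_mean), 1L)
      meth <- rbinom(n_sites, coverage, p)
      tibble(chrom = chrom, pos = pos,
             count_methylated = as.integer(meth),
             count_unmethylated = as.integer(coverage - meth),
             sample_id = sample_id)
    })

    tiles <- tibble(
      tile_id = seq_len(n_tiles), chrom = chrom,
      start = tile_start, end = tile_start + tile_size,
      n_cpgs = n_cpg, p_baseline = p0, p_mid = p_mid,
      label = region_labels %||% NA_character_
    )
    planted <- bind_rows(
      tibble(tile_id = loss_tiles, direction = "loss",
             delta = loss_delta, condition = ko, timepoint = t_last),
      tibble(tile_id = gain_tiles, direction = "gain",
             delta = gain_delta, condition = ko, timepoint = t_last)
    )
    planted <- planted |>
      mutate(chrom = chrom,
             start = tiles$start[.data$tile_id],
             end = tiles$end[.data$tile_id],
             recoverable = tiles$n_cpgs[.data$tile_id] >= 3)
    if (nrow(planted) > 0 && any(!planted$recoverable)) {
      warn(sprintf("%d planted DMR(s) fall in tiles with < 3 CpGs and are flagged unrecoverable",
                   sum(!planted$recoverable)))
    }
    list(
      cpgs = cpgs, tiles = tiles,
      truth = list(
        planted_dmrs = planted,
        dev_gain_tiles = tibble(tile_id = gained, chrom = chrom,
                                start = tiles$start[gained],
                                end = tiles$end[gained])
      ),
      design = design, chrom_lengths = chrom_lengths
    )
  })
}

#' Simulate a count matrix with planted differential genes
#'
#' Two-group negative-binomial counts with planted log2 fold-changes, plus a
#' built-in per-gene differential table (log2FC, p, q) from an exact
#' negative-binomial two-group comparison at the known dispersion — the
#' consumed-DE-table stand-in for closed-loop testing.
#'
#' @param n_genes Number of genes.
#' @param n_rep Replicates per group (>= 2).
#' @param baseline_range Range of baseline means (log-uniform draw).
#' @param dispersion NB dispersion (> 0).
#' @param n_deg Number of planted differential genes.
#' @param deg_lfc Magnitude of planted log2 fold-changes (sign alternates).
#' @param planted Optional tibble (`gene_id`, `true_log2fc`) overriding
#'   `n_deg`/`deg_lfc`; `gene_id` must be of the form `gene0001`..
#' @param seed Integer seed.
#' @return List: `counts` (tibble, `gene_id` + one column per sample),
#'   `gene_lengths` (tibble `gene_id`, `length`), `de_table` (tibble
#'   `gene_id`, `log2fc`, `p`, `q`), `truth` (tibble `gene_id`,
#'   `true_log2fc`), `groups` (named character vector sample -> group).
#' @export
sim_counts <- function(n_genes = 2000, n_rep = 3,
                       baseline_range = c(50, 2000), dispersion = 0.05,
                       n_deg = 100, deg_lfc = 2, planted = NULL, seed) {
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (n_rep < 2) abort("at least 2 replicates per group are required")
  with_sim_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    true_lfc <- setNames(numeric(n_genes), gene_id)
    if (is.null(planted)) {
      if (n_deg > 0) {
        idx <- sample.int(n_genes, n_deg)
        true_lfc[idx] <- deg_lfc * rep_len(c(1, -1), n_deg)
      }
    } else {
      true_lfc[planted$gene_id] <- planted$true_log2fc
    }
    baseline <- exp(runif(n_genes, log(baseline_range[1]),
                          log(baseline_range[2])))
    samples <- c(sprintf("A_r%d", seq_len(n_rep)),
                 sprintf("B_r%d", seq_len(n_rep)))
    groups <- setNames(rep(c("A", "B"), each = n_rep), samples)
    mu <- cbind(matrix(baseline, n_genes, n_rep),
                matrix(baseline * 2^true_lfc, n_genes, n_rep))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_genes, 2 * n_rep, dimnames = list(gene_id, samples))
    de_table <- nb_two_group_test(counts, groups, dispersion)
    list(
      counts = bind_cols(tibble(gene_id = gene_id), as_tibble(counts)),
      gene_lengths = tibble(gene_id = gene_id,
                            length = round(runif(n_genes, 500, 5000))),
      de_table = de_table,
      truth = tibble(gene_id = gene_id, true_log2fc = unname(true_lfc)),
      groups = groups
    )
  })
}

# exact NB two-group comparison at known dispersion (the generator's built-in
# stand-in for an externally produced DE table)
nb_two_group_test <- function(counts, groups, dispersion) {
  y <- edgeR::DGEList(counts = counts, group = factor(groups[colnames(counts)]))
  y <- edgeR::calcNormFactors(y)
  et <- edgeR::exactTest(y, dispersion = dispersion)
  tibble(gene_id = rownames(et$table),
         log2fc = et$table$logFC,
         p = et$table$PValue,
         q = p.adjust(et$table$PValue, method = "BH"))
}

#' Simulate a high-throughput qPCR Ct table
#'
#' Per-assay mean Ct values with per-sample shifts and well-level noise.
#' Planted outlier samples receive a global Ct shift and strongly elevated
#' dropout. Dropped-out wells have missing Ct and `detected = FALSE`.
#' Optionally, a planted per-assay log2 fold-change between the first and
#' second replicate group is encoded as a Ct difference (lower Ct = higher
#' expression).
#'
#' @param n_assays,n_samples Panel dimensions.
#' @param group_size Consecutive samples per replicate group; must divide
#'   `n_samples`.
#' @param dropout_rate Baseline probability that a well is undetected, in
#'   `[0, 1)`.
#' @param n_outlier_samples Number of planted outlier samples.
#' @param outlier_shift Global Ct shift (cycles, >= 5) of outlier samples.
#' @param outlier_dropout Dropout probability in outlier samples.
#' @param planted_lfc Optional named numeric vector (assay id -> log2 FC
#'   between replicate group 2 and group 1).
#' @param seed Integer seed.
#' @return List: `ct` (long tibble `assay_id`, `sample_id`, `ct`, `detected`,
#'   `quality`), `replicate_groups` (named character vector sample -> group),
#'   `truth` (list with `outlier_samples`, `planted_lfc`).
#' @export
sim_ct_table <- function(n_assays = 48, n_samples = 20, group_size = 4,
                         dropout_rate = 0.05, n_outlier_samples = 2,
                         outlier_shift = 6, outlier_dropout = 0.5,
                         planted_lfc = NULL, seed) {
  assert_scalar_number(dropout_rate, "dropout_rate", 0, 1, strict_upper = TRUE)
  if (n_samples %% group_size != 0) {
    abort("`group_size` must partition the samples evenly")
  }
  if (outlier_shift < 5 && n_outlier_samples > 0) {
    warn("outlier_shift < 5 cycles makes planted outliers subtle")
  }
  with_sim_seed(seed, {
    assays <- sprintf("assay%03d", seq_len(n_assays))
    samples <- sprintf("s%02d", seq_len(n_samples))
    groups <- setNames(sprintf("g%d", ceiling(seq_len(n_samples) / group_size)),
                       samples)
    outliers <- if (n_outlier_samples > 0) {
      sort(sample(samples, n_outlier_samples))
    } else character(0)
    assay_mu <- runif(n_assays, 18, 30)
    sample_shift <- rnorm(n_samples, 0, 0.3)
    lfc <- setNames(numeric(n_assays), assays)
    if (!is.null(planted_lfc)) lfc[names(planted_lfc)] <- planted_lfc
    grid <- tidyr::expand_grid(assay_id = assays, sample_id = samples)
    is_out <- grid$sample_id %in% outliers
    in_g2 <- groups[grid$sample_id] == "g2"
    ct <- assay_mu[match(grid$assay_id, assays)] +
      sample_shift[match(grid$sample_id, samples)] +
      rnorm(nrow(grid), 0, 0.2) +
      ifelse(is_out, outlier_shift, 0) -
      ifelse(in_g2, lfc[grid$assay_id], 0)
    p_drop <- ifelse(is_out, outlier_dropout, dropout_rate)
    dropped <- runif(nrow(grid)) < p_drop
    quality <- ifelse(dropped, runif(nrow(grid), 0, 0.3),
                      runif(nrow(grid), 0.8, 1))
    out <- grid |>
      mutate(ct = ifelse(dropped, NA_real_, ct),
             detected = !dropped, quality = quality)
    list(ct = out, replicate_groups = groups,
         truth = list(outlier_samples = outliers, planted_lfc = lfc))
  })
}

#' Simulate ChIP peak intervals around target regions
#'
#' Target peaks are centred on the midpoints of a sampled subset of the
#' regions of interest, with Normal positional jitter; background peaks are
#' uniform on the chromosomes. Peaks pushed off-chromosome by jitter are
#' clipped back in.
#'
#' @param regions Tibble of regions (`chrom`, `start`, `end`, optionally
#'   `region_id`).
#' @param n_target Number of region-centred peaks (<= number of regions;
#'   sampled without replacement when fewer, recycled over regions when
#'   equal).
#' @param n_background Number of uniform background peaks.
#' @param jitter_sd SD of the Normal offset applied to target peak centres
#'   (bp).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param peak_width Width of every simulated peak (bp).
#' @param seed Integer seed.
#' @return List: `peaks` (tibble `peak_id`, `chrom`, `start`, `end`),
#'   `truth` (tibble `peak_id`, `region_id` with `NA` for background peaks).
#' @export
sim_peaks <- function(regions, n_target, n_background = 0, jitter_sd = 200,
                      chrom_lengths, peak_width = 200, seed) {
  assert_intervals(regions, "regions")
  if (n_target > nrow(regions)) {
    abort("`n_target` must not exceed the number of regions of interest")
  }
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("region%05d", seq_len(nrow(regions)))
  }
  with_sim_seed(seed, {
    tgt <- regions[sort(sample.int(nrow(regions), n_target)), ]
    mid <- floor((tgt$start + tgt$end) / 2)
    jit <- round(rnorm(n_target, 0, jitter_sd))
    centre <- mid + jit
    lim <- unname(chrom_lengths[tgt$chrom])
    clipped <- centre < peak_width / 2 | centre > lim - peak_width / 2
    centre <- pmin(pmax(centre, ceiling(peak_width / 2)),
                   lim - ceiling(peak_width / 2))
    target_peaks <- tibble(chrom = tgt$chrom,
                           start = centre - floor(peak_width / 2),
                           end = centre - floor(peak_width / 2) + peak_width,
                           region_id = tgt$region_id)
    bg_peaks <- if (n_background > 0) {
      chroms <- sample(names(chrom_lengths), n_background, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
      start <- vapply(chroms, function(ch) {
        sample.int(max(1, chrom_lengths[[ch]] - peak_width), 1) - 1
      }, numeric(1))
      tibble(chrom = chroms, start = start, end = start + peak_width,
             region_id = NA_character_)
    } else tibble()
    peaks <- bind_rows(target_peaks, bg_peaks) |>
      mutate(peak_id = sprintf("peak%05d", row_number()))
    if (any(clipped)) {
      message(sprintf("%d target peak(s) clipped to chromosome bounds",
                      sum(clipped)))
    }
    list(peaks = select(peaks, "peak_id", "chrom", "start", "end"),
         truth = select(peaks, "peak_id", "region_id"))
  })
}
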