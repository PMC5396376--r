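test_that("CpG observed/expected ratio matches hand-computed values", {
  expect_equal(cpg_obs_exp("CGCGCG"), (3 * 6) / (3 * 3))  # 2.0
  expect_equal(cpg_obs_exp("ACGT"), (1 * 4) / (1 * 1))
  expect_equal(cpg_obs_exp("AAAA"), 0)        # no C, no G
  expect_equal(cpg_obs_exp("CCCC"), 0)        # no G
  expect_equal(cpg_obs_exp("cgcgcg"), 2)      # case insensitive
  # N excluded from counts and effective length; CG cannot span an N
  expect_equal(cpg_obs_exp("CGNCG"), (2 * 4) / (2 * 2))
  expect_equal(cpg_obs_exp(c("CGCGCG", "ACGT")), c(2, 4))
  expect_error(cpg_obs_exp("CGX"), "only")
})

test_that("HCP/LCP split partitions promoters with a strict boundary", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 300)))
  promoters <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                              start = c(0, 100), end = c(40, 140))
  out <- split_promoters_hcp_lcp(promoters, genome)
  expect_equal(out$promoter_class, c("HCP", "HCP"))  # ACGT repeat ratio ~ 4
  expect_true(all(out$promoter_class %in% c("HCP", "LCP")))

  # exactly at the boundary is LCP (strictly-above rule)
  at <- split_promoters_hcp_lcp(promoters, genome, threshold = out$cpg_ratio[1])
  expect_equal(at$promoter_class[1], "LCP")
})

test_that("interval extension pads, clips and merges", {
  iv <- tibble::tibble(chrom = "chr1", start = c(100, 500, 5000),
                       end = c(200, 600, 5100))
  out <- extend_intervals(iv, pad = 200, chrom_lengths = c(chr1 = 5200))
  # first two intervals merge after padding ([0,400) and [300,800))
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(0, 4800))
  expect_equal(out$end, c(800, 5200))   # clipped at chromosome end
})

test_that("tile annotation matches the all-pairs precedence oracle", {
  set.seed(51)
  tiles <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                          start = sample(0:99000, 500)) |>
    dplyr::mutate(end = start + 400)
  labels <- region_precedence()
  regions <- tibble::tibble(
    label = sample(labels, 300, TRUE),
    chrom = sample(c("chr1", "chr2"), 300, TRUE),
    start = sample(0:99000, 300)
  ) |>
    dplyr::mutate(end = start + sample(100:2000, 300, TRUE))
  got <- annotate_tiles(tiles, regions)
  want <- oracle_annotate(tiles, regions, labels)
  expect_equal(got$label, want)
  expect_error(annotate_tiles(tiles, dplyr::mutate(regions, label = "bogus")),
               "bogus")
})

test_that("one-base overlaps count and precedence picks the earlier class", {
  tile <- tibble::tibble(chrom = "chr1", start = 1000, end = 1400)
  expect_equal(annotate_tiles(
    tile, tibble::tibble(label = "TE", chrom = "chr1",
                         start = 1399, end = 1500))$label, "TE")
  expect_equal(annotate_tiles(
    tile, tibble::tibble(label = "TE", chrom = "chr1",
                         start = 1400, end = 1500))$label, "other")
  both <- tibble::tibble(label = c("intron", "CGI"), chrom = "chr1",
                         start = c(900, 1200), end = c(1600, 1250))
  expect_equal(annotate_tiles(tile, both)$label, "CGI")
})

test_that("per-class methylation deltas include the genome aggregate", {
  t1 <- tibble::tibble(chrom = "chr1", start = c(0, 400, 800),
                       end = c(400, 800, 1200), n_cpgs = 3,
                       meth = c(10, 20, 30), unmeth = c(90, 80, 70),
                       meth_pct = c(10, 20, 30))
  t2 <- dplyr::mutate(t1, meth_pct = c(40, 20, 35))
  res <- region_delta_distribution(t1, t2, c("CGI", "CGI", "TE"))
  expect_equal(sort(unique(res$deltas$label)), c("CGI", "TE", "genome"))
  gsum <- res$summary[res$summary$label == "genome", ]
  expect_equal(gsum$n, 3)
  expect_equal(gsum$median, 5)
  expect_equal(gsum$frac_gt20, 1 / 3)   # only the +30 tile exceeds 20
  cgi <- res$deltas$delta[res$deltas$label == "CGI"]
  expect_equal(sort(cgi), c(0, 30))
  expect_error(region_delta_distribution(t1, t1[1:2, ], c("a", "b", "c")),
               "universe")
  expect_error(region_delta_distribution(t1, t2, "CGI"), "one entry")
})

test_that("metagene profiles bin CpGs correctly on both strands", {
  genes <- tibble::tibble(gene_id = c("plus", "minus"),
                          chrom = c("chr1", "chr2"), strand = c("+", "-"),
                          start = 10000, end = 14000)
  # one fully methylated CpG at the very 5' end of each gene body
  cpgs <- tibble::tibble(
    chrom = c("chr1", "chr2"), pos = c(10000, 13999),
    count_methylated = 10, count_unmethylated = 0, sample_id = "s1")
  prof <- metagene_profile(cpgs, genes, flank = 1000, body_bins = 40,
                           flank_bins = 20)
  expect_equal(nrow(prof), 80)
  first_body <- prof[prof$zone == "body", ][1, ]
  expect_equal(first_body$meth_pct, 100)
  expect_equal(first_body$coverage, 20)   # both genes' 5' CpG lands here
  expect_true(all(is.na(prof$meth_pct[prof$coverage == 0])))

  # an upstream CpG of a minus-strand gene falls in the downstream zone? no:
  # it is 5' of the gene on its own strand, so it maps to the upstream zone
  up_minus <- tibble::tibble(chrom = "chr2", pos = 14500,
                             count_methylated = 5, count_unmethylated = 5,
                             sample_id = "s1")
  p2 <- metagene_profile(up_minus, genes[2, ], flank = 1000)
  expect_equal(p2$zone[which(p2$coverage > 0)], "upstream")

  expect_message(
    metagene_profile(cpgs, dplyr::mutate(genes, end = start + 10)),
    "excluded")
})
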