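test_that("bipartite hits on hand-built sequences are exactly right", {
  # CACCTG at 0, gap 4, CACCTG at 10; plus the same pair on the minus strand
  s <- "CACCTGAAAACACCTG"
  hits <- scan_bipartite(s, "CACCTG", "CACCTG", max_gap = 40)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$first_start, 0)
  expect_equal(plus$second_start, 10)
  expect_equal(plus$gap, 4)
  # CACCTG is not its own reverse complement (CAGGTG), so no minus hits here
  expect_equal(sum(hits$strand == "-"), 0)

  # two CAGGTG sites = two CACCTG sites on the minus strand; the pair is
  # reported in plus coordinates with "first" = 5'-most on the minus strand
  s2 <- "CAGGTGAAAACAGGTG"
  h2 <- scan_bipartite(s2, "CACCTG", "CACCTG", max_gap = 40)
  expect_equal(h2$strand, "-")
  expect_equal(h2$first_start, 10)   # minus-strand 5' site is the rightmost
  expect_equal(h2$first_end, 16)
  expect_equal(h2$second_start, 0)
  expect_equal(h2$gap, 4)
  expect_equal(nrow(scan_bipartite(s2, "CACCTG", "CACCTG", 40,
                                   both_strands = FALSE)), 0)

  # gap boundary: gap must be <= max_gap and >= 0 (no overlap)
  expect_equal(nrow(scan_bipartite("CACCTGCACCTG", "CACCTG", "CACCTG", 0,
                                   both_strands = FALSE)), 1)
  expect_equal(nrow(scan_bipartite("CACCTGACACCTG", "CACCTG", "CACCTG", 0,
                                   both_strands = FALSE)), 0)
  overlapping <- "CACCTGG"  # no room for a second site
  expect_equal(nrow(scan_bipartite(overlapping, "CACCTG", "CACCTG", 40)), 0)
})

test_that("IUPAC degeneracy and asymmetric motifs behave as documented", {
  # YACCTG matches TACCTG and CACCTG
  s <- "TACCTGAAACACCTG"
  h <- scan_bipartite(s, "YACCTG", "YACCTG", max_gap = 10,
                      both_strands = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(h$first_motif, "TACCTG")
  expect_equal(h$second_motif, "CACCTG")

  # differing motifs count both orders once each
  s2 <- "CACCTAAACACCTG"  # CACCT at 0 and 8; CACCTG at 8 only
  h2 <- scan_bipartite(s2, "CACCTG", "CACCT", max_gap = 10,
                       both_strands = FALSE)
  # pairs: CACCT(0) -> CACCTG(8) gap 3
  expect_equal(nrow(h2), 1)
  expect_equal(h2$gap, 3)

  expect_error(scan_bipartite("ACGT", "CAXCTG", "CACCTG"), "IUPAC")
})

test_that("scans agree with the quadratic regex oracle on random sequences", {
  set.seed(61)
  presets <- list(motif_preset("methods"), motif_preset("results-fig2d"))
  for (i in 1:40) {
    s <- random_dna(600, gc = 0.55)
    for (p in presets) {
      got <- scan_bipartite(s, p$motif_a, p$motif_b, p$max_gap)
      want <- oracle_scan(s, p$motif_a, p$motif_b, p$max_gap)
      expect_identical(hit_keys(got), hit_keys(want))
    }
  }
})

test_that("promoter windows are clipped and carry plus-strand sequence", {
  genome <- sim_genome(c(chr1 = 10000), seed = 71)
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          strand = c("+", "-"), tss = c(500, 5000))
  expect_message(pr <- extract_promoters(genes, genome, flank = 2000),
                 "clipped")
  expect_equal(pr$start, c(0, 3000))
  expect_equal(pr$end, c(2500, 7000))
  expect_equal(pr$clipped, c(TRUE, FALSE))
  expect_equal(pr$seq[2],
               as.character(Biostrings::subseq(genome[["chr1"]], 3001, 7000)))
  expect_error(extract_promoters(
    dplyr::mutate(genes, chrom = "chrX"), genome), "gA")
})

test_that("enrichment p-values are one-sided exact tests with finite odds", {
  res <- fisher_enrichment(8, 10, 20, 100, "over")
  expect_equal(res$p, res$p_over)
  expect_equal(res$p_over, oracle_tail_greater(8, 2, 20, 80),
               tolerance = 1e-12)
  expect_equal(res$p_under, oracle_tail_less(8, 2, 20, 80), tolerance = 1e-12)
  expect_lt(res$p_over, 0.001)

  zero <- fisher_enrichment(0, 10, 20, 100)
  expect_true(is.finite(zero$odds_ratio))
  expect_error(fisher_enrichment(11, 10, 1, 10), "exceed")
})

test_that("DEG motif reports test the documented partitions", {
  hit_table <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    n_hits = c(rep(2, 30), rep(0, 70))) |>
    dplyr::mutate(has_hit = n_hits > 0)
  deg <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    deg_status = c(rep("up", 10), rep("down", 10), rep("ns", 80)))
  rep_out <- deg_motif_report(deg, hit_table)
  expect_equal(rep_out$partition, c("up", "down", "all"))
  expect_equal(rep_out$alternative, c("over", "under", "over"))
  up <- rep_out[rep_out$partition == "up", ]
  # up genes g001..g010 all carry hits; background 30/100
  expect_equal(up$k_fg, 10)
  expect_equal(up$p, oracle_tail_greater(10, 0, 30, 70), tolerance = 1e-12)

  no_down <- dplyr::mutate(deg,
                           deg_status = sub("down", "ns", deg_status))
  expect_warning(out2 <- deg_motif_report(no_down, hit_table), "down")
  expect_false("down" %in% out2$partition)
  expect_error(deg_motif_report(
    dplyr::mutate(deg, gene_id = sub("g001", "gX", gene_id)), hit_table),
    "gX")
})

test_that("planted promoter motifs are detected as enriched", {
  with_sim_seed(81, {
    n <- 200
    seqs <- vapply(seq_len(n), function(i) random_dna(1000, 0.45),
                   character(1))
    planted <- 1:30  # make the first 30 genes motif-positive
    for (i in planted) {
      s <- seqs[i]
      ins <- paste0("CACCTG", strrep("A", 10), "CACCTG")
      substr(s, 300, 300 + nchar(ins) - 1) <- ins
      seqs[i] <- s
    }
    promoters <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), seq = seqs)
    ht <- promoter_hit_table(promoters, "CACCTG", "CACCTG", 40)
    expect_true(all(ht$has_hit[planted]))
    deg <- tibble::tibble(gene_id = promoters$gene_id,
                          deg_status = ifelse(seq_len(n) %in% planted,
                                              "up", "ns"))
    expect_warning(res <- deg_motif_report(deg, ht), "down")
    expect_lt(res$p[res$partition == "up"], 1e-6)
  })
})
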