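make_cpgs <- function(chrom, pos, meth, unmeth, sample_id = "s1") {
  tibble::tibble(chrom = chrom, pos = pos, count_methylated = meth,
                 count_unmethylated = unmeth, sample_id = sample_id)
}

test_that("depth filtering removes shallow sites at the stated boundary", {
  cpgs <- make_cpgs("chr1", 0:3, c(2, 3, 4, 5), c(2, 1, 1, 0))
  out <- filter_cpgs(cpgs, min_depth = 5, top_coverage_fraction = 0)
  expect_equal(out$pos, c(2, 3))  # coverage 4 removed, coverage 5 kept
})

test_that("top-coverage filtering removes the extreme site and nothing when flat", {
  set.seed(1)
  cpgs <- make_cpgs("chr1", 0:999, rep(10, 1000), rep(10, 1000))
  cpgs$count_methylated[500] <- 100
  cpgs$count_unmethylated[500] <- 100
  out <- filter_cpgs(cpgs, min_depth = 1, top_coverage_fraction = 0.001)
  expect_false((500 - 1) %in% out$pos)
  expect_equal(nrow(out), 999)

  flat <- make_cpgs("chr1", 0:99, rep(5, 100), rep(5, 100))
  expect_equal(nrow(filter_cpgs(flat, 1, 0.01)), 100)
})

test_that("filtering is order-independent", {
  set.seed(2)
  cpgs <- make_cpgs("chr1", 0:499, rpois(500, 10), rpois(500, 10),
                    sample_id = rep(c("a", "b"), 250))
  shuffled <- cpgs[sample.int(500), ]
  a <- dplyr::arrange(filter_cpgs(cpgs), sample_id, chrom, pos)
  b <- dplyr::arrange(filter_cpgs(shuffled), sample_id, chrom, pos)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("common-site intersection keeps exactly the shared sites", {
  sites <- list(a = 0:9, b = c(0:6, 20, 21, 22), c = c(0:6, 30, 31, 32))
  cpgs <- dplyr::bind_rows(lapply(names(sites), function(s) {
    make_cpgs("chr1", sites[[s]], 3, 3, s)
  }))
  out <- intersect_common_cpgs(cpgs)
  expect_equal(sort(unique(out$pos)), 0:6)
  expect_equal(as.integer(table(out$sample_id)), rep(7L, 3))

  same <- dplyr::filter(cpgs, pos <= 6)
  expect_equal(as.data.frame(intersect_common_cpgs(same)),
               as.data.frame(dplyr::arrange(same, sample_id, chrom, pos)))
  disjoint <- make_cpgs("chr1", c(1, 2), 3, 3, c("a", "b"))
  expect_warning(res <- intersect_common_cpgs(disjoint), "common")
  expect_equal(nrow(res), 0)
})

test_that("methylation histograms use half-open bins with a closed last bin", {
  cpgs <- make_cpgs("chr1", 0:2, c(0, 10, 1), c(10, 0, 19))  # 0%, 100%, 5%
  h <- methylation_histogram(cpgs)
  expect_equal(nrow(h), 20)
  expect_equal(h$n[1], 1)     # 0% in [0,5)
  expect_equal(h$n[2], 1)     # exactly 5% in [5,10)
  expect_equal(h$n[20], 1)    # 100% in the closed last bin
  expect_equal(sum(h$n), 3)
  expect_error(methylation_histogram(cpgs, bin_width = 7), "divide")
})

test_that("tiles pool counts coverage-weighted and respect the CpG minimum", {
  cpgs <- make_cpgs("chr1", c(10, 200, 399), c(5, 10, 0), c(5, 0, 10))
  t1 <- tile_methylation(cpgs)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$meth_pct, 100 * 15 / 30)  # weighted, not mean of 50/100/0

  two <- make_cpgs("chr1", c(10, 20), c(5, 5), c(5, 5))
  expect_equal(nrow(tile_methylation(two)), 0)

  at_400 <- make_cpgs("chr1", c(399, 400, 401, 402), 5, 5)
  t2 <- tile_methylation(at_400)
  expect_equal(t2$start, 400)  # 399 alone in [0,400) is dropped
  expect_equal(t2$n_cpgs, 3)
})

test_that("tile methylation recomputes exactly from member CpGs", {
  sim <- sim_methylome(n_tiles = 50, n_loss = 5, seed = 13)
  tl <- tile_methylation(sim$cpgs)
  cp <- dplyr::mutate(sim$cpgs, start = (pos %/% 400) * 400)
  for (i in sample.int(nrow(tl), 10)) {
    members <- dplyr::filter(cp, sample_id == tl$sample_id[i],
                             chrom == tl$chrom[i], start == tl$start[i])
    expect_equal(tl$meth_pct[i],
                 100 * sum(members$count_methylated) /
                   sum(members$count_methylated + members$count_unmethylated),
                 tolerance = 1e-9)
  }
})

test_that("DMR calls match the exact-test oracle and the thresholds", {
  mk <- function(meth, unmeth) {
    tibble::tibble(chrom = "chr1", start = (seq_along(meth) - 1) * 400,
                   end = seq_along(meth) * 400, n_cpgs = 3,
                   meth = meth, unmeth = unmeth,
                   meth_pct = 100 * meth / (meth + unmeth))
  }
  same <- call_dmrs(mk(c(10, 50), c(90, 50)), mk(c(10, 50), c(90, 50)))
  expect_true(all(same$status == "not_significant"))
  expect_true(all(same$p == 1))

  d <- call_dmrs(mk(10, 90), mk(45, 55))
  expect_equal(d$meth_diff, 35)
  ref <- stats::fisher.test(matrix(c(10, 90, 45, 55), 2, byrow = TRUE))$p.value
  expect_equal(d$p, ref, tolerance = 1e-10)
  expect_lt(d$p, 1e-6)
  expect_equal(d$status, "hyper")  # B more methylated than A

  # large difference but 4 reads per group: not significant
  tiny <- call_dmrs(mk(1, 3), mk(2, 2))
  expect_equal(tiny$status, "not_significant")

  expect_error(call_dmrs(mk(c(1, 2), c(3, 4)), mk(1, 3)), "mismatch|differ")
})

test_that("temporal classes partition the tested tiles", {
  sim <- sim_methylome(n_tiles = 300, n_loss = 20, seed = 21)
  pp <- run_methylome_pipeline(sim)
  res <- classify_temporal(call_dmrs(pp$pool("KO", 4), pp$pool("KO", 6)))
  expect_equal(sum(res$summary$n), nrow(res$tiles))
  expect_equal(sum(res$summary$pct), 100)
  stable_only <- classify_temporal(
    call_dmrs(pp$pool("Ctrl", 4), pp$pool("Ctrl", 6)))
  expect_gt(stable_only$summary$pct[stable_only$summary$class == "stable"], 95)
})

test_that("acquired methylation is flagged lost only when it drops", {
  sim <- sim_methylome(n_tiles = 300, n_loss = 20, seed = 22)
  pp <- run_methylome_pipeline(sim)
  gain_ko <- call_dmrs(pp$pool("KO", 0), pp$pool("KO", 4))
  ma_ko <- maintained_acquisition(gain_ko, pp$pool("KO", 4), pp$pool("KO", 6))
  truth_key <- with(sim$truth$planted_dmrs, paste(chrom, start))
  flagged <- with(ma_ko[ma_ko$lost, ], paste(chrom, start))
  expect_true(all(flagged %in% truth_key))

  # identical mid/late tiles: nothing lost
  ma_same <- maintained_acquisition(gain_ko, pp$pool("KO", 4),
                                    pp$pool("KO", 4))
  expect_false(any(ma_same$lost))
})

test_that("hyper and hypo DMR p-values equal the hypergeometric oracle", {
  set.seed(30)
  mk <- function(meth, unmeth) {
    tibble::tibble(chrom = "chr1", start = (seq_along(meth) - 1) * 400,
                   end = seq_along(meth) * 400, n_cpgs = 3,
                   meth = meth, unmeth = unmeth,
                   meth_pct = 100 * meth / (meth + unmeth))
  }
  a_m <- sample(0:30, 50, TRUE); a_u <- sample(1:30, 50, TRUE)
  b_m <- sample(0:30, 50, TRUE); b_u <- sample(1:30, 50, TRUE)
  d <- call_dmrs(mk(a_m, a_u), mk(b_m, b_u))
  ref <- mapply(function(am, au, bm, bu) {
    stats::fisher.test(matrix(c(am, au, bm, bu), 2, byrow = TRUE))$p.value
  }, a_m, a_u, b_m, b_u)
  expect_equal(d$p, unname(ref), tolerance = 1e-10)
})
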