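test_that("TPM columns sum to one million and respect gene length", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           s1 = c(100, 100, 300), s2 = c(10, 0, 90))
  lens <- tibble::tibble(gene_id = c("a", "b", "c"),
                         length = c(1000, 2000, 3000))
  tpm <- counts_to_tpm(counts, lens)
  expect_equal(colSums(tpm[c("s1", "s2")]), c(s1 = 1e6, s2 = 1e6),
               tolerance = 1e-9)
  # equal count / double length -> half the rate
  expect_equal(tpm$s1[1] / tpm$s1[2], 2, tolerance = 1e-12)
  expect_equal(tpm$s2[2], 0)
  expect_error(counts_to_tpm(counts, lens[1:2, ]), "missing")
  expect_error(counts_to_tpm(counts, dplyr::mutate(lens, length = 0)), "> 0")
})

test_that("gene filters drop biotypes, low expression and low variability", {
  set.seed(91)
  n <- 50
  ids <- sprintf("g%02d", 1:n)
  mat <- matrix(runif(n * 4, 10, 100), n, 4,
                dimnames = list(ids, paste0("s", 1:4)))
  mat[2, ] <- c(5, 5, 5, 1)      # boundary: exactly 5 in exactly 3 -> kept
  mat[3, ] <- 50                 # flat -> zero variability
  mat[4, ] <- c(6, 6, 4, 4)      # >= 5 in only 2 samples -> dropped
  tpm <- tibble::as_tibble(cbind(data.frame(gene_id = ids), mat))
  bt <- tibble::tibble(gene_id = ids,
                       biotype = c("miRNA", rep("protein_coding", n - 1)))

  # biotype + inclusive expression boundary, no variability drop
  keep0 <- filter_genes(tpm, bt, drop_low_variability_fraction = 0)
  expect_false("g01" %in% keep0$gene_id)  # short-noncoding biotype
  expect_true("g02" %in% keep0$gene_id)   # >= 5 TPM in >= 3 samples, inclusive
  expect_false("g04" %in% keep0$gene_id)  # fails the expression filter
  expect_equal(nrow(keep0), 48)           # 50 - g01 - g04

  # variability drop removes floor(0.2 * 48) = 9, zero-variance gene first
  out <- filter_genes(tpm, bt)
  expect_equal(nrow(out), 48 - 9)
  expect_false("g03" %in% out$gene_id)

  # idempotence: re-filtering the retained set with no floor changes nothing
  tpm2 <- dplyr::semi_join(tpm, out, by = "gene_id")
  out2 <- filter_genes(tpm2, bt, drop_low_variability_fraction = 0)
  expect_equal(out2$gene_id, out$gene_id)
})

test_that("DEG calls use strict thresholds and fold-change bins", {
  de <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    log2fc = c(1.5, 1.0, -2.5, 0.5, 5, -1.2),
    p = c(0.005, 0.005, 0.001, 0.001, 0.01, 0.02))
  out <- deg_call(de)
  expect_equal(out$deg_status,
               c("up", "ns", "down", "ns", "ns", "ns"))
  # strictly greater than 1 and strictly below 0.01 required:
  # g2 fails |lfc| = 1, g5 fails p = 0.01, g6 fails p
  expect_equal(out$lfc_bin[1], "(1,2]")
  expect_equal(out$lfc_bin[3], "(2,4]")
  expect_true(is.na(out$lfc_bin[2]))
  expect_warning(deg_call(dplyr::mutate(de, p = NA_real_)), "missing")
})

test_that("pi-values combine significance and direction as documented", {
  de <- tibble::tibble(gene_id = c("a", "b", "c"),
                       log2fc = c(2, -2, 1),
                       q = c(0.01, 0.01, 0))
  out <- pi_rank(de)
  expect_equal(out$pi[out$gene_id == "a"], -log10(0.01) * 2)  # 4.0
  expect_equal(out$pi[out$gene_id == "b"], -4)
  # q = 0 clamps to the smallest positive q (0.01)
  expect_equal(out$pi[out$gene_id == "c"], 2)
  expect_equal(out$gene_id, c("a", "c", "b"))  # sorted by pi descending
  expect_error(pi_rank(dplyr::mutate(de, q = c(-0.1, 0.5, 0.5))), "0, 1")
})

test_that("persistence fractions match direct set algebra", {
  ids <- sprintf("g%02d", 1:20)
  s1 <- rep("ns", 20); s1[1:6] <- "up"; s1[7:10] <- "down"
  s2 <- rep("ns", 20); s2[c(1:4, 11)] <- "up"; s2[7] <- "down"
  s2[5] <- "down"   # g05 switches direction
  d1 <- tibble::tibble(gene_id = ids, deg_status = s1)
  d2 <- tibble::tibble(gene_id = ids, deg_status = s2)
  res <- deg_persistence(d1, d2)
  up <- res$fractions[res$fractions$direction == "up", ]
  expect_equal(up$n_t1, 6)
  expect_equal(up$n_persist, 4)
  expect_equal(up$persistence, 4 / 6)
  down <- res$fractions[res$fractions$direction == "down", ]
  expect_equal(down$persistence, 1 / 4)
  expect_equal(res$fates$fate[res$fates$gene_id == "g05"], "switched")
  expect_equal(res$fates$fate[res$fates$gene_id == "g06"], "dropped")
  # t1 ns genes never appear in fates, even if they become DEGs later
  expect_false("g11" %in% res$fates$gene_id)
  expect_error(deg_persistence(d1, d2[1:10, ]), "universe")
})

test_that("correlation clustering reproduces a literal UPGMA oracle", {
  set.seed(101)
  mat <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
  cl <- correlation_cluster(mat)
  rho <- cor(mat, method = "spearman")
  expect_equal(cl$dist, 1 - rho)
  expect_equal(sort(cl$hclust$height),
               oracle_upgma_heights(as.dist(1 - rho)), tolerance = 1e-12)
  expect_setequal(cl$leaf_order, colnames(mat))
  # deterministic: permuting columns leaves the tree heights identical
  cl2 <- correlation_cluster(mat[, sample(8)])
  expect_equal(sort(cl2$hclust$height), sort(cl$hclust$height),
               tolerance = 1e-12)

  td <- tidy(cl)
  expect_equal(nrow(td), 7)
  expect_equal(td$height, cl$hclust$height)
  gl <- glance(cl)
  expect_equal(gl$n_items, 8)
  expect_error(correlation_cluster(cbind(mat, flat = rep(1, 10))), "flat")
})

test_that("samples sharing a planted signature cluster together", {
  with_sim_seed(111, {
    base <- rnorm(200)
    grp <- function(shift) replicate(3, base + shift + rnorm(200, sd = 0.3))
    mat <- cbind(grp(0), grp(3))
    colnames(mat) <- c(paste0("A", 1:3), paste0("B", 1:3))
    # make ranks differ between groups: B reverses the top half
    mat[1:100, 4:6] <- -mat[1:100, 4:6]
    cl <- correlation_cluster(mat)
    ord <- cl$leaf_order
    a_pos <- which(ord %in% paste0("A", 1:3))
    expect_true(all(diff(sort(a_pos)) == 1))  # A samples contiguous
  })
})
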