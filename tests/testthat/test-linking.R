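toy_genome <- function(seed = 1) {
  set.seed(seed)
  starts <- sort(sample.int(3e6, 50))
  peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                          start = starts, end = starts + 400,
                          id = region_id("chr1", starts, starts + 400))
  peaks$id <- region_id(peaks$chrom, peaks$start, peaks$end)
  genes <- tibble::tibble(gene = paste0("g", 1:10),
                          chrom = sample(c("chr1", "chr2"), 10, TRUE),
                          tss = sample.int(3e6, 10),
                          strand = sample(c("+", "-"), 10, TRUE))
  list(peaks = peaks, genes = genes)
}

test_that("candidate pairs equal the brute-force distance scan", {
  tg <- toy_genome()
  got <- candidate_pairs(tg$peaks, tg$genes, window = 5e5)
  centers <- (tg$peaks$start + tg$peaks$end) / 2
  want <- 0
  for (g in seq_len(10)) {
    for (p in seq_len(50)) {
      if (tg$peaks$chrom[p] == tg$genes$chrom[g] &&
          abs(centers[p] - tg$genes$tss[g]) <= 5e5) {
        want <- want + 1
        expect_true(any(got$peak == tg$peaks$id[p] &
                          got$gene == tg$genes$gene[g]))
      }
    }
  }
  expect_equal(nrow(got), want)
  # peak centered exactly at the TSS is included
  pk <- tibble::tibble(chrom = "chr1", start = 900, end = 1100,
                       id = "chr1-900-1100")
  gn <- tibble::tibble(gene = "G", chrom = "chr1", tss = 1000, strand = "+")
  expect_equal(nrow(candidate_pairs(pk, gn)), 1)
  # gene with no peak within the window yields no pairs
  gn2 <- tibble::tibble(gene = "G", chrom = "chr1", tss = 5e6, strand = "+")
  expect_equal(nrow(candidate_pairs(pk, gn2)), 0)
})

test_that("grouped correlation matches the definitional oracle", {
  acc <- rbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 7))
  expr <- rbind(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1),
                c(2.2, 0.1, 5.3, 1.7, 4.4, 3.3))
  pairs <- tibble::tibble(peak = "p1", gene = c("g1", "g2", "g3"),
                          peak_idx = 1L, gene_idx = 1:3,
                          distance = 0)
  got <- grouped_correlation(pairs, acc, expr)
  expect_equal(got$r[1], 1)
  expect_equal(got$r[2], -1)
  # definitional loop oracle
  x <- acc[1, ]; y <- expr[3, ]
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r[3], num / den, tolerance = 1e-12)
  # zero-variance vectors are dropped with a message
  accz <- rbind(acc, c(2, 2, 2, 2, 2, 2))
  pz <- tibble::tibble(peak = "pz", gene = "g1", peak_idx = 3L, gene_idx = 1L,
                       distance = 0)
  expect_message(out <- grouped_correlation(pz, accz, expr), "zero-variance")
  expect_equal(nrow(out), 0)
})

test_that("trans null uses 1000 shared peaks per chromosome, deterministically", {
  ch <- tiny_cohort()
  emb <- lsi_embedding(ch$atac, n_components = 10)
  mm <- make_metacells(emb, k = 20, n_groups = 60, seed = 1)
  accv <- as.matrix(log_normalize(aggregate_metacells(ch$atac, mm)))
  exprv <- as.matrix(log_normalize(aggregate_metacells(ch$rna, mm)))
  # 300 peaks over 4 chromosomes: fewer than 1000 trans peaks, so the null
  # must sample with replacement and report it
  expect_message(
    null <- build_null(ch$atac$peaks, ch$rna$genes, accv, exprv, seed = 5),
    "with replacement")
  np <- attr(null, "null_peaks")
  expect_true(all(lengths(np) == 1000))
  for (chr in names(np)) {
    expect_true(all(ch$atac$peaks$chrom[np[[chr]]] != chr))
  }
  null2 <- suppressMessages(
    build_null(ch$atac$peaks, ch$rna$genes, accv, exprv, seed = 5))
  expect_identical(attr(null, "null_peaks"), attr(null2, "null_peaks"))
  expect_true(all(null$sd0 > 0))
  expect_lt(mean(abs(null$mu0)), 0.05)
})

test_that("null z-scores and p-values follow the normal CDF oracle", {
  null <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                         mu0 = c(0, 0.1), sd0 = c(0.2, 0.2))
  class(null) <- c("null_model", class(null))
  pairs <- tibble::tibble(gene = c("g1", "g1", "g2", "g2"),
                          r = c(0.4, 0, 0.1, 0.3))
  got <- null_significance(pairs, null)
  expect_equal(got$z[1], 2)
  expect_equal(got$p[1], 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(got$p[1], 0.0455, tolerance = 1e-3)
  expect_equal(got$z[3], 0)
  expect_equal(got$p[3], 1)
  # symmetry: equal deviations on either side give equal p
  pm <- tibble::tibble(gene = c("g1", "g1"), r = c(0.25, -0.25))
  ps <- null_significance(pm, null)
  expect_equal(ps$p[1], ps$p[2])
  bad <- null; bad$sd0 <- c(0, 0.2)
  expect_error(null_significance(pairs, bad), "positive")
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(12)
  p <- runif(1000)^2
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("reliability combines FDR and promoter co-accessibility cutoffs", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(900, 50000, 80000),
                          end = c(1100, 50400, 80400),
                          id = c("prom", "distal1", "distal2"))
  peaks$id <- region_id(peaks$chrom, peaks$start, peaks$end)
  genes <- tibble::tibble(gene = "G", chrom = "chr1", tss = 1000,
                          strand = "+")
  base <- tibble::tibble(peak = peaks$id[2:3], gene = "G",
                         peak_idx = 2:3, gene_idx = 1L,
                         distance = c(49200, 79200), r = c(0.5, 0.5),
                         z = c(4, 4), p = c(1e-4, 1e-4))
  co <- tibble::tibble(peak_i = peaks$id[1], peak_j = peaks$id[2:3],
                       score = c(0.30, 0.15), distance = c(49200, 79200),
                       n_windows = 1L)
  net <- build_link_network(
    dplyr::mutate(base, fdr = c(0.05, 0.05)), co, peaks, genes)
  expect_true(net$reliable[net$peak == peaks$id[2]])   # fdr .05, coaccess .30
  expect_false(net$reliable[net$peak == peaks$id[3]])  # coaccess .15 fails
  # fdr above cutoff fails even with good co-accessibility
  net2 <- build_link_network(
    dplyr::mutate(base, fdr = c(0.15, 0.05)), co, peaks, genes)
  expect_false(net2$reliable[net2$peak == peaks$id[2]])
  # ovarian-cancer override relaxes the cutoff to 0.2
  net3 <- build_link_network(
    dplyr::mutate(base, fdr = c(0.15, 0.05)), co, peaks, genes,
    cancer_label = "OC")
  expect_true(net3$reliable[net3$peak == peaks$id[2]])
  expect_equal(attr(net3, "fdr_cut"), 0.2)
  # genes without a promoter peak are excluded with a message
  genes2 <- tibble::tibble(gene = "G", chrom = "chr1", tss = 2e5,
                           strand = "+")
  expect_message(
    net4 <- build_link_network(dplyr::mutate(base, fdr = 0.05), co, peaks,
                               genes2), "without a promoter")
  expect_equal(nrow(net4), 0)
})

test_that("candidate TFs are the motif union over reliable linked peaks", {
  net <- tibble::tibble(peak = c("p1", "p2", "p3"), gene = "G",
                        reliable = c(TRUE, TRUE, FALSE))
  matches <- matrix(c(TRUE, FALSE, TRUE,
                      TRUE, TRUE, TRUE,
                      FALSE, TRUE, TRUE), nrow = 3, byrow = TRUE,
                    dimnames = list(c("p1", "p2", "p3"), c("A", "B", "C")))
  expect_setequal(candidate_tfs_for_gene(net, matches, "G"), c("A", "B", "C"))
  net$reliable <- c(TRUE, FALSE, FALSE)
  expect_setequal(candidate_tfs_for_gene(net, matches, "G"), c("A", "C"))
  net$reliable <- FALSE
  expect_equal(candidate_tfs_for_gene(net, matches, "G"), character())
  expect_equal(candidate_tfs_for_gene(net, matches, "H"), character())
})

test_that("z is invariant to adding a constant to both grouped vectors", {
  set.seed(13)
  acc <- matrix(rnorm(5 * 30), 5)
  expr <- matrix(rnorm(4 * 30), 4)
  pairs <- tibble::tibble(peak = "p1", gene = "g1", peak_idx = 1L,
                          gene_idx = 1L, distance = 0)
  r1 <- grouped_correlation(pairs, acc, expr)$r
  r2 <- grouped_correlation(pairs, acc + 7, expr + 3)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})
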