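make_frags <- function(chrom, start, end, barcode, count = 1L) {
  tibble::tibble(chrom = chrom, start = start, end = end, barcode = barcode,
                 count = as.integer(count))
}

test_that("TSS enrichment is ~1 for uniform insertions and 0 without fragments", {
  set.seed(2)
  tss <- tibble::tibble(chrom = "chr1", tss = 50000)
  # fragments whose cut sites tile the window uniformly
  pos <- round(runif(20000, 48500, 51500))
  fr <- make_frags("chr1", pos, pos + 60, "cellU")
  sc <- tss_enrichment(fr, tss)
  expect_equal(sc$tss_enrichment, 1, tolerance = 0.1)
  # a cell with fragments nowhere near the TSS scores 0
  fr2 <- rbind(fr, make_frags("chr2", 100, 160, "cellFar"))
  sc2 <- tss_enrichment(fr2, tss)
  expect_equal(sc2$tss_enrichment[sc2$barcode == "cellFar"], 0)
})

test_that("TSS enrichment matches direct arithmetic on a 5-fragment toy", {
  tss <- tibble::tibble(chrom = "chr1", tss = 1000)
  # all insertions at the TSS itself: starts at 1000, ends at 1001 -> cut 1000
  fr <- make_frags("chr1", rep(1000, 5), rep(1001, 5), "cellT")
  sc <- tss_enrichment(fr, tss)
  # 10 insertions in the window, none in the flanks:
  # (10 / 2001) / (0.5 / 200)
  expect_equal(sc$tss_enrichment, (10 / 2001) / (0.5 / 200), tolerance = 1e-12)
})

test_that("nucleosome signal is the mono/sub length-band ratio", {
  fr <- make_frags("chr1", rep(0, 20), c(rep(50, 20)), "a")
  expect_equal(nucleosome_signal(fr)$nucleosome_signal, 0)
  fr2 <- rbind(make_frags("chr1", 0, 200, rep("b", 10)),
               make_frags("chr1", 0, 80, rep("b", 10)))
  expect_equal(nucleosome_signal(fr2)$nucleosome_signal, 1)
  fr3 <- rbind(make_frags("chr1", 0, 100, rep("c", 3)),
               make_frags("chr1", 0, 160, rep("c", 6)))
  expect_equal(nucleosome_signal(fr3)$nucleosome_signal, 2)
  # no subnucleosomal fragments -> infinite
  fr4 <- make_frags("chr1", 0, 200, "d")
  expect_equal(nucleosome_signal(fr4)$nucleosome_signal, Inf)
})

test_that("qc_filter applies strict printed bounds per modality", {
  thr <- qc_thresholds("atac")
  mk <- function(n_count, nucleosome_signal, tss_enrichment) {
    tibble::tibble(barcode = "c1", n_count = n_count,
                   nucleosome_signal = nucleosome_signal,
                   tss_enrichment = tss_enrichment)
  }
  counts <- Matrix::sparseMatrix(i = 1, j = 1, x = 3, dims = c(2, 1))
  x <- accessibility_matrix(counts,
                            tibble::tibble(chrom = "chr1", start = c(0, 200),
                                           end = c(100, 300),
                                           id = c("chr1-0-100", "chr1-200-300")),
                            "c1")
  keep_n <- function(metrics) {
    suppressWarnings(ncol(qc_filter(x, metrics, thr)$filtered$counts))
  }
  expect_equal(keep_n(mk(2500, 1.2, 4.0)), 1)     # passes all bounds
  expect_equal(keep_n(mk(2000, 1.2, 4.0)), 0)     # boundary count fails (strict)
  expect_equal(keep_n(mk(30000, 1.2, 4.0)), 0)    # upper bound strict
  expect_equal(keep_n(mk(2500, 4, 4.0)), 0)       # nucleosome must be < 4
  expect_equal(keep_n(mk(2500, 1.2, 2)), 0)       # TSS must be > 2

  rthr <- qc_thresholds("rna")
  expect_true(all(c(500, 50000) %in% unlist(rthr[rthr$metric == "n_count",
                                                 c("lower", "upper")])))
  rm <- tibble::tibble(barcode = "c1", n_count = 400, n_feature = 1000,
                       pct_mito = 5)
  y <- expression_matrix(counts,
                         tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                                        tss = c(10, 20), strand = "+"), "c1")
  expect_equal(suppressWarnings(
    ncol(qc_filter(y, rm, rthr)$filtered$counts)), 0)

  mthr <- qc_thresholds("multiome_atac")
  mm <- tibble::tibble(barcode = "c1", n_count = 25000, tss_enrichment = 5)
  expect_equal(suppressWarnings(
    ncol(qc_filter(x, mm, mthr)$filtered$counts)), 0)
})

test_that("qc_filter is idempotent and reports co-firing criteria", {
  thr <- qc_thresholds("atac")
  metrics <- tibble::tibble(barcode = paste0("c", 1:4),
                            n_count = c(2500, 100, 100, 4000),
                            nucleosome_signal = c(1, 1, 6, 1),
                            tss_enrichment = c(3, 1, 1, 3))
  counts <- Matrix::Matrix(matrix(1, 2, 4), sparse = TRUE)
  x <- accessibility_matrix(counts,
                            tibble::tibble(chrom = "chr1", start = c(0, 200),
                                           end = c(100, 300),
                                           id = c("p1", "p2")),
                            paste0("c", 1:4))
  res <- qc_filter(x, metrics, thr)
  expect_equal(res$filtered$cells, c("c1", "c4"))
  total <- res$report$removed[res$report$metric == "total"]
  expect_equal(total, 2)
  expect_gte(sum(res$report$removed[res$report$metric != "total"]), total)
  # idempotent: filtering again removes nothing
  res2 <- qc_filter(res$filtered, metrics, thr)
  expect_equal(res2$filtered$cells, res$filtered$cells)
})

test_that("log_normalize matches the closed form and a scalar-loop oracle", {
  m <- Matrix::Matrix(matrix(c(0, 10, 5, 3, 0, 2), nrow = 3), sparse = TRUE)
  ln <- log_normalize(m, scale = 1e4)
  expect_equal(as.numeric(ln[1, 1]), 0)
  # count 10 with column total 10000 at scale 1e4 -> ln(11)
  big <- Matrix::Matrix(matrix(c(10, 9990), ncol = 1), sparse = TRUE)
  expect_equal(as.numeric(log_normalize(big)[1, 1]), log(11), tolerance = 1e-12)
  # elementwise oracle
  dm <- as.matrix(m)
  want <- dm
  for (j in seq_len(ncol(dm))) {
    for (i in seq_len(nrow(dm))) {
      want[i, j] <- log(1 + dm[i, j] / sum(dm[, j]) * 1e4)
    }
  }
  expect_equal(as.matrix(ln), want, tolerance = 1e-12, ignore_attr = TRUE)
  m0 <- Matrix::Matrix(matrix(c(1, 0, 0, 0), 2), sparse = TRUE)
  expect_error(log_normalize(m0), "zero total")
})

test_that("LSI embedding agrees with a dense SVD oracle up to sign", {
  set.seed(3)
  m <- Matrix::Matrix(matrix(rpois(50 * 40, 1.2), nrow = 50), sparse = TRUE)
  m[1, ] <- 0  # all-zero peak must be tolerated
  m <- Matrix::drop0(m)
  emb <- lsi_embedding(m, n_components = 5)
  # dense oracle: same TF-IDF then base::svd
  dm <- as.matrix(m)
  dm <- dm[rowSums(dm > 0) > 0, ]
  tf <- sweep(dm, 2, colSums(as.matrix(m)), "/")
  idf <- log(1 + ncol(dm) / rowSums(dm > 0))
  sv <- svd(tf * idf)
  want <- sv$v[, seq_len(5)] %*% diag(sv$d[seq_len(5)])
  keep <- seq_len(ncol(emb))
  if (attr(emb, "dropped_first")) want <- want[, -1, drop = FALSE]
  for (k in seq_len(ncol(emb))) {
    cs <- abs(cor(emb[, k], want[, k]))
    expect_gte(cs, 0.999)
  }
  # duplicated cells embed identically
  m2 <- cbind(m, m[, 1])
  emb2 <- lsi_embedding(m2, n_components = 5)
  expect_equal(emb2[1, ], emb2[ncol(m2), ], tolerance = 1e-4)
})

test_that("metacell groups have exactly k members and cap overlap", {
  set.seed(4)
  emb <- matrix(rnorm(300 * 5), 300)
  mm <- make_metacells(emb, k = 50, n_groups = 40, max_overlap = 0.8, seed = 1)
  expect_true(all(lengths(mm$groups) == 50))
  expect_gt(length(mm$groups), 1)
  for (i in seq_along(mm$groups)) {
    for (j in seq_len(i - 1)) {
      ov <- length(intersect(mm$groups[[i]], mm$groups[[j]]))
      expect_lte(ov / (100 - ov), 0.8)
    }
  }
  # n_cells == k -> the single full group
  mm1 <- make_metacells(emb[1:50, ], k = 50, n_groups = 10, seed = 1)
  expect_equal(length(mm1$groups), 1)
  expect_equal(mm1$groups[[1]], 1:50)
  expect_error(make_metacells(emb[1:10, ], k = 50), "fewer cells")
  # duplicated seed neighborhoods: only one of two identical groups kept
  emb2 <- rbind(matrix(0.001 * rnorm(100 * 2), 100),
                matrix(5 + 0.001 * rnorm(100 * 2), 100))
  mm2 <- make_metacells(emb2, k = 100, n_groups = 200, max_overlap = 0.8,
                        seed = 2)
  expect_equal(length(mm2$groups), 2)
})

test_that("metacell aggregation preserves totals over covered cells", {
  ch <- tiny_cohort()
  emb <- lsi_embedding(ch$atac, n_components = 10)
  mm <- make_metacells(emb, k = 20, n_groups = 10, seed = 1)
  agg <- aggregate_metacells(ch$atac, mm)
  expect_equal(ncol(agg), length(mm$groups))
  g <- mm$groups[[3]]
  expect_equal(as.numeric(agg[, 3]),
               as.numeric(Matrix::rowSums(ch$atac$counts[, g])))
})

test_that("TSS enrichment separates intact from degraded cells", {
  ch <- memo("degraded", simulate_cohort(simulation_config(
    n_samples = 2, n_cancer_types = 2, cells_per_sample = 150,
    n_peaks = 600, n_genes = 150, n_motifs = 10, n_planted_links = 5,
    n_planted_programs = 2, program_gene_count = 15, n_planted_dars = 6,
    n_tumor_tfs = 2, degraded_fraction = 0.3, seed = 21)))
  tssl <- tibble::tibble(chrom = ch$rna$genes$chrom, tss = ch$rna$genes$tss)
  sc <- tss_enrichment(ch$fragments, tssl)
  lab <- sc$barcode %in% ch$truth$degraded_cells
  # AUROC via rank-sum identity
  r <- rank(sc$tss_enrichment)
  auroc <- (sum(r[!lab]) - sum(!lab) * (sum(!lab) + 1) / 2) /
    (sum(!lab) * sum(lab))
  expect_gt(auroc, 0.9)
})
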