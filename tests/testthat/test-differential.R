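test_that("small-sample Wilcoxon matches exact enumeration with ties", {
  x <- rep(5, 8); y <- rep(0, 8)
  expect_equal(creglink:::exact_ranksum_p(x, y), ranksum_enum_p(x, y),
               tolerance = 1e-12)
  set.seed(14)
  for (i in 1:5) {
    x <- sample(0:3, 7, replace = TRUE)
    y <- sample(0:3, 6, replace = TRUE)
    expect_equal(creglink:::exact_ranksum_p(x, y), ranksum_enum_p(x, y),
                 tolerance = 1e-12)
  }
  # without ties it also agrees with stats::wilcox.test exact p
  x <- c(1.2, 3.4, 2.2, 5.5); y <- c(0.3, 0.9, 4.1, 2.8, 1.9)
  expect_equal(creglink:::exact_ranksum_p(x, y),
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("find_dars flags planted peaks and gates by min_pct", {
  set.seed(15)
  n_per <- 30
  counts <- matrix(rpois(40 * 2 * n_per, 2), nrow = 40)
  counts[1, 1:n_per] <- rpois(n_per, 20)      # accessible only in type A
  counts[2, ] <- 0
  counts[2, 1] <- 1                           # below min_pct in type A
  peaks <- tibble::tibble(chrom = "chr1", start = (0:39) * 1000,
                          end = (0:39) * 1000 + 500,
                          id = region_id("chr1", (0:39) * 1000,
                                         (0:39) * 1000 + 500))
  labels <- rep(c("A", "B"), each = n_per)
  dars <- find_dars(Matrix::Matrix(counts, sparse = TRUE), labels,
                    peaks = peaks)
  expect_true(peaks$id[1] %in% dars$peak[dars$cell_type == "A"])
  expect_false(peaks$id[2] %in% dars$peak)
  expect_error(find_dars(Matrix::Matrix(counts, sparse = TRUE),
                         rep("A", 2 * n_per), peaks = peaks), "2 cell types")
})

test_that("identical accessibility distributions yield no DARs", {
  set.seed(16)
  counts <- matrix(rpois(50 * 60, 3), nrow = 50)
  peaks <- tibble::tibble(chrom = "chr1", start = (0:49) * 1000,
                          end = (0:49) * 1000 + 500,
                          id = region_id("chr1", (0:49) * 1000,
                                         (0:49) * 1000 + 500))
  dars <- find_dars(Matrix::Matrix(counts, sparse = TRUE),
                    rep(c("A", "B"), each = 30), peaks = peaks)
  expect_equal(nrow(dars), 0)
})

test_that("exact path matches enumeration inside find_dars on a 16-cell toy", {
  counts <- matrix(0, 2, 16)
  counts[1, 1:8] <- 5
  counts[2, ] <- rep(c(1, 2), 8)
  peaks <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                          end = c(500, 1500),
                          id = c("chr1-0-500", "chr1-1000-1500"))
  labels <- rep(c("A", "B"), each = 8)
  dars <- find_dars(Matrix::Matrix(counts, sparse = TRUE), labels,
                    peaks = peaks, fdr_max = 1.1, logfc_min = 0)
  ln <- as.matrix(log_normalize(Matrix::Matrix(counts, sparse = TRUE)))
  want <- ranksum_enum_p(ln[1, 1:8], ln[1, 9:16])
  got <- dars$p[dars$peak == peaks$id[1] & dars$cell_type == "A"]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cancer-exclusive DARs follow the 1 bp overlap rule", {
  dars <- tibble::tibble(
    chrom = "chr1",
    start = c(100, 150, 5000, 9000, 9100, 20000),
    end = c(200, 250, 5500, 9500, 9200, 20400),
    cell_type = "tumor",
    cancer_type = c("CA", "CB", "CA", "CB", "CA", "CB"))
  res <- cancer_specific_dars(dars)
  sp <- res$specific
  # rows 1-2 overlap across cancers -> excluded; 4-5 likewise
  expect_false(any(sp$start %in% c(100, 150, 9000, 9100)))
  expect_true(all(c(5000, 20000) %in% sp$start))
  # symmetric in cancer order
  res2 <- cancer_specific_dars(dars[seq(nrow(dars), 1), ])
  expect_setequal(paste(res2$specific$start), paste(sp$start))
})

test_that("mean specific proportion averages per-cancer proportions", {
  # 4/10 specific in CA and 2/10 in CB -> mean proportion 0.3
  mk <- function(cancer, n_specific, n_total, offset) {
    start <- offset + seq_len(n_total) * 1000
    shared <- n_total - n_specific
    tibble::tibble(chrom = "chr1", start = start, end = start + 100,
                   cell_type = "tumor", cancer_type = cancer,
                   shared = seq_len(n_total) <= shared)
  }
  ca <- mk("CA", 4, 10, 0)
  cb <- mk("CB", 2, 10, 100000)
  # CB rows 1-6 coincide with CA rows 1-6; CB rows 7-8 overlap CA rows 1-2
  # again (shifted), so CA loses rows 1-6 (4 specific) and CB rows 1-8
  # (2 specific)
  cb$start[1:6] <- ca$start[1:6]; cb$end[1:6] <- ca$end[1:6]
  cb$start[7:8] <- ca$start[1:2] + 10; cb$end[7:8] <- ca$end[1:2] + 10
  dars <- dplyr::bind_rows(ca[, 1:5], cb[, 1:5])
  res <- cancer_specific_dars(dars)
  props <- res$proportions
  expect_equal(sort(props$proportion), c(0.2, 0.4))
  expect_equal(unique(props$mean_proportion), 0.3)
})

test_that("iterative overlap merging matches hand iterations and the greedy oracle", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0, 50, 500),
                            end = c(100, 150, 600),
                            score = c(10, 5, 1))
  out <- iterative_overlap_merge(regions)
  expect_equal(out$start, c(0, 500))  # A beats B, C disjoint
  # chain A-B-C with scores 5,10,5: only B survives
  chain <- tibble::tibble(chrom = "chr1", start = c(0, 80, 160),
                          end = c(100, 180, 260), score = c(5, 10, 5))
  expect_equal(iterative_overlap_merge(chain)$start, 80)
  # no overlaps -> unchanged (sorted)
  disjoint <- tibble::tibble(chrom = "chr1", start = c(300, 0),
                             end = c(400, 100), score = c(1, 2))
  expect_equal(iterative_overlap_merge(disjoint)$start, c(0, 300))

  greedy_oracle <- function(rg) {
    rg$keep <- FALSE
    alive <- rep(TRUE, nrow(rg))
    repeat {
      cand <- which(alive)
      if (!length(cand)) break
      top <- cand[order(-rg$score[cand], rg$chrom[cand], rg$start[cand])][1]
      rg$keep[top] <- TRUE
      for (j in cand) {
        if (rg$chrom[j] == rg$chrom[top] &&
            min(rg$end[j], rg$end[top]) - max(rg$start[j], rg$start[top]) >= 1)
          alive[j] <- FALSE
      }
    }
    dplyr::arrange(rg[rg$keep, c("chrom", "start", "end", "score")],
                   chrom, start)
  }
  for (seed in 1:3) {
    set.seed(seed)
    rg <- random_regions(80, seed = seed)[, 1:3]
    rg$score <- round(runif(80, 0, 50), 1)
    got <- iterative_overlap_merge(rg)
    want <- greedy_oracle(rg)
    expect_equal(got[, c("chrom", "start", "end")],
                 want[, c("chrom", "start", "end")])
    # output is provably non-overlapping
    ov <- overlap_regions(got, got)
    expect_true(all(ov$i == ov$j))
    # every input overlaps some retained region
    cov <- overlap_regions(rg, got)
    expect_setequal(unique(cov$i), seq_len(nrow(rg)))
  }
})

test_that("conserved regions require support from at least two cancers", {
  mk <- function(cancer, starts) {
    tibble::tibble(chrom = "chr1", start = starts, end = starts + 100,
                   score = 5, cancer_type = cancer)
  }
  regions <- dplyr::bind_rows(
    mk("CA", c(1000, 5000)), mk("CB", c(1020, 9000)), mk("CC", c(1040, 13000)))
  out <- conserved_regulatory_regions(regions)
  # the 1000/1020/1040 cluster is supported by 3 cancers; others by 1
  expect_equal(nrow(out), 1)
  expect_equal(out$n_cancers, 3L)
  expect_error(conserved_regulatory_regions(mk("CA", 1000)), "2 cancer")
  # a cohort where only one cancer contributes regions yields empty output
  expect_equal(nrow(conserved_regulatory_regions(
    dplyr::bind_rows(mk("CA", 1000)[0, ], mk("CB", 2000)),
    n_cancer_types = 2)), 0)
})

test_that("regulatory regions intersect reliable peaks with cell-type DARs", {
  net <- tibble::tibble(
    peak = c("chr1-100-200", "chr1-5000-5100"),
    peak_chrom = "chr1", peak_start = c(100, 5000), peak_end = c(200, 5100),
    gene = c("g1", "g2"), fdr = c(1e-4, 1e-3), reliable = c(TRUE, TRUE))
  dars <- tibble::tibble(chrom = "chr1", start = 150, end = 400,
                         cell_type = "tumor")
  rg <- regulatory_regions_for_cell_type(net, dars, "tumor")
  expect_equal(nrow(rg), 1)
  expect_equal(rg$start, 100)
  expect_equal(rg$score, 4)
  expect_equal(nrow(regulatory_regions_for_cell_type(net, dars, "t_cell")), 0)
})
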