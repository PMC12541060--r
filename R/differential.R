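# Exact two-sided rank-sum p-value with ties, by dynamic programming over
# the distribution of the group-1 midrank sum (all equally likely subsets).
# Midranks are multiples of 1/2, so doubling makes the DP integral.
exact_ranksum_p <- function(x, y) {
  v <- c(x, y)
  n <- length(v)
  n1 <- length(x)
  r2 <- as.integer(round(2 * rank(v)))  # doubled midranks
  w_obs <- sum(r2[seq_len(n1)])
  # dp[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (val in r2) {
    for (k in min(n1, n):1) {
      nz <- which(dp[k, ] > 0)
      if (!length(nz)) next
      tgt <- nz + val
      ok <- tgt <= smax + 1
      dp[k + 1, tgt[ok]] <- dp[k + 1, tgt[ok]] + dp[k, nz[ok]]
    }
  }
  counts <- dp[n1 + 1, ]
  total <- sum(counts)
  sums <- seq_along(counts) - 1
  mu <- sum(counts * sums) / total
  dev <- abs(sums - mu)
  p <- sum(counts[dev >= abs(w_obs - mu) - 1e-9]) / total
  min(p, 1)
}

# Vectorized one-vs-rest rank-sum test over the rows of a matrix.
# ranks: precomputed per-row ranks over all cells; ties: per-row tie
# correction term sum(t^3 - t). Normal approximation with continuity
# correction, as used by the standard single-cell marker implementations.
ranksum_rows <- function(ranks, ties, in_group) {
  n <- ncol(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  w <- rowSums(ranks[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
  sigma2[sigma2 <= 0] <- NA
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p[is.na(p)] <- 1
  list(p = pmin(p, 1), auc = w / (n1 * n2))
}

row_tie_term <- function(m) {
  apply(m, 1, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
}

#' Cell-type differential accessible regions
#'
#' One-vs-rest Wilcoxon rank-sum tests on log-normalized accessibility for
#' every cell type, with detection-fraction and fold-change pre-filters and
#' a BH post-filter, in the manner of the standard single-cell marker tests.
#' Small comparisons (16 or fewer cells in total) use an exact tie-aware
#' rank-sum distribution; larger ones use the tie-corrected normal
#' approximation.
#'
#' @param x `accessibility_matrix`, or a peaks x cells matrix (then `peaks`
#'   must be given).
#' @param labels per-cell group labels; defaults to `cell_meta$cell_type`.
#' @param min_pct minimum detection fraction in the target group.
#' @param logfc_min minimum log2 fold change (target vs rest) of expm1-mean
#'   normalized accessibility, pseudocount 1.
#' @param fdr_max BH threshold applied within each cell type's tested peaks.
#' @param peaks region tibble when `x` is a bare matrix.
#' @return tibble of DARs passing all filters: `peak`, `chrom`, `start`,
#'   `end`, `cell_type`, `log2_fc`, `p`, `fdr`, `pct_in`, `pct_out`.
#' @export
find_dars <- function(x, labels = NULL, min_pct = 0.05, logfc_min = 0.25,
                      fdr_max = 0.05, peaks = NULL) {
  if (inherits(x, "accessibility_matrix")) {
    labels <- labels %||% x$cell_meta$cell_type
    peaks <- x$peaks
    counts <- x$counts
  } else {
    counts <- x
    if (is.null(peaks)) stop("peaks required for matrix input")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 cell types")
  if (min(table(labels)) < 3) stop("need at least 3 cells per type")
  ln <- as.matrix(log_normalize(counts))
  n <- ncol(ln)
  detected <- ln > 0
  small <- n <= 16
  if (!small) {
    ranks <- t(apply(ln, 1, rank))
    ties <- row_tie_term(ln)
  }
  res <- list()
  for (ct in sort(unique(labels))) {
    in_g <- labels == ct
    pct_in <- rowMeans(detected[, in_g, drop = FALSE])
    pct_out <- rowMeans(detected[, !in_g, drop = FALSE])
    mean_in <- rowMeans(expm1(ln[, in_g, drop = FALSE]))
    mean_out <- rowMeans(expm1(ln[, !in_g, drop = FALSE]))
    log2_fc <- log2((mean_in + 1) / (mean_out + 1))
    test <- which(pct_in >= min_pct & log2_fc >= logfc_min)
    if (!length(test)) next
    if (small) {
      p <- vapply(test, function(i)
        exact_ranksum_p(ln[i, in_g], ln[i, !in_g]), numeric(1))
    } else {
      p <- ranksum_rows(ranks[test, , drop = FALSE], ties[test], in_g)$p
    }
    fdr <- bh_adjust(p)
    keep <- fdr < fdr_max & mean_in[test] > mean_out[test]
    if (!any(keep)) next
    idx <- test[keep]
    res[[ct]] <- tibble::tibble(
      peak = peaks$id[idx], chrom = peaks$chrom[idx],
      start = peaks$start[idx], end = peaks$end[idx],
      cell_type = ct, log2_fc = log2_fc[idx], p = p[keep], fdr = fdr[keep],
      pct_in = pct_in[idx], pct_out = pct_out[idx])
  }
  if (!length(res)) {
    return(tibble::tibble(peak = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          cell_type = character(), log2_fc = numeric(),
                          p = numeric(), fdr = numeric(), pct_in = numeric(),
                          pct_out = numeric()))
  }
  dplyr::bind_rows(res)
}

#' Cancer-exclusive cell-type DARs
#'
#' A DAR is specific to its cancer type when it has no 1 bp-or-more overlap
#' with any DAR of the same cell type from another cancer type. Also
#' reports, per cell type, the proportion of specific DARs in each cancer
#' and the mean proportion over cancers.
#'
#' @param dars tibble of DARs with columns `chrom`, `start`, `end`,
#'   `cell_type`, `cancer_type` (e.g. [find_dars()] output run per cancer
#'   and bound together with a `cancer_type` column).
#' @return list with `specific` (the cancer-exclusive DAR rows) and
#'   `proportions` (tibble `cell_type`, `cancer_type`, `n_dars`,
#'   `n_specific`, `proportion`, `mean_proportion` per cell type).
#' @export
cancer_specific_dars <- function(dars) {
  stopifnot(all(c("chrom", "start", "end", "cell_type", "cancer_type")
                %in% names(dars)))
  dars <- dplyr::mutate(dars, .row = dplyr::row_number())
  specific_flag <- rep(TRUE, nrow(dars))
  for (ct in unique(dars$cell_type)) {
    sub <- dars[dars$cell_type == ct, , drop = FALSE]
    if (nrow(sub) < 2) next
    ov <- overlap_regions(sub, sub)
    ov <- ov[ov$i != ov$j, , drop = FALSE]
    cross <- sub$cancer_type[ov$i] != sub$cancer_type[ov$j]
    hit <- unique(ov$i[cross])
    specific_flag[sub$.row[hit]] <- FALSE
  }
  dars$specific <- specific_flag
  props <- dars |>
    dplyr::group_by(.data$cell_type, .data$cancer_type) |>
    dplyr::summarise(n_dars = dplyr::n(),
                     n_specific = sum(.data$specific), .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_specific / .data$n_dars) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(mean_proportion = mean(.data$proportion)) |>
    dplyr::ungroup()
  list(specific = dplyr::select(dars[dars$specific, , drop = FALSE], -".row",
                                -"specific"),
       proportions = props)
}

#' Iterative-overlap merging of scored regions
#'
#' Greedy selection of a non-overlapping region set: the highest-scoring
#' remaining region is kept and every region overlapping it (1 bp or more)
#' is discarded, until no region remains. Ties on score are broken by larger
#' `log2_fc` (when present) and then by coordinate order.
#'
#' @param regions tibble with `chrom`, `start`, `end`, `score` and
#'   optionally `log2_fc`.
#' @return the retained rows, sorted by coordinate, mutually
#'   non-overlapping; every input region overlaps exactly one retained
#'   region or is itself retained.
#' @export
iterative_overlap_merge <- function(regions) {
  if (!nrow(regions)) return(regions)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(regions)))
  lfc <- if ("log2_fc" %in% names(regions)) regions$log2_fc else rep(0, nrow(regions))
  ord <- order(-regions$score, -lfc, regions$chrom, regions$start, regions$end)
  ov <- overlap_regions(regions, regions)
  adj <- split(ov$j, ov$i)  # includes self
  alive <- rep(TRUE, nrow(regions))
  keep <- logical(nrow(regions))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[adj[[as.character(i)]]] <- FALSE
  }
  out <- regions[keep, , drop = FALSE]
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Cell-type-conserved regulatory regions across cancer types
#'
#' Per cancer type, the cell-type-associated regulatory regions are the
#' reliable-link peaks overlapping (1 bp or more) that cancer's cell-type
#' DARs. These are merged across cancers with the iterative-overlap method
#' and only merged regions supported by regions from at least
#' `min_cancers` cancer types are retained.
#'
#' @param regions tibble of per-cancer cell-type-associated regulatory
#'   regions: `chrom`, `start`, `end`, `score`, `cancer_type` (see
#'   [regulatory_regions_for_cell_type()] for the intersection step).
#' @param min_cancers minimum number of distinct cancer types a retained
#'   region must be supported by.
#' @param n_cancer_types number of cancer types in the analysis (defaults
#'   to the number present in `regions`); fewer than 2 is an error, but a
#'   cohort where some cancers contribute no regions yields an empty
#'   result rather than an error.
#' @return tibble of conserved regions with `n_cancers` support counts.
#' @export
conserved_regulatory_regions <- function(regions, min_cancers = 2,
                                         n_cancer_types = NULL) {
  present <- length(unique(regions$cancer_type))
  n_cancer <- n_cancer_types %||% present
  if (n_cancer < 2) stop("need at least 2 cancer types")
  if (!nrow(regions) || present < min_cancers) return(tibble::tibble())
  merged <- iterative_overlap_merge(regions)
  ov <- overlap_regions(merged, regions)
  support <- tapply(regions$cancer_type[ov$j], ov$i,
                    function(v) length(unique(v)))
  merged$n_cancers <- 0L
  merged$n_cancers[as.integer(names(support))] <- as.integer(support)
  merged[merged$n_cancers >= min_cancers, , drop = FALSE]
}

#' Intersect reliable-link peaks with cell-type DARs
#'
#' Step one of the conserved-region analysis for one cancer type: reliable
#' peaks of the link network that overlap (1 bp or more) the given cell
#' type's DARs. The region score is `-log10(fdr)` of the best link of the
#' peak.
#'
#' @param network `link_network` tibble for one cancer type.
#' @param dars DAR tibble for the same cancer type ([find_dars()] output).
#' @param cell_type cell type of interest.
#' @return region tibble (`chrom`, `start`, `end`, `score`).
#' @export
regulatory_regions_for_cell_type <- function(network, dars, cell_type) {
  rel <- network[network$reliable, , drop = FALSE]
  if (!nrow(rel)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), score = numeric()))
  }
  pk <- rel |>
    dplyr::group_by(.data$peak) |>
    dplyr::summarise(chrom = dplyr::first(.data$peak_chrom),
                     start = dplyr::first(.data$peak_start),
                     end = dplyr::first(.data$peak_end),
                     score = -log10(pmax(min(.data$fdr), 1e-300)),
                     .groups = "drop")
  d <- dars[dars$cell_type == cell_type, , drop = FALSE]
  if (!nrow(d)) return(pk[0, c("chrom", "start", "end", "score")])
  ov <- overlap_regions(pk, d)
  pk[sort(unique(ov$i)), c("chrom", "start", "end", "score")]
}
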