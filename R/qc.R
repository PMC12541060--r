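#' Tn5 insertion sites of fragments
#'
#' Each sequenced fragment contributes two Tn5 insertion events, one at each
#' end. In 0-based half-open coordinates the cut positions are `start` and
#' `end - 1`.
#'
#' @param fragments fragment tibble (`chrom`, `start`, `end`, `barcode`,
#'   `count`).
#' @return tibble with columns `chrom`, `pos`, `barcode`, `count` (two rows
#'   per fragment).
#' @export
fragment_insertions <- function(fragments) {
  tibble::tibble(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start, fragments$end - 1),
    barcode = rep(fragments$barcode, 2L),
    count = rep(fragments$count, 2L)
  )
}

#' Per-cell TSS enrichment score
#'
#' For every cell, Tn5 insertions are aggregated over windows of +/- 1000 bp
#' around each TSS. The score is the mean insertion count per base over the
#' whole window divided by the mean insertion count per base in the outer
#' 100 bp flanks (positions 901-1000 bp from the TSS on both sides), with a
#' pseudocount of 0.5 added to the flank insertion total so cells without
#' flank insertions get a finite score.
#'
#' @param fragments fragment tibble.
#' @param tss_list tibble with columns `chrom` and `tss` (0-based position).
#' @param flank_width width of the outer flank used for normalization (bp).
#' @param window half-width of the TSS window (bp).
#' @return tibble with columns `barcode`, `tss_enrichment`. Cells present in
#'   `fragments` but with no insertions near any TSS score 0.
#' @export
tss_enrichment <- function(fragments, tss_list, window = 1000,
                           flank_width = 100) {
  stopifnot(nrow(tss_list) >= 1)
  barcodes <- unique(fragments$barcode)
  ins <- fragment_insertions(fragments)
  center_n <- setNames(numeric(length(barcodes)), barcodes)
  flank_n <- setNames(numeric(length(barcodes)), barcodes)
  for (chr in intersect(unique(ins$chrom), unique(tss_list$chrom))) {
    ii <- ins[ins$chrom == chr, ]
    tss <- tss_list$tss[tss_list$chrom == chr]
    pts <- IRanges::IRanges(start = ii$pos + 1L, width = 1L)
    win <- IRanges::IRanges(start = tss - window + 1L, end = tss + window + 1L)
    hits <- IRanges::findOverlaps(pts, win)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    d <- abs(ii$pos[qi] - tss[S4Vectors::subjectHits(hits)])
    w <- ii$count[qi]
    bc <- ii$barcode[qi]
    cc <- tapply(w, bc, sum)
    center_n[names(cc)] <- center_n[names(cc)] + cc
    in_flank <- d > (window - flank_width) & d <= window
    if (any(in_flank)) {
      fc <- tapply(w[in_flank], bc[in_flank], sum)
      flank_n[names(fc)] <- flank_n[names(fc)] + fc
    }
  }
  n_center_bases <- (2 * window + 1) * nrow(tss_list)
  n_flank_bases <- 2 * flank_width * nrow(tss_list)
  score <- (center_n / n_center_bases) / ((flank_n + 0.5) / n_flank_bases)
  score[center_n == 0] <- 0
  tibble::tibble(barcode = barcodes, tss_enrichment = unname(score[barcodes]))
}

#' Per-cell nucleosome signal
#'
#' Ratio of mononucleosome-length fragments (147-294 bp) to subnucleosomal
#' fragments (< 147 bp), weighted by duplicate count. Cells with no
#' subnucleosomal fragments get `Inf`.
#'
#' @param fragments fragment tibble.
#' @param mono length range `c(low, high)` counted as mononucleosomal.
#' @return tibble with columns `barcode`, `nucleosome_signal`.
#' @export
nucleosome_signal <- function(fragments, mono = c(147, 294)) {
  len <- fragments$end - fragments$start
  is_mono <- len >= mono[1] & len <= mono[2]
  is_sub <- len < mono[1]
  bc <- unique(fragments$barcode)
  mono_n <- tapply(fragments$count[is_mono], fragments$barcode[is_mono], sum)
  sub_n <- tapply(fragments$count[is_sub], fragments$barcode[is_sub], sum)
  m <- setNames(numeric(length(bc)), bc)
  s <- setNames(numeric(length(bc)), bc)
  m[names(mono_n)] <- mono_n
  s[names(sub_n)] <- sub_n
  tibble::tibble(barcode = bc, nucleosome_signal = unname(m[bc] / s[bc]))
}

#' Quality-control thresholds for a modality
#'
#' Returns the per-cell QC bounds applied to each modality. All bounds are
#' strict inequalities: a cell is kept only if `metric > lower` and
#' `metric < upper` for every bounded metric. Defaults follow common
#' practice for droplet single-cell assays: ATAC cells need between 2000 and
#' 30,000 fragment counts in peaks, nucleosome signal below 4 and TSS
#' enrichment above 2; RNA cells need between 500 and 50,000 UMIs, between
#' 500 and 6000 detected features and below 25% mitochondrial reads;
#' multiome cells use 1000-20,000 (ATAC) and 500-25,000 (RNA) count bounds.
#'
#' @param modality one of `"atac"`, `"rna"`, `"multiome_atac"`,
#'   `"multiome_rna"`.
#' @return tibble with columns `metric`, `lower`, `upper` (NA = unbounded).
#' @export
qc_thresholds <- function(modality = c("atac", "rna", "multiome_atac",
                                       "multiome_rna")) {
  modality <- match.arg(modality)
  tb <- switch(modality,
    atac = tibble::tribble(
      ~metric, ~lower, ~upper,
      "n_count", 2000, 30000,
      "nucleosome_signal", NA, 4,
      "tss_enrichment", 2, NA
    ),
    rna = tibble::tribble(
      ~metric, ~lower, ~upper,
      "n_count", 500, 50000,
      "n_feature", 500, 6000,
      "pct_mito", NA, 25
    ),
    multiome_atac = tibble::tribble(
      ~metric, ~lower, ~upper,
      "n_count", 1000, 20000,
      "tss_enrichment", 2, NA
    ),
    multiome_rna = tibble::tribble(
      ~metric, ~lower, ~upper,
      "n_count", 500, 25000,
      "n_feature", 500, 6000,
      "pct_mito", NA, 25
    )
  )
  bad <- !is.na(tb$lower) & !is.na(tb$upper) & tb$lower >= tb$upper
  stopifnot(!any(bad))
  tb$modality <- modality
  tb
}

#' Filter cells on QC metrics
#'
#' Applies the strict-inequality bounds of a threshold table to a per-cell
#' metric table and subsets the count matrix to the passing cells.
#'
#' @param x an `accessibility_matrix` or `expression_matrix`.
#' @param metrics tibble with a `barcode` column and one column per metric
#'   named in `thresholds` (extra columns ignored). Every cell of `x` must
#'   have a metric row.
#' @param thresholds threshold tibble from [qc_thresholds()] (possibly
#'   edited).
#' @return list with `filtered` (same class as `x`, passing cells only) and
#'   `report` (tibble of per-criterion removal counts; criteria can co-fire
#'   so the counts may sum to more than the total removed).
#' @export
qc_filter <- function(x, metrics, thresholds) {
  cells <- x$cells
  idx <- match(cells, metrics$barcode)
  if (anyNA(idx)) stop("metrics missing for ", sum(is.na(idx)), " cells")
  metrics <- metrics[idx, , drop = FALSE]
  keep <- rep(TRUE, length(cells))
  rows <- vector("list", nrow(thresholds))
  for (i in seq_len(nrow(thresholds))) {
    m <- thresholds$metric[i]
    if (!m %in% names(metrics)) stop("metric '", m, "' absent from metrics table")
    v <- metrics[[m]]
    ok <- rep(TRUE, length(v))
    if (!is.na(thresholds$lower[i])) ok <- ok & v > thresholds$lower[i]
    if (!is.na(thresholds$upper[i])) ok <- ok & v < thresholds$upper[i]
    ok[is.na(v)] <- FALSE
    rows[[i]] <- tibble::tibble(metric = m,
                                lower = thresholds$lower[i],
                                upper = thresholds$upper[i],
                                removed = sum(!ok))
    keep <- keep & ok
  }
  report <- dplyr::bind_rows(rows)
  report <- dplyr::bind_rows(report, tibble::tibble(
    metric = "total", lower = NA, upper = NA, removed = sum(!keep)))
  if (!any(keep)) warning("qc_filter removed every cell")
  filtered <- subset_cells(x, which(keep))
  list(filtered = filtered, report = report)
}

#' Subset a matrix object to a set of cells
#' @param x `accessibility_matrix` or `expression_matrix`.
#' @param idx integer or logical index over cells.
#' @export
subset_cells <- function(x, idx) {
  x$counts <- x$counts[, idx, drop = FALSE]
  x$cells <- x$cells[idx]
  x$cell_meta <- x$cell_meta[idx, , drop = FALSE]
  x
}

#' Basic per-cell count metrics from a count matrix
#' @param x `accessibility_matrix` or `expression_matrix`.
#' @return tibble with `barcode`, `n_count`, `n_feature`.
#' @export
count_metrics <- function(x) {
  tibble::tibble(
    barcode = x$cells,
    n_count = col_totals(x$counts),
    n_feature = Matrix::colSums(x$counts > 0)
  )
}
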