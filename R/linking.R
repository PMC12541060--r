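#' Candidate peak-gene pairs within a genomic window
#'
#' All pairs of a peak and a gene on the same chromosome whose peak center
#' lies within `window` bp of the gene's strand-aware TSS.
#'
#' @param peaks region tibble.
#' @param genes gene tibble (`gene`, `chrom`, `tss`, `strand`).
#' @param window half-width of the search window around the TSS (bp).
#' @return tibble with columns `peak`, `gene`, `peak_idx`, `gene_idx`,
#'   `distance` (peak center minus TSS, signed in TSS-to-peak direction on
#'   the gene strand).
#' @export
candidate_pairs <- function(peaks, genes, window = 5e5) {
  validate_regions(peaks)
  centers <- (peaks$start + peaks$end) / 2
  out <- list()
  for (chr in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    pi <- which(peaks$chrom == chr)
    gi <- which(genes$chrom == chr)
    for (g in gi) {
      hit <- pi[abs(centers[pi] - genes$tss[g]) <= window]
      if (!length(hit)) next
      d <- centers[hit] - genes$tss[g]
      if (genes$strand[g] == "-") d <- -d
      out[[length(out) + 1]] <- tibble::tibble(
        peak = peaks$id[hit], gene = genes$gene[g],
        peak_idx = hit, gene_idx = g, distance = d)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(peak = character(), gene = character(),
                          peak_idx = integer(), gene_idx = integer(),
                          distance = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Pearson correlation of candidate pairs over metacell groups
#'
#' @param pairs tibble from [candidate_pairs()].
#' @param acc_values peaks x groups matrix of log-normalized aggregated
#'   accessibility.
#' @param expr_values genes x groups matrix of log-normalized aggregated
#'   expression (same group order).
#' @return `pairs` with an added column `r`. Pairs where either vector has
#'   zero variance are dropped with a message.
#' @export
grouped_correlation <- function(pairs, acc_values, expr_values) {
  stopifnot(ncol(acc_values) == ncol(expr_values))
  if (ncol(acc_values) < 3) stop("need at least 3 metacell groups")
  acc_values <- as.matrix(acc_values)
  expr_values <- as.matrix(expr_values)
  va <- apply(acc_values, 1, var)
  vg <- apply(expr_values, 1, var)
  ok <- va[pairs$peak_idx] > 0 & vg[pairs$gene_idx] > 0
  if (any(!ok)) {
    message("dropping ", sum(!ok), " pair(s) with zero-variance vectors")
    pairs <- pairs[ok, , drop = FALSE]
  }
  az <- standardize_rows(acc_values)
  gz <- standardize_rows(expr_values)
  n <- ncol(az)
  r <- rowSums(az[pairs$peak_idx, , drop = FALSE] *
                 gz[pairs$gene_idx, , drop = FALSE]) / (n - 1)
  pairs$r <- unname(r)
  pairs
}

standardize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0] <- 1
  (m - mu) / s
}

#' Trans-chromosomal null model for peak-gene correlations
#'
#' For each chromosome, `n_null` peaks located on other chromosomes are
#' sampled once and correlated with every gene on that chromosome; each
#' gene's null mean and standard deviation calibrate its cis correlations.
#'
#' @param peaks region tibble matching `acc_values` rows.
#' @param genes gene tibble matching `expr_values` rows.
#' @param acc_values,expr_values log-normalized aggregated matrices as in
#'   [grouped_correlation()].
#' @param n_null number of trans-chromosome peaks per chromosome.
#' @param seed RNG seed for null-peak sampling.
#' @return `null_model` object: tibble with columns `gene`, `chrom`, `mu0`,
#'   `sd0`, plus attribute `null_peaks` (list of peak index vectors per
#'   chromosome).
#' @export
build_null <- function(peaks, genes, acc_values, expr_values, n_null = 1000,
                       seed = 1) {
  acc_values <- as.matrix(acc_values)
  expr_values <- as.matrix(expr_values)
  az <- standardize_rows(acc_values)
  gz <- standardize_rows(expr_values)
  n <- ncol(az)
  set.seed(seed)
  chroms <- unique(genes$chrom)
  null_sets <- list()
  rows <- list()
  for (chr in chroms) {
    off <- which(peaks$chrom != chr)
    if (!length(off)) stop("no trans-chromosome peaks available for ", chr)
    if (length(off) >= n_null) {
      pick <- sample(off, n_null)
    } else {
      message("chromosome ", chr, ": only ", length(off),
              " trans peaks; sampling with replacement")
      pick <- sample(off, n_null, replace = TRUE)
    }
    null_sets[[chr]] <- pick
    gi <- which(genes$chrom == chr)
    # genes-on-chr x null-peaks correlation matrix
    rmat <- tcrossprod(gz[gi, , drop = FALSE], az[pick, , drop = FALSE]) / (n - 1)
    mu0 <- rowMeans(rmat)
    sd0 <- apply(rmat, 1, sd)
    if (any(sd0 == 0)) stop("degenerate null: zero standard deviation")
    rows[[chr]] <- tibble::tibble(gene = genes$gene[gi], chrom = chr,
                                  mu0 = mu0, sd0 = sd0)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "null_peaks") <- null_sets
  class(out) <- c("null_model", class(out))
  out
}

#' Calibrate correlations against the trans null
#'
#' Transforms each correlation into a z-score using the gene's null mean and
#' standard deviation, and into a two-sided normal p-value.
#'
#' @param pairs tibble with columns `gene` and `r` (from
#'   [grouped_correlation()]).
#' @param null `null_model` from [build_null()].
#' @return `pairs` with added columns `z` and `p`.
#' @export
null_significance <- function(pairs, null) {
  idx <- match(pairs$gene, null$gene)
  if (anyNA(idx)) stop("null model missing for some genes")
  mu0 <- null$mu0[idx]
  sd0 <- null$sd0[idx]
  if (any(sd0 <= 0)) stop("null standard deviation must be positive")
  z <- (pairs$r - mu0) / sd0
  pairs$z <- z
  pairs$p <- 2 * pnorm(-abs(z))
  pairs
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, pooled over the supplied vector.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted values, clipped to 1, monotone in `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Assemble the reliable peak-gene link network
#'
#' A gene's promoter peaks are the peaks overlapping TSS +/-
#' `promoter_window / 2`. A link is reliable when its correlation survives
#' the FDR cutoff and the peak's best co-accessibility to any promoter peak
#' of the gene (other than itself) exceeds `coaccess_cut`. For ovarian
#' cancer (`cancer_label = "OC"`) the FDR cutoff is relaxed to 0.2.
#'
#' @param pairs tibble with `peak`, `gene`, `peak_idx`, `gene_idx`,
#'   `distance`, `r`, `z`, `p` (see [null_significance()]); `fdr` is added
#'   here by pooled BH over all supplied pairs if absent.
#' @param coaccess co-accessibility tibble from [coaccess_scores()].
#' @param peaks,genes region and gene tibbles.
#' @param promoter_window total promoter width centered on the TSS (bp).
#' @param fdr_cut FDR cutoff for a significant correlation.
#' @param coaccess_cut minimum peak-to-promoter co-accessibility.
#' @param cancer_label optional cancer-type label; `"OC"` switches
#'   `fdr_cut` to 0.2.
#' @return `link_network` tibble: one row per candidate pair of a gene with
#'   at least one promoter peak, with columns `peak`, `peak_chrom`,
#'   `peak_start`, `peak_end`, `gene`, `gene_chrom`, `tss`, `distance`, `r`,
#'   `z`, `p`, `fdr`, `coaccess`, `reliable`.
#' @export
build_link_network <- function(pairs, coaccess, peaks, genes,
                               promoter_window = 2000, fdr_cut = 0.1,
                               coaccess_cut = 0.2, cancer_label = NULL) {
  if (!is.null(cancer_label) && identical(cancer_label, "OC")) fdr_cut <- 0.2
  if (!"fdr" %in% names(pairs)) pairs$fdr <- bh_adjust(pairs$p)
  half <- promoter_window / 2
  prom <- tibble::tibble(chrom = genes$chrom,
                         start = pmax(genes$tss - half, 0),
                         end = genes$tss + half)
  hits <- overlap_regions(peaks, prom)
  promoter_peaks <- split(peaks$id[hits$i], genes$gene[hits$j])
  no_prom <- setdiff(unique(pairs$gene), names(promoter_peaks))
  if (length(no_prom)) {
    message(length(no_prom), " gene(s) without a promoter peak excluded")
    pairs <- pairs[!pairs$gene %in% no_prom, , drop = FALSE]
  }
  # symmetric score lookup, vectorized over (pair, promoter peak) combos
  co_keys <- c(paste(coaccess$peak_i, coaccess$peak_j, sep = "|"),
               paste(coaccess$peak_j, coaccess$peak_i, sep = "|"))
  co_vals <- c(coaccess$score, coaccess$score)
  prom_tb <- tibble::tibble(
    gene = as.character(rep(names(promoter_peaks), lengths(promoter_peaks))),
    prom_peak = as.character(unlist(promoter_peaks, use.names = FALSE)))
  combos <- dplyr::inner_join(
    tibble::tibble(pair_id = seq_len(nrow(pairs)), peak = pairs$peak,
                   gene = pairs$gene),
    prom_tb, by = "gene", relationship = "many-to-many")
  combos <- combos[combos$prom_peak != combos$peak, , drop = FALSE]
  combos$score <- co_vals[match(paste(combos$peak, combos$prom_peak, sep = "|"),
                                co_keys)]
  combos <- combos[!is.na(combos$score), , drop = FALSE]
  best_co <- rep(NA_real_, nrow(pairs))
  if (nrow(combos)) {
    agg <- tapply(combos$score, combos$pair_id, max)
    best_co[as.integer(names(agg))] <- unname(agg)
  }
  gidx <- match(pairs$gene, genes$gene)
  pidx <- match(pairs$peak, peaks$id)
  out <- tibble::tibble(
    peak = pairs$peak,
    peak_chrom = peaks$chrom[pidx],
    peak_start = peaks$start[pidx],
    peak_end = peaks$end[pidx],
    gene = pairs$gene,
    gene_chrom = genes$chrom[gidx],
    tss = genes$tss[gidx],
    distance = pairs$distance,
    r = pairs$r, z = pairs$z, p = pairs$p, fdr = pairs$fdr,
    coaccess = best_co,
    reliable = pairs$fdr < fdr_cut & !is.na(best_co) & best_co > coaccess_cut
  )
  class(out) <- c("link_network", class(out))
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "coaccess_cut") <- coaccess_cut
  out
}

#' Candidate transcription factors for a gene
#'
#' The union of motifs matched in any reliable peak linked to the gene.
#'
#' @param network `link_network` tibble.
#' @param matches logical/numeric peak-by-motif match matrix with peak ids
#'   as row names and motif names as column names.
#' @param gene gene symbol.
#' @return character vector of motif names (empty if the gene has no
#'   reliable links).
#' @export
candidate_tfs_for_gene <- function(network, matches, gene) {
  pk <- network$peak[network$gene == gene & network$reliable]
  pk <- intersect(pk, rownames(matches))
  if (!length(pk)) return(character())
  sub <- matches[pk, , drop = FALSE]
  colnames(sub)[colSums(as.matrix(sub)) > 0]
}

#' Peak-gene linking pipeline step
#'
#' Convenience wrapper: candidate pairs, grouped correlations, trans null,
#' z/p calibration, pooled BH adjustment, and reliable-network assembly.
#'
#' @inheritParams candidate_pairs
#' @inheritParams build_link_network
#' @param acc_agg,expr_agg aggregated (metacell) count matrices, peaks x
#'   groups and genes x groups; log-normalized internally.
#' @param n_null trans-null peaks per chromosome.
#' @param seed RNG seed for the null.
#' @return `link_network` tibble (see [build_link_network()]).
#' @export
link_peaks <- function(acc_agg, expr_agg, peaks, genes, coaccess,
                       window = 5e5, n_null = 1000, promoter_window = 2000,
                       fdr_cut = 0.1, coaccess_cut = 0.2,
                       cancer_label = NULL, seed = 1) {
  acc_values <- as.matrix(log_normalize(acc_agg))
  expr_values <- as.matrix(log_normalize(expr_agg))
  pairs <- candidate_pairs(peaks, genes, window = window)
  pairs <- grouped_correlation(pairs, acc_values, expr_values)
  null <- build_null(peaks, genes, acc_values, expr_values,
                     n_null = n_null, seed = seed)
  pairs <- null_significance(pairs, null)
  pairs$fdr <- bh_adjust(pairs$p)
  build_link_network(pairs, coaccess, peaks, genes,
                     promoter_window = promoter_window, fdr_cut = fdr_cut,
                     coaccess_cut = coaccess_cut, cancer_label = cancer_label)
}
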