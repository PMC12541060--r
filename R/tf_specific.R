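#' Tumor-specific transcription factors (triple filter)
#'
#' A TF is called tumor-specific when, comparing tumor cells with normal
#' epithelial cells, it shows (a) higher motif deviation z-scores
#' (Wilcoxon, BH FDR below `fdr_max`, higher tumor mean), (b) increased
#' binding, operationalized as a higher flank-normalized footprint maximum
#' in the tumor pseudo-bulk, and (c) elevated expression of the TF gene
#' (log2 fold change above `logfc_min` with Wilcoxon BH FDR below
#' `fdr_max`). Results are ranked by the tumor-minus-normal deviation
#' difference.
#'
#' @param deviations `deviation_result` from [chromvar_deviations()].
#' @param fragments fragment tibble (for footprints).
#' @param motif_sites tibble with columns `motif`, `chrom`, `center`.
#' @param expr `expression_matrix`; TF genes are matched to motif names via
#'   `motif_genes`.
#' @param cell_meta tibble with `barcode` and `cell_type` covering the
#'   deviation and expression cells.
#' @param tumor_label,normal_label cell-type labels being compared.
#' @param fdr_max BH threshold for criteria (a) and (c).
#' @param logfc_min expression log2 fold-change threshold for criterion (c).
#' @param motif_genes named character vector mapping motif name to gene
#'   symbol; defaults to the identity mapping.
#' @return tibble, one row per motif, ranked by deviation difference among
#'   selected TFs first: `motif`, `gene`, `dev_diff`, `dev_fdr`,
#'   `pass_deviation`, `fp_max_tumor`, `fp_max_normal`, `pass_footprint`,
#'   `expr_log2_fc`, `expr_fdr`, `pass_expression`, `selected`.
#' @export
tumor_specific_tfs <- function(deviations, fragments, motif_sites, expr,
                               cell_meta, tumor_label = "tumor",
                               normal_label = "epithelial", fdr_max = 0.05,
                               logfc_min = 0.25, motif_genes = NULL) {
  z <- deviations$z
  motifs <- rownames(z)
  if (is.null(motif_genes)) motif_genes <- setNames(motifs, motifs)
  lab <- cell_meta$cell_type[match(colnames(z), cell_meta$barcode)]
  if (!tumor_label %in% lab || !normal_label %in% lab) {
    stop("both tumor and normal labels must be present")
  }
  in_t <- lab == tumor_label
  in_n <- lab == normal_label
  # (a) deviation z, tumor vs normal epithelium
  zsub <- z[, in_t | in_n, drop = FALSE]
  sub_t <- lab[in_t | in_n] == tumor_label
  zsub[is.na(zsub)] <- 0
  ranks <- t(apply(zsub, 1, rank))
  ties <- row_tie_term(zsub)
  dev_p <- ranksum_rows(ranks, ties, sub_t)$p
  dev_fdr <- bh_adjust(dev_p)
  dev_diff <- rowMeans(z[, in_t, drop = FALSE], na.rm = TRUE) -
    rowMeans(z[, in_n, drop = FALSE], na.rm = TRUE)
  pass_dev <- dev_fdr < fdr_max & dev_diff > 0
  # (b) footprint maxima in pseudo-bulk
  cells_t <- cell_meta$barcode[cell_meta$cell_type == tumor_label]
  cells_n <- cell_meta$barcode[cell_meta$cell_type == normal_label]
  fp_t <- fp_n <- rep(NA_real_, length(motifs))
  for (m in seq_along(motifs)) {
    sites <- motif_sites[motif_sites$motif == motifs[m], , drop = FALSE]
    if (!nrow(sites)) next
    fp_t[m] <- tryCatch(max(footprint_profile(fragments, sites, cells_t)$norm),
                        error = function(e) NA_real_)
    fp_n[m] <- tryCatch(max(footprint_profile(fragments, sites, cells_n)$norm),
                        error = function(e) NA_real_)
  }
  pass_fp <- !is.na(fp_t) & !is.na(fp_n) & fp_t > fp_n
  # (c) TF gene expression, tumor vs normal epithelium
  ln <- as.matrix(log_normalize(expr))
  elab <- expr$cell_meta$cell_type
  e_t <- elab == tumor_label
  e_n <- elab == normal_label
  genes <- unname(motif_genes[motifs])
  gi <- match(genes, rownames(ln))
  expr_lfc <- expr_p <- rep(NA_real_, length(motifs))
  have <- which(!is.na(gi))
  if (length(setdiff(seq_along(motifs), have))) {
    message(length(motifs) - length(have),
            " motif(s) without an expression record fail criterion (c)")
  }
  if (length(have)) {
    sub_t2 <- c(rep(TRUE, sum(e_t)), rep(FALSE, sum(e_n)))
    sub <- cbind(ln[gi[have], e_t, drop = FALSE], ln[gi[have], e_n, drop = FALSE])
    rk <- t(apply(sub, 1, rank))
    tt <- row_tie_term(sub)
    expr_p[have] <- ranksum_rows(rk, tt, sub_t2)$p
    m_in <- rowMeans(expm1(ln[gi[have], e_t, drop = FALSE]))
    m_out <- rowMeans(expm1(ln[gi[have], e_n, drop = FALSE]))
    expr_lfc[have] <- log2((m_in + 1) / (m_out + 1))
  }
  expr_fdr <- rep(NA_real_, length(motifs))
  expr_fdr[have] <- bh_adjust(expr_p[have])
  pass_expr <- !is.na(expr_fdr) & expr_fdr < fdr_max &
    !is.na(expr_lfc) & expr_lfc > logfc_min
  out <- tibble::tibble(
    motif = motifs, gene = genes,
    dev_diff = dev_diff, dev_fdr = dev_fdr, pass_deviation = pass_dev,
    fp_max_tumor = fp_t, fp_max_normal = fp_n, pass_footprint = pass_fp,
    expr_log2_fc = expr_lfc, expr_fdr = expr_fdr, pass_expression = pass_expr,
    selected = pass_dev & pass_fp & pass_expr
  )
  dplyr::arrange(out, dplyr::desc(.data$selected), dplyr::desc(.data$dev_diff))
}
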