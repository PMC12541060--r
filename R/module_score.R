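#' Expression-bin-controlled module score
#'
#' Per-cell score of a gene set against expression-matched controls: genes
#' are binned by average expression into `n_bins` equal-occupancy bins; for
#' every gene of the set, `n_ctrl` control genes are drawn from its bin
#' (without replacement when the bin is large enough); the score is the
#' mean expression of the set minus the mean expression of the pooled
#' control genes, per cell.
#'
#' @param values genes x cells matrix of log-normalized expression (dense or
#'   sparse, with gene row names), or an `expression_matrix` (log-normalized
#'   internally).
#' @param gene_set character vector of gene names; genes absent from the
#'   matrix are ignored (error if none remain).
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed RNG seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(values, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  if (inherits(values, "expression_matrix")) values <- log_normalize(values)
  genes <- rownames(values)
  if (is.null(genes)) stop("values must have gene row names")
  set <- intersect(gene_set, genes)
  if (!length(set)) stop("no gene of the set is present in the matrix")
  set.seed(seed)
  avg <- row_totals(values) / ncol(values)
  n_bins <- min(n_bins, length(avg))
  bins <- dplyr::ntile(avg, n_bins)
  names(bins) <- genes
  ctrl <- character(0)
  for (g in set) {
    pool <- genes[bins == bins[g]]
    pool <- setdiff(pool, g)
    if (!length(pool)) next
    ctrl <- c(ctrl, if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
              else sample(pool, n_ctrl, replace = TRUE))
  }
  set_mean <- col_totals(values[set, , drop = FALSE]) / length(set)
  ctrl_mean <- if (length(ctrl)) {
    # control genes keep their sampling multiplicity
    idx <- match(ctrl, genes)
    col_totals(values[idx, , drop = FALSE]) / length(ctrl)
  } else rep(0, ncol(values))
  out <- set_mean - ctrl_mean
  names(out) <- colnames(values)
  out
}
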