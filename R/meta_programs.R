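#' Cross-sample meta-programs from per-sample NMF fits
#'
#' Every program (from any sample) is represented by its top-gene signature
#' and scored in every sample's tumor cells with the bin-controlled module
#' score, so programs from different samples are comparable. Within each
#' sample the Pearson correlations of all program score vectors are
#' computed, correlation matrices are averaged across samples, and the
#' programs are clustered by Ward linkage on `1 - average correlation`.
#' The number of clusters is chosen to maximize the mean silhouette width.
#' Clusters whose member programs cover less than `coverage_fraction` of
#' the samples are disregarded. Each retained cluster's meta-program
#' signature is the `top_n` genes with the highest average (max-scaled)
#' NMF score over its member programs.
#'
#' @param fits named list of `nmf_result` objects, one per sample.
#' @param expr_by_sample named list of log-normalized genes x cells
#'   matrices of the same samples' tumor cells.
#' @param coverage_fraction minimum fraction of samples a cluster must
#'   cover.
#' @param top_n signature size.
#' @param n_bins,n_ctrl,seed module-score controls.
#' @return `meta_program_set`: list with `members` (tibble `meta_program`,
#'   `sample`, `program`), `signatures` (tibble `meta_program`, `gene`,
#'   `avg_score`, `rank`), `avg_cor`, `n_clusters`, `dropped` (tibble of
#'   disregarded clusters).
#' @export
meta_programs <- function(fits, expr_by_sample, coverage_fraction = 0.5,
                          top_n = 100, n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)),
            all(names(fits) %in% names(expr_by_sample)))
  samples <- names(fits)
  prog <- tibble::tibble(
    sample = rep(samples, vapply(fits, function(f) as.integer(f$k), 1L)),
    program = unlist(lapply(fits, function(f) seq_len(f$k)), use.names = FALSE)
  )
  prog$id <- paste0(prog$sample, "|p", prog$program)
  n_prog <- nrow(prog)
  if (n_prog < 3) stop("need at least 3 programs to cluster")
  gene_sets <- lapply(seq_len(n_prog), function(i)
    program_signature(fits[[prog$sample[i]]], prog$program[i], top_n)$gene)
  # per-sample correlation of program module scores
  cors <- array(NA_real_, c(n_prog, n_prog, length(samples)))
  for (s in seq_along(samples)) {
    vals <- expr_by_sample[[samples[s]]]
    scores <- vapply(gene_sets, function(gs)
      module_score(vals, gs, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
      numeric(ncol(vals)))
    cs <- suppressWarnings(cor(scores))
    cors[, , s] <- cs
  }
  avg_cor <- apply(cors, c(1, 2), mean, na.rm = TRUE)
  avg_cor[is.nan(avg_cor)] <- 0
  diag(avg_cor) <- 1
  dimnames(avg_cor) <- list(prog$id, prog$id)
  d <- as.dist(1 - avg_cor)
  hc <- hclust(d, method = "ward.D2")
  sil_for <- function(k) {
    cl <- cutree(hc, k)
    mean(silhouette_widths(cl, as.matrix(d)))
  }
  kcand <- 2:(n_prog - 1)
  sil <- vapply(kcand, sil_for, numeric(1))
  n_clusters <- kcand[which.max(sil)]
  cl <- cutree(hc, n_clusters)
  keep <- members <- sigs <- list()
  dropped <- list()
  mp <- 0
  for (g in sort(unique(cl))) {
    ids <- which(cl == g)
    cov <- length(unique(prog$sample[ids])) / length(samples)
    if (cov < coverage_fraction) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        cluster = g, programs = paste(prog$id[ids], collapse = ","),
        coverage = cov)
      next
    }
    mp <- mp + 1
    members[[mp]] <- tibble::tibble(meta_program = mp,
                                    sample = prog$sample[ids],
                                    program = prog$program[ids])
    # average max-scaled NMF scores over member programs
    acc <- NULL
    for (i in ids) {
      w <- fits[[prog$sample[i]]]$W[, prog$program[i]]
      w <- w / max(w)
      acc <- if (is.null(acc)) w else acc + w[names(acc)]
    }
    acc <- acc / length(ids)
    ord <- order(-acc, names(acc))[seq_len(min(top_n, length(acc)))]
    sigs[[mp]] <- tibble::tibble(meta_program = mp, gene = names(acc)[ord],
                                 avg_score = unname(acc[ord]),
                                 rank = seq_along(ord))
  }
  if (!mp) warning("every cluster was dropped by the coverage rule")
  structure(list(
    members = if (mp) dplyr::bind_rows(members) else tibble::tibble(),
    signatures = if (mp) dplyr::bind_rows(sigs) else tibble::tibble(),
    avg_cor = avg_cor, n_clusters = n_clusters,
    dropped = if (length(dropped)) dplyr::bind_rows(dropped) else tibble::tibble()),
    class = "meta_program_set")
}

# mean silhouette helper on a precomputed distance matrix
silhouette_widths <- function(cl, dmat) {
  n <- length(cl)
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(dmat[i, own & seq_len(n) != i]) else 0
    bs <- vapply(setdiff(unique(cl), cl[i]),
                 function(g) mean(dmat[i, cl == g]), numeric(1))
    b <- min(bs)
    out[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  out
}

#' @exportS3Method base::print
print.meta_program_set <- function(x, ...) {
  n_mp <- length(unique(x$members$meta_program))
  cat("meta_program_set: ", n_mp, " meta-programs from ",
      x$n_clusters, " clusters\n", sep = "")
  invisible(x)
}

#' Heatmap of average program-program correlations
#' @param object `meta_program_set`.
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.meta_program_set <- function(object, ...) {
  m <- object$avg_cor
  df <- tibble::tibble(
    a = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    b = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    cor = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$cor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "avg r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
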