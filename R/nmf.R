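#' Per-sample relative expression matrices of tumor cells
#'
#' For every sample with more than `min_cells` tumor cells, the tumor
#' cells' log-normalized expression is centered per gene across the
#' sample's tumor cells and negative values are set to zero, giving the
#' nonnegative input for program factorization. Samples at or below the
#' cell gate are skipped with a message.
#'
#' @param expr `expression_matrix` with `cell_meta` columns `sample` and
#'   `cell_type`.
#' @param min_cells strict lower bound on tumor cells per sample.
#' @param tumor_label cell-type label identifying tumor cells.
#' @return named list of dense nonnegative genes x cells matrices.
#' @export
relative_expression <- function(expr, min_cells = 500, tumor_label = "tumor") {
  meta <- expr$cell_meta
  stopifnot(all(c("sample", "cell_type") %in% names(meta)))
  ln <- log_normalize(expr)
  out <- list()
  for (s in unique(meta$sample)) {
    idx <- which(meta$sample == s & meta$cell_type == tumor_label)
    if (length(idx) <= min_cells) {
      message("sample ", s, ": ", length(idx),
              " tumor cells (<= ", min_cells, "), skipped")
      next
    }
    m <- as.matrix(ln[, idx, drop = FALSE])
    m <- m - rowMeans(m)
    m[m < 0] <- 0
    out[[s]] <- m
  }
  if (!length(out)) stop("no sample exceeds the tumor-cell gate")
  out
}

# One KL-divergence (Brunet) multiplicative-update NMF run. Following the
# original consensus-NMF recipe, a run stops once the connectivity
# structure (argmax-H cluster assignment) has been stable for
# `stable_checks` consecutive checks (every 10 iterations), rather than at
# full numerical convergence; this keeps restarts diverse when the rank
# does not match the data.
nmf_kl <- function(V, k, max_iter = 300, tol = 1e-6, seed = 1, eps = 1e-10,
                   stable_checks = 4) {
  if (any(V < 0)) stop("NMF input must be nonnegative")
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  fit <- .nmf_kl_cpp(V, W, H, max_iter = max_iter, tol = tol,
                     stable_checks = stable_checks, eps = eps)
  fit$cluster <- fit$cluster + 1L  # 0-based factor indices from C++
  fit
}

#' Consensus NMF of one sample
#'
#' Runs multiplicative-update NMF (KL divergence) `nrun` times from
#' distinct sub-seeds, records in the consensus matrix the fraction of runs
#' in which each cell pair shares the argmax-H cluster, and summarizes
#' clustering robustness by the cophenetic coefficient: the Pearson
#' correlation between consensus distances (1 - consensus) and the
#' cophenetic distances of their average-linkage dendrogram. The run with
#' the best objective supplies `W` and `H`.
#'
#' @param V nonnegative genes x cells matrix (no all-zero rows are used in
#'   the factorization).
#' @param k factorization rank.
#' @param nrun number of restarts.
#' @param max_iter,tol per-run convergence controls.
#' @param seed master seed; run `i` uses `seed + i`.
#' @return `nmf_result`: list with `k`, `W`, `H`, `consensus`,
#'   `cophenetic`, `objective`, `seed`, `genes`.
#' @export
nmf_consensus <- function(V, k, nrun = 30, max_iter = 300, tol = 1e-6,
                          seed = 1) {
  if (any(V < 0)) stop("NMF input must be nonnegative")
  if (is.null(rownames(V))) rownames(V) <- sprintf("g%d", seq_len(nrow(V)))
  used <- rowSums(V) > 0
  Vu <- V[used, , drop = FALSE]
  m <- ncol(Vu)
  co <- matrix(0, m, m)
  best <- NULL
  for (run in seq_len(nrun)) {
    fit <- nmf_kl(Vu, k, max_iter = max_iter, tol = tol, seed = seed + run)
    co <- co + outer(fit$cluster, fit$cluster, "==")
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  co <- co / nrun
  d <- as.dist(1 - co)
  hc <- hclust(d, method = "average")
  coph <- suppressWarnings(cor(d, cophenetic(hc)))
  if (is.na(coph)) coph <- 1  # degenerate: all cells always co-cluster
  W <- matrix(0, nrow(V), k, dimnames = list(rownames(V), NULL))
  W[used, ] <- best$W
  structure(list(k = k, W = W, H = best$H, consensus = co,
                 cophenetic = coph, objective = best$objective,
                 seed = seed, genes = rownames(V)),
            class = "nmf_result")
}

#' @exportS3Method base::print
print.nmf_result <- function(x, ...) {
  cat("nmf_result: k = ", x$k, ", cophenetic = ", round(x$cophenetic, 3),
      ", KL objective = ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy NMF gene loadings
#' @param x `nmf_result`.
#' @param ... unused.
#' @return tibble with columns `gene`, `program`, `score`.
#' @export
tidy.nmf_result <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$genes, times = x$k),
    program = rep(seq_len(x$k), each = length(x$genes)),
    score = as.vector(x$W)
  )
}

#' One-row NMF fit summary
#' @param x `nmf_result`.
#' @param ... unused.
#' @return tibble with `k`, `cophenetic`, `objective`.
#' @export
glance.nmf_result <- function(x, ...) {
  tibble::tibble(k = x$k, cophenetic = x$cophenetic, objective = x$objective)
}

#' Select the factorization rank from cophenetic coefficients
#'
#' The chosen rank is the one immediately preceding the largest drop in the
#' cophenetic coefficient, with ties resolved toward the smallest rank.
#' Because the coefficients are estimated from a finite number of restarts,
#' drops within `drop_tol` of the largest drop are treated as ties of the
#' maximum, and the smallest such rank is returned (the parsimony
#' convention). When coefficients only increase, the largest rank is
#' returned with a warning.
#'
#' @param cophenetic named numeric vector of cophenetic coefficients, names
#'   being the ranks (e.g. `"2"..."6"`), in increasing rank order.
#' @param after select the rank after the drop instead (alternative
#'   reading).
#' @param drop_tol fraction of the maximum drop within which a smaller
#'   rank's drop counts as tied.
#' @return the selected rank (integer).
#' @export
select_k <- function(cophenetic, after = FALSE, drop_tol = 0.5) {
  ks <- as.integer(names(cophenetic))
  stopifnot(length(ks) >= 2, !anyNA(ks), all(diff(ks) > 0))
  drops <- cophenetic[-length(cophenetic)] - cophenetic[-1]
  if (all(drops <= 0)) {
    warning("cophenetic coefficients never decrease; returning the largest k")
    return(ks[length(ks)])
  }
  i <- which(drops >= (1 - drop_tol) * max(drops) - 1e-9)[1]
  if (after) ks[i + 1] else ks[i]
}

#' Top-gene signature of one program
#'
#' @param x `nmf_result` (or a genes x k matrix `W`).
#' @param program program (column) index.
#' @param top_n number of genes, by descending NMF score; ties broken by
#'   gene-name order.
#' @return `program_signature` tibble with columns `gene`, `score`, `rank`.
#' @export
program_signature <- function(x, program, top_n = 100) {
  W <- if (inherits(x, "nmf_result")) x$W else x
  genes <- rownames(W) %||% paste0("g", seq_len(nrow(W)))
  stopifnot(program >= 1, program <= ncol(W))
  sc <- W[, program]
  if (length(sc) < top_n) {
    warning("only ", length(sc), " genes available (top_n = ", top_n, ")")
    top_n <- length(sc)
  }
  ord <- order(-sc, genes)[seq_len(top_n)]
  out <- tibble::tibble(gene = genes[ord], score = sc[ord],
                        rank = seq_len(top_n))
  class(out) <- c("program_signature", class(out))
  out
}

#' Cophenetic-coefficient curve over candidate ranks
#' @param cophenetic named numeric vector as in [select_k()].
#' @return ggplot object with the selected rank highlighted.
#' @export
plot_cophenetic <- function(cophenetic) {
  ks <- as.integer(names(cophenetic))
  kstar <- select_k(cophenetic)
  df <- tibble::tibble(k = ks, cophenetic = as.numeric(cophenetic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$cophenetic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = kstar, linetype = 2, color = "red") +
    ggplot2::labs(x = "rank k", y = "cophenetic coefficient") +
    ggplot2::theme_minimal()
}
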