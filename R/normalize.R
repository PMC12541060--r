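#' Log-normalize a count matrix
#'
#' Per cell (column), counts are scaled to a fixed total and log-transformed:
#' `x <- log(1 + count / column_total * scale)`. Sparsity is preserved.
#'
#' @param counts sparse or dense nonnegative matrix (features x cells), or an
#'   `accessibility_matrix` / `expression_matrix` (its counts are used).
#' @param scale library-size scale factor.
#' @return matrix of the same shape (sparse if input was sparse).
#' @export
log_normalize <- function(counts, scale = 1e4) {
  if (inherits(counts, c("accessibility_matrix", "expression_matrix"))) {
    counts <- counts$counts
  }
  tot <- col_totals(counts)
  if (any(tot <= 0)) {
    stop(sum(tot <= 0), " cell(s) with zero total counts; filter before normalizing")
  }
  if (inherits(counts, "Matrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale / tot)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, tot / scale, "/"))
  }
}

#' Latent semantic indexing embedding of an accessibility matrix
#'
#' Term frequency (per-cell count fraction) is weighted by inverse document
#' frequency `log(1 + n_cells / peak_df)` and decomposed by truncated SVD.
#' All-zero peaks are excluded from the decomposition. The first component is
#' dropped when its absolute correlation with per-cell sequencing depth
#' exceeds `depth_corr_max`, as it then carries depth rather than biology.
#'
#' @param x `accessibility_matrix` or a sparse peaks x cells matrix.
#' @param n_components number of singular vectors to compute.
#' @param depth_corr_max threshold on |cor(component, depth)| above which
#'   component 1 is dropped.
#' @return numeric matrix, cells x kept components; attribute
#'   `"dropped_first"` records whether component 1 was removed.
#' @export
lsi_embedding <- function(x, n_components = 30, depth_corr_max = 0.9) {
  counts <- if (inherits(x, "accessibility_matrix")) x$counts else x
  depth <- col_totals(counts)
  if (any(depth <= 0)) stop("cells with zero counts; run QC first")
  df <- Matrix::rowSums(counts > 0)
  keep <- df > 0
  counts <- counts[keep, , drop = FALSE]
  df <- df[keep]
  n_cells <- ncol(counts)
  max_rank <- min(nrow(counts), n_cells) - 1L
  if (n_components > max_rank) {
    warning("rank-deficient input: returning ", max_rank, " components")
    n_components <- max_rank
  }
  tf <- counts %*% Matrix::Diagonal(x = 1 / depth)
  idf <- log(1 + n_cells / df)
  xw <- Matrix::Diagonal(x = idf) %*% tf
  sv <- irlba::irlba(xw, nv = n_components)
  emb <- sv$v %*% diag(sv$d, nrow = n_components)
  dropped <- FALSE
  if (abs(cor(emb[, 1], depth)) > depth_corr_max && ncol(emb) > 1) {
    emb <- emb[, -1, drop = FALSE]
    dropped <- TRUE
  }
  rownames(emb) <- colnames(counts)
  colnames(emb) <- paste0("LSI_", seq_len(ncol(emb)))
  attr(emb, "dropped_first") <- dropped
  emb
}

#' Build k-nearest-neighbor metacell groups
#'
#' Seed cells are sampled without replacement; each group is the seed plus
#' its `k - 1` nearest neighbors in the embedding. Groups whose Jaccard
#' overlap with an already accepted group exceeds `max_overlap` are
#' discarded, so accepted groups are distinct aggregates.
#'
#' @param embedding cells x dims matrix (e.g. from [lsi_embedding()]).
#' @param k cells per group.
#' @param n_groups number of seed cells to draw.
#' @param max_overlap maximum allowed Jaccard overlap between groups.
#' @param seed RNG seed for seed-cell sampling.
#' @return `metacell_map` object: list with `groups` (list of integer cell
#'   index vectors, each of length `k`), `k`, `seeds` and `barcodes`.
#' @export
make_metacells <- function(embedding, k = 50, n_groups = 200,
                           max_overlap = 0.8, seed = 1) {
  n <- nrow(embedding)
  if (n < k) stop("fewer cells (", n, ") than metacell size k = ", k)
  set.seed(seed)
  seeds <- sample.int(n, min(n_groups, n))
  # squared distances seed x cells via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  cn <- rowSums(embedding^2)
  groups <- list()
  kept_seeds <- integer()
  for (s in seeds) {
    d2 <- cn + cn[s] - 2 * drop(embedding %*% embedding[s, ])
    grp <- sort(order(d2)[seq_len(k)])
    ok <- TRUE
    for (g in groups) {
      ov <- length(intersect(g, grp))
      if (ov / (2 * k - ov) > max_overlap) { ok <- FALSE; break }
    }
    if (ok) {
      groups[[length(groups) + 1]] <- grp
      kept_seeds <- c(kept_seeds, s)
    }
  }
  structure(list(groups = groups, k = k, seeds = kept_seeds,
                 barcodes = rownames(embedding)),
            class = "metacell_map")
}

#' @exportS3Method base::print
print.metacell_map <- function(x, ...) {
  cat("metacell_map: ", length(x$groups), " groups of ", x$k, " cells\n", sep = "")
  invisible(x)
}

#' Aggregate counts over metacell groups
#'
#' Sums raw counts over the member cells of each group. Aggregated totals
#' over the covered cells are preserved exactly.
#'
#' @param x `accessibility_matrix`, `expression_matrix` or a features x cells
#'   matrix whose columns match the map's cells.
#' @param map `metacell_map` from [make_metacells()].
#' @return sparse features x groups matrix of summed counts.
#' @export
aggregate_metacells <- function(x, map) {
  counts <- if (inherits(x, c("accessibility_matrix", "expression_matrix")))
    x$counts else x
  n_groups <- length(map$groups)
  j <- rep(seq_len(n_groups), each = map$k)
  i <- unlist(map$groups)
  memb <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                               dims = c(ncol(counts), n_groups))
  out <- counts %*% memb
  colnames(out) <- paste0("mc_", seq_len(n_groups))
  methods::as(out, "CsparseMatrix")
}
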