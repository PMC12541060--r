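#' Sample GC- and accessibility-matched background peaks
#'
#' Peaks are binned on a two-dimensional equal-occupancy grid of GC content
#' by log mean accessibility; each peak draws `n_bg` background peaks from
#' its own bin (excluding itself). Bins left with a single peak fall back to
#' the nearest nonempty neighboring bin.
#'
#' @param gc per-peak GC content.
#' @param mean_accessibility per-peak mean raw accessibility.
#' @param n_bins total 2-D bin budget (the grid uses roughly
#'   `sqrt(n_bins)` equal-occupancy bins per axis, keeping per-bin pools
#'   large enough for diverse background sets).
#' @param n_bg background peaks per peak.
#' @param seed RNG seed.
#' @return integer matrix, peaks x `n_bg`, of background peak indices.
#' @export
sample_background_peaks <- function(gc, mean_accessibility, n_bins = 50,
                                    n_bg = 50, seed = 1) {
  stopifnot(length(gc) == length(mean_accessibility))
  n <- length(gc)
  set.seed(seed)
  per_axis <- max(1L, floor(sqrt(n_bins)))
  gbin <- dplyr::ntile(gc, per_axis)
  abin <- dplyr::ntile(log1p(mean_accessibility), per_axis)
  bin <- (gbin - 1L) * per_axis + abin
  members <- split(seq_len(n), bin)
  sizes <- lengths(members)
  # peaks alone in their bin borrow the nearest nonempty bin (grid distance)
  bin_ids <- as.integer(names(members))
  bg <- matrix(0L, nrow = n, ncol = n_bg)
  for (b in seq_along(members)) {
    idx <- members[[b]]
    pool <- idx
    if (length(pool) == 1) {
      gb <- (bin_ids[b] - 1L) %/% per_axis + 1L
      ab <- (bin_ids[b] - 1L) %% per_axis + 1L
      others <- setdiff(seq_along(members), b)
      og <- (bin_ids[others] - 1L) %/% per_axis + 1L
      oa <- (bin_ids[others] - 1L) %% per_axis + 1L
      dgrid <- abs(og - gb) + abs(oa - ab)
      nb <- others[which.min(dgrid)]
      pool <- c(pool, members[[nb]])
      message("background bin of size 1: borrowing ", length(members[[nb]]),
              " peaks from a neighboring bin")
    }
    for (i in idx) {
      cand <- setdiff(pool, i)
      bg[i, ] <- if (length(cand) >= n_bg) sample(cand, n_bg)
      else sample(cand, n_bg, replace = TRUE)
    }
  }
  bg
}

#' Bias-corrected motif deviation z-scores
#'
#' For each motif and cell, the observed count in motif-matched peaks is
#' compared with the expectation under the cell's depth and the peaks'
#' pooled read fractions: `E = cell_total * sum(matched peak fractions)`;
#' the raw deviation is `(obs - E) / E`. The same deviation is computed for
#' `n_bg` background peak sets matched on GC and accessibility, and the
#' z-score standardizes the raw deviation by the background mean and
#' standard deviation.
#'
#' @param counts sparse peaks x cells count matrix (QC-filtered).
#' @param matches logical/numeric peaks x motifs match matrix.
#' @param backgrounds integer peaks x n_bg background assignment from
#'   [sample_background_peaks()].
#' @return `deviation_result`: list with `raw` and `z` (motifs x cells
#'   matrices), `n_bg`, and the expectation matrix `expected`. Entries with
#'   zero expectation are `NA`.
#' @export
chromvar_deviations <- function(counts, matches, backgrounds) {
  counts <- methods::as(counts, "CsparseMatrix")
  matches <- as.matrix(matches) * 1
  stopifnot(nrow(counts) == nrow(matches),
            nrow(backgrounds) == nrow(counts))
  if (any(colSums(matches) < 1)) stop("every motif needs at least one matched peak")
  n_bg <- ncol(backgrounds)
  cell_tot <- col_totals(counts)
  frac <- row_totals(counts) / sum(cell_tot)
  obs <- as.matrix(Matrix::crossprod(matches, counts))     # motifs x cells
  expected <- outer(drop(crossprod(matches, frac)), cell_tot)
  raw <- (obs - expected) / expected
  raw[expected == 0] <- NA
  bg_sum <- matrix(0, nrow(raw), ncol(raw))
  bg_sumsq <- matrix(0, nrow(raw), ncol(raw))
  n_peaks <- nrow(counts)
  for (b in seq_len(n_bg)) {
    map <- Matrix::sparseMatrix(i = seq_len(n_peaks), j = backgrounds[, b],
                                x = 1, dims = c(n_peaks, n_peaks))
    m_b <- Matrix::crossprod(map, matches)                 # peaks x motifs
    obs_b <- as.matrix(Matrix::crossprod(m_b, counts))
    exp_b <- outer(drop(crossprod(as.matrix(m_b), frac)), cell_tot)
    dev_b <- (obs_b - exp_b) / exp_b
    dev_b[exp_b == 0] <- NA
    bg_sum <- bg_sum + dev_b
    bg_sumsq <- bg_sumsq + dev_b^2
  }
  bg_mean <- bg_sum / n_bg
  bg_sd <- sqrt(pmax(bg_sumsq / n_bg - bg_mean^2, 0) * n_bg / (n_bg - 1))
  z <- (raw - bg_mean) / bg_sd
  z[!is.finite(z)] <- NA
  dimnames(raw) <- dimnames(z) <- list(colnames(matches), colnames(counts))
  structure(list(raw = raw, z = z, expected = expected, n_bg = n_bg),
            class = "deviation_result")
}

#' @exportS3Method base::print
print.deviation_result <- function(x, ...) {
  cat("deviation_result: ", nrow(x$z), " motifs x ", ncol(x$z),
      " cells (", x$n_bg, " background sets)\n", sep = "")
  invisible(x)
}

#' Tidy motif deviations into a long tibble
#' @param x `deviation_result`.
#' @param ... unused.
#' @return tibble with columns `motif`, `cell`, `raw`, `z`.
#' @export
tidy.deviation_result <- function(x, ...) {
  tibble::tibble(
    motif = rep(rownames(x$z), times = ncol(x$z)),
    cell = rep(colnames(x$z), each = nrow(x$z)),
    raw = as.vector(x$raw),
    z = as.vector(x$z)
  )
}
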