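#' Genomic windows for co-accessibility estimation
#'
#' Tiles each chromosome with overlapping windows of width `window_size`
#' stepped by `step`, and assigns peaks to windows by their centers. With
#' the default half-window step, every peak pair whose centers lie within
#' `step` of each other shares at least one window, and no pair sharing a
#' window is farther apart than `window_size` — the maximum interaction
#' distance. Windows with fewer than two peaks are dropped.
#'
#' @param peaks region tibble.
#' @param window_size maximum interaction distance in bp.
#' @param step window step in bp.
#' @return tibble with columns `window`, `chrom`, `win_start`, `win_end` and
#'   a list-column `peak_idx` of row indices into `peaks`.
#' @export
coaccess_windows <- function(peaks, window_size = 5e5, step = window_size / 2) {
  validate_regions(peaks)
  centers <- (peaks$start + peaks$end) / 2
  out <- list()
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr)
    cc <- centers[idx]
    lo <- floor(min(cc) / step) * step
    starts <- seq(lo - step, max(cc), by = step)
    for (s in starts) {
      members <- idx[cc >= s & cc < s + window_size]
      if (length(members) >= 2) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chr, win_start = s, win_end = s + window_size,
          peak_idx = list(members))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(window = integer(), chrom = character(),
                          win_start = numeric(), win_end = numeric(),
                          peak_idx = list()))
  }
  res <- dplyr::bind_rows(out)
  res$window <- seq_len(nrow(res))
  res[, c("window", "chrom", "win_start", "win_end", "peak_idx")]
}

#' Regularized precision matrix for one window
#'
#' Runs the graphical lasso on the empirical correlation matrix of the
#' window's peaks across metacells, with an off-diagonal penalty that grows
#' linearly with genomic distance:
#' `rho_ij = distance_penalty_scale * d_ij / window_size`. The diagonal
#' penalty is a small ridge.
#'
#' @param values numeric matrix, window peaks x metacells, of log-normalized
#'   aggregated accessibility.
#' @param centers peak center coordinates (bp), one per row of `values`.
#' @param window_size maximum interaction distance (penalty denominator).
#' @param distance_penalty_scale multiplier on the distance penalty.
#' @param ridge diagonal penalty.
#' @param max_iter,tol graphical-lasso convergence controls.
#' @return precision matrix (peaks x peaks) with attribute `"kept"` giving
#'   the row indices retained (zero-variance peaks are excluded).
#' @export
window_glasso <- function(values, centers, window_size = 5e5,
                          distance_penalty_scale = 1, ridge = 0.01,
                          max_iter = 100, tol = 1e-4) {
  if (ncol(values) < 5) stop("need at least 5 metacell observations")
  v <- apply(values, 1, var)
  kept <- which(v > 0)
  if (length(kept) < 2) {
    out <- matrix(numeric(0), 0, 0)
    attr(out, "kept") <- kept
    return(out)
  }
  values <- values[kept, , drop = FALSE]
  centers <- centers[kept]
  S <- cor(t(values))
  d <- abs(outer(centers, centers, "-"))
  Rho <- distance_penalty_scale * d / window_size
  diag(Rho) <- ridge
  fit <- .glasso_cpp(S, Rho, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    stop("graphical lasso failed to converge (", fit$iterations, " iterations)")
  }
  out <- fit$omega
  attr(out, "kept") <- kept
  out
}

#' Co-accessibility scores between peak pairs
#'
#' Estimates a distance-penalized graphical lasso per window and converts
#' each precision matrix to scaled partial correlations
#' `score_ij = -omega_ij / sqrt(omega_ii * omega_jj)`. Pairs falling in
#' several windows are averaged; pairs with center distance greater than
#' `window_size` are never emitted.
#'
#' @param aggregated sparse or dense peaks x metacells matrix of aggregated
#'   counts (raw; log-normalized internally) or already-normalized values if
#'   `normalize = FALSE`.
#' @param peaks region tibble matching the rows of `aggregated`.
#' @param window_size maximum interaction distance (bp).
#' @param step window step (bp).
#' @param distance_penalty_scale distance penalty multiplier.
#' @param ridge diagonal penalty.
#' @param normalize log-normalize aggregated counts first.
#' @return tibble with columns `peak_i`, `peak_j` (peak ids, `i < j` in
#'   genomic order), `score`, `distance`, `n_windows`.
#' @export
coaccess_scores <- function(aggregated, peaks, window_size = 5e5,
                            step = window_size / 2,
                            distance_penalty_scale = 1, ridge = 0.01,
                            normalize = TRUE) {
  stopifnot(nrow(peaks) == nrow(aggregated))
  values <- if (normalize) log_normalize(aggregated) else aggregated
  values <- as.matrix(values)
  centers <- (peaks$start + peaks$end) / 2
  windows <- coaccess_windows(peaks, window_size, step)
  acc <- new.env(parent = emptyenv())
  for (w in seq_len(nrow(windows))) {
    idx <- windows$peak_idx[[w]]
    omega <- tryCatch(
      window_glasso(values[idx, , drop = FALSE], centers[idx],
                    window_size = window_size,
                    distance_penalty_scale = distance_penalty_scale,
                    ridge = ridge),
      error = function(e) stop("window ", windows$window[w], ": ",
                               conditionMessage(e)))
    kept <- idx[attr(omega, "kept")]
    if (length(kept) < 2) next
    dd <- sqrt(diag(omega))
    sc <- -omega / outer(dd, dd)
    for (a in seq_along(kept)[-length(kept)]) {
      for (b in (a + 1):length(kept)) {
        i <- kept[a]; j <- kept[b]
        if (abs(centers[i] - centers[j]) > window_size) next
        key <- paste0(i, "_", j)
        prev <- acc[[key]]
        if (is.null(prev)) acc[[key]] <- c(sc[a, b], 1)
        else acc[[key]] <- c(prev[1] + sc[a, b], prev[2] + 1)
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(tibble::tibble(peak_i = character(), peak_j = character(),
                          score = numeric(), distance = numeric(),
                          n_windows = integer()))
  }
  ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  vals <- vapply(keys, function(k) acc[[k]], numeric(2))
  res <- tibble::tibble(
    peak_i = peaks$id[i],
    peak_j = peaks$id[j],
    score = vals[1, ] / vals[2, ],
    distance = abs(centers[i] - centers[j]),
    n_windows = as.integer(vals[2, ])
  )
  dplyr::arrange(res, match(.data$peak_i, peaks$id), match(.data$peak_j, peaks$id))
}
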