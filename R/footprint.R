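#' Pseudo-bulk Tn5 footprint profile around motif sites
#'
#' Aggregates Tn5 insertion events (both fragment ends) from the cells of
#' one group over windows of +/- 250 bp around each motif site, and
#' normalizes the per-position insertion counts by the mean count in the
#' outer flanks (`flank_norm[1]` to `flank_norm[2]` bp from the center on
#' both sides). Bound transcription factors leave a central dip protected
#' from transposition, flanked by accessible DNA.
#'
#' @param fragments fragment tibble.
#' @param motif_sites tibble with columns `chrom` and `center` (0-based
#'   position of the motif center), one row per site.
#' @param cells barcodes of the pseudo-bulk group.
#' @param flank_norm two integers: inner and outer bound of the
#'   normalization flank in bp from the center.
#' @param window half-width of the profile (bp).
#' @return `footprint_profile` tibble with columns `position`
#'   (-window..window), `insertions`, `norm`; attributes `n_sites`,
#'   `n_insertions`.
#' @export
footprint_profile <- function(fragments, motif_sites, cells,
                              flank_norm = c(200, 250), window = 250) {
  if (!length(cells)) stop("empty cell set")
  if (!nrow(motif_sites)) stop("need at least one motif site")
  frag <- fragments[fragments$barcode %in% cells, , drop = FALSE]
  ins <- fragment_insertions(frag)
  prof <- numeric(2 * window + 1)
  for (chr in intersect(unique(ins$chrom), unique(motif_sites$chrom))) {
    ii <- ins[ins$chrom == chr, ]
    centers <- motif_sites$center[motif_sites$chrom == chr]
    if (!nrow(ii) || !length(centers)) next
    pts <- IRanges::IRanges(start = ii$pos + 1L, width = 1L)
    win <- IRanges::IRanges(start = centers - window + 1L,
                            end = centers + window + 1L)
    hits <- IRanges::findOverlaps(pts, win)
    if (!length(hits)) next
    off <- ii$pos[S4Vectors::queryHits(hits)] -
      centers[S4Vectors::subjectHits(hits)]
    w <- ii$count[S4Vectors::queryHits(hits)]
    acc <- tapply(w, off, sum)
    pos <- as.integer(names(acc)) + window + 1L
    prof[pos] <- prof[pos] + acc
  }
  n_ins <- sum(prof)
  positions <- -window:window
  in_flank <- abs(positions) >= flank_norm[1] & abs(positions) <= flank_norm[2]
  flank_mean <- mean(prof[in_flank])
  if (flank_mean <= 0) stop("no insertions in the normalization flanks")
  out <- tibble::tibble(position = positions, insertions = prof,
                        norm = prof / flank_mean)
  class(out) <- c("footprint_profile", class(out))
  attr(out, "n_sites") <- nrow(motif_sites)
  attr(out, "n_insertions") <- n_ins
  out
}

#' Footprint plot
#' @param object `footprint_profile` (or a named list of them, overlaid).
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.footprint_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$norm)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "distance from motif center (bp)",
                  y = "flank-normalized insertions") +
    ggplot2::theme_minimal()
}

#' Compare footprint profiles across pseudo-bulk groups
#' @param profiles named list of `footprint_profile` objects.
#' @return ggplot object with one line per group.
#' @export
plot_footprints <- function(profiles) {
  df <- dplyr::bind_rows(lapply(profiles, function(p)
    tibble::as_tibble(p[, c("position", "norm")])), .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$norm,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from motif center (bp)",
                  y = "flank-normalized insertions", color = NULL) +
    ggplot2::theme_minimal()
}
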