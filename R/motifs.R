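#' Read JASPAR-format position frequency matrices
#'
#' Parses the plain-text JASPAR format: a `>ID NAME` header line followed by
#' four rows `A [ 1 2 3 ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path PFM text file.
#' @return named list of 4 x width numeric matrices (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers found")
  out <- list()
  for (h in seq_along(heads)) {
    from <- heads[h]
    name <- sub("^>\\s*", "", lines[from])
    name <- strsplit(name, "\\s+")[[1]]
    name <- name[length(name)]  # prefer the TF name over the matrix id
    rows <- lines[(from + 1):(from + 4)]
    vals <- lapply(rows, function(l) {
      l <- sub("^[ACGTacgt]\\s*\\[?", "", l)
      l <- sub("\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(lengths(vals))
    if (length(w) != 1) stop("ragged PFM for motif ", name)
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stop("negative PFM entry for motif ", name)
    out[[name]] <- m
  }
  out
}

pfm_to_log_odds <- function(pfm, pseudocount = 0.8, background = 0.25) {
  probs <- sweep(pfm + pseudocount / 4, 2, colSums(pfm) + pseudocount, "/")
  log2(probs / background)
}

revcomp_matrix <- function(m) {
  m <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  m
}

seq_to_codes <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  match(chars, c("A", "C", "G", "T"))  # N and others -> NA
}

scan_one_strand <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes)
  if (n < w) return(-Inf)
  npos <- n - w + 1
  score <- numeric(npos)
  for (k in seq_len(w)) {
    col <- lo[, k]
    v <- col[codes[k:(k + npos - 1)]]
    v[is.na(v)] <- 0  # N scores as expectation 0
    score <- score + v
  }
  max(score)
}

#' Scan peak sequences for motif matches
#'
#' Position frequency matrices are converted to log-odds scores against a
#' uniform background; a peak matches a motif when any position on either
#' strand scores at least `score_fraction` of the motif's maximum achievable
#' log-odds. `N` bases contribute the background expectation (score 0).
#'
#' @param sequences named character vector of peak sequences over
#'   `{A, C, G, T, N}`.
#' @param motifs named list of PFMs (as from [read_jaspar_pfm()]).
#' @param score_fraction fraction of the maximum log-odds required.
#' @param pseudocount total pseudocount spread over the four bases.
#' @return logical peak-by-motif matrix (peaks in rows).
#' @export
scan_motifs <- function(sequences, motifs, score_fraction = 0.8,
                        pseudocount = 0.8) {
  stopifnot(length(motifs) > 0)
  codes <- lapply(sequences, seq_to_codes)
  out <- matrix(FALSE, nrow = length(sequences), ncol = length(motifs),
                dimnames = list(names(sequences), names(motifs)))
  for (m in seq_along(motifs)) {
    if (ncol(motifs[[m]]) < 4) stop("motif width must be >= 4")
    lo <- pfm_to_log_odds(motifs[[m]], pseudocount)
    lo_rc <- revcomp_matrix(lo)
    thr <- score_fraction * sum(apply(lo, 2, max))
    for (s in seq_along(codes)) {
      sc <- scan_one_strand(codes[[s]], lo)
      if (sc < thr) sc <- max(sc, scan_one_strand(codes[[s]], lo_rc))
      out[s, m] <- sc >= thr
    }
  }
  out
}

#' GC content of sequences
#' @param sequences character vector of DNA sequences.
#' @return numeric fraction of G/C over non-N bases.
#' @export
gc_content <- function(sequences) {
  vapply(sequences, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    known <- ch %in% c("A", "C", "G", "T")
    if (!any(known)) return(NA_real_)
    mean(ch[known] %in% c("C", "G"))
  }, numeric(1), USE.NAMES = FALSE)
}
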