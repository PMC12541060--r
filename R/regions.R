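#' Parse region id strings into a region tibble
#'
#' Regions are represented throughout the package as tibbles with columns
#' `chrom`, `start`, `end` (BED-style 0-based half-open coordinates) and a
#' stable string `id` rendered as `"chrom-start-end"`, e.g.
#' `"chr8-133320109-133321082"`.
#'
#' @param ids character vector of `"chrom-start-end"` ids.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`.
#' @export
#' @examples
#' parse_region_id("chr8-133320109-133321082")
parse_region_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)-([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed region id(s): ", paste(utils::head(ids[bad], 3), collapse = ", "))
  }
  out <- tibble::tibble(
    chrom = vapply(m, `[[`, "", 2L),
    start = as.numeric(vapply(m, `[[`, "", 3L)),
    end   = as.numeric(vapply(m, `[[`, "", 4L)),
    id    = as.character(ids)
  )
  validate_regions(out)
  out
}

#' Build region ids from coordinates
#' @param chrom,start,end vectors of chromosome, 0-based start, exclusive end.
#' @return character vector of `"chrom-start-end"` ids.
#' @export
region_id <- function(chrom, start, end) {
  sprintf("%s-%d-%d", chrom, as.integer(start), as.integer(end))
}

validate_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start < 0)) stop("negative region start coordinate")
  if (any(regions$end <= regions$start)) {
    i <- which(regions$end <= regions$start)[1]
    stop("region end <= start at row ", i)
  }
  invisible(regions)
}

#' Read a peak BED file (BED3+)
#'
#' Coordinates are interpreted as 0-based half-open, the BED convention.
#'
#' @param path BED file, tab-separated, optionally with `#` comment lines.
#' @return region tibble (`chrom`, `start`, `end`, `id`).
#' @export
read_peak_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- seq_along(keep)[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3)) {
    stop("malformed BED line ", line_no[which(nf < 3)[1]], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) stop("malformed BED line ", line_no[which(bad)[1]], ": non-numeric coordinates")
  if (any(start < 0)) stop("malformed BED line ", line_no[which(start < 0)[1]], ": negative start")
  if (any(end <= start)) stop("malformed BED line ", line_no[which(end <= start)[1]], ": end <= start")
  tibble::tibble(chrom = chrom, start = start, end = end,
                 id = region_id(chrom, start, end))
}

#' Read a peak-by-cell accessibility matrix
#'
#' Reads a MatrixMarket sparse count matrix together with its peak BED file,
#' cell barcodes and (optionally) per-cell metadata, and assembles an
#' accessibility matrix object.
#'
#' @param mtx_path MatrixMarket file, peaks in rows, cells in columns.
#' @param peaks_bed_path BED3 file with one row per matrix row.
#' @param barcodes_path one barcode per line, one line per matrix column.
#' @param meta_path optional TSV with columns `barcode`, `cell_type`,
#'   `cancer_type`, `sample`.
#' @return An `accessibility_matrix` object: list with `counts`
#'   (dgCMatrix, peaks x cells), `peaks` (region tibble), `cells`
#'   (barcodes) and `cell_meta` (tibble).
#' @export
read_peak_matrix <- function(mtx_path, peaks_bed_path, barcodes_path,
                             meta_path = NULL) {
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  peaks <- read_peak_bed(peaks_bed_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(peaks) != nrow(counts)) {
    stop("format error: BED has ", nrow(peaks), " peaks but matrix has ",
         nrow(counts), " rows")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("format error: ", length(barcodes), " barcodes but matrix has ",
         ncol(counts), " columns")
  }
  meta <- if (!is.null(meta_path)) read_cell_meta(meta_path, barcodes) else
    tibble::tibble(barcode = barcodes)
  accessibility_matrix(counts, peaks, barcodes, meta)
}

read_cell_meta <- function(meta_path, barcodes) {
  meta <- tibble::as_tibble(utils::read.delim(meta_path, stringsAsFactors = FALSE))
  if (!"barcode" %in% names(meta)) stop("format error: metadata lacks 'barcode' column")
  missing <- setdiff(barcodes, meta$barcode)
  if (length(missing)) {
    stop("format error: ", length(missing), " barcodes absent from metadata")
  }
  meta[match(barcodes, meta$barcode), , drop = FALSE]
}

#' Construct an accessibility matrix object
#' @param counts sparse nonnegative integer matrix, peaks x cells.
#' @param peaks region tibble with one row per matrix row.
#' @param cells character barcodes, one per column.
#' @param cell_meta per-cell tibble with at least a `barcode` column.
#' @export
accessibility_matrix <- function(counts, peaks, cells, cell_meta = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  validate_regions(peaks)
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  if (anyDuplicated(cells)) stop("duplicate cell barcodes")
  if (nrow(peaks) != nrow(counts) || length(cells) != ncol(counts)) {
    stop("format error: inconsistent dimensions")
  }
  if (any(counts@x < 0)) stop("negative counts")
  if (is.null(cell_meta)) cell_meta <- tibble::tibble(barcode = cells)
  rownames(counts) <- peaks$id
  colnames(counts) <- cells
  structure(list(counts = counts, peaks = peaks, cells = cells,
                 cell_meta = tibble::as_tibble(cell_meta)),
            class = "accessibility_matrix")
}

#' Construct an expression matrix object
#'
#' @param counts sparse nonnegative integer matrix, genes x cells.
#' @param genes tibble with columns `gene`, `chrom`, `tss` (0-based position
#'   of the strand-aware transcription start site) and `strand` (`+`/`-`).
#' @param cells character barcodes.
#' @param cell_meta per-cell tibble.
#' @export
expression_matrix <- function(counts, genes, cells, cell_meta = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("every gene must have exactly one TSS record")
  if (anyDuplicated(cells)) stop("duplicate cell barcodes")
  if (nrow(genes) != nrow(counts) || length(cells) != ncol(counts)) {
    stop("format error: inconsistent dimensions")
  }
  if (any(genes$tss < 0)) stop("negative TSS coordinate")
  if (any(counts@x < 0)) stop("negative counts")
  if (is.null(cell_meta)) cell_meta <- tibble::tibble(barcode = cells)
  rownames(counts) <- genes$gene
  colnames(counts) <- cells
  structure(list(counts = counts, genes = tibble::as_tibble(genes),
                 cells = cells, cell_meta = tibble::as_tibble(cell_meta)),
            class = "expression_matrix")
}

#' @exportS3Method base::print
print.accessibility_matrix <- function(x, ...) {
  cat("accessibility_matrix: ", nrow(x$counts), " peaks x ", ncol(x$counts),
      " cells (", format(Matrix::nnzero(x$counts), big.mark = ","),
      " nonzero)\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells (", format(Matrix::nnzero(x$counts), big.mark = ","),
      " nonzero)\n", sep = "")
  invisible(x)
}

#' Read a fragments file
#'
#' Tab-separated with at least five columns (chrom, start, end, barcode,
#' duplicate count) following the common 10x convention; `#`-prefixed header
#' lines are skipped.
#'
#' @param path fragment file path.
#' @return tibble with columns `chrom`, `start`, `end`, `barcode`, `count`
#'   in file order.
#' @export
read_fragments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), barcode = character(),
                          count = integer())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 5)) stop("parse error: fragment line with fewer than 5 fields")
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  count <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(start) || anyNA(end)) stop("parse error: non-integer fragment coordinates")
  if (anyNA(count) || any(count < 1)) stop("parse error: fragment count must be >= 1")
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end,
    barcode = vapply(fields, `[[`, "", 4L),
    count = count
  )
  if (any(out$start < 0)) stop("parse error: negative fragment coordinate")
  if (any(out$end <= out$start)) stop("parse error: fragment length must be positive")
  out
}

#' Write fragments to a tab-separated file
#' @param fragments fragment tibble.
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlapping pairs between two region sets
#'
#' Returns every pair of regions sharing at least `min_bp` overlapping bases.
#' A minimum of 1 bp overlap defines genomic coordinate overlap; half-open
#' abutting regions do not overlap.
#'
#' @param a,b region tibbles (`chrom`, `start`, `end`).
#' @param min_bp minimum overlap width in bases (>= 1).
#' @return tibble with columns `i`, `j` (row indices into `a` and `b`) and
#'   `overlap` (overlap width in bp).
#' @export
overlap_regions <- function(a, b, min_bp = 1) {
  stopifnot(min_bp >= 1)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), overlap = numeric()))
  }
  validate_regions(a); validate_regions(b)
  res <- vector("list", 0)
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    # half-open [start, end) -> 1-based closed [start + 1, end]
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = min_bp)
    if (length(hits) == 0) next
    qi <- ia[S4Vectors::queryHits(hits)]
    sj <- ib[S4Vectors::subjectHits(hits)]
    ov <- pmin(a$end[qi], b$end[sj]) - pmax(a$start[qi], b$start[sj])
    res[[length(res) + 1]] <- tibble::tibble(i = qi, j = sj, overlap = ov)
  }
  if (length(res) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), overlap = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$i, .data$j)
}

#' Write a peak-gene link network to a BEDPE-style TSV
#'
#' @param links tibble of peak-gene links as produced by
#'   [build_link_network()]: columns `peak`, `peak_chrom`, `peak_start`,
#'   `peak_end`, `gene`, `gene_chrom`, `tss`, `r`, `z`, `p`, `fdr`,
#'   `coaccess`, `reliable`.
#' @param path output TSV path.
#' @export
write_link_network <- function(links, path) {
  cols <- c("peak", "peak_chrom", "peak_start", "peak_end", "gene",
            "gene_chrom", "tss", "r", "z", "p", "fdr", "coaccess", "reliable")
  missing <- setdiff(cols, names(links))
  if (length(missing)) stop("links lack columns: ", paste(missing, collapse = ", "))
  out <- links[, cols]
  num <- c("r", "z", "p", "fdr", "coaccess")
  for (cn in num) out[[cn]] <- formatC(out[[cn]], digits = 8, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a link network written by [write_link_network()]
#' @param path TSV path.
#' @return link tibble.
#' @export
read_link_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tb <- tibble::as_tibble(df)
  tb$reliable <- as.logical(tb$reliable)
  tb
}
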