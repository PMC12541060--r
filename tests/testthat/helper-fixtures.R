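# Shared fixtures for the test suite. Cohorts are generated in code and
# memoized so several test files can reuse them without regenerating.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# desk-scale cohort for fast unit tests
tiny_config <- function(...) {
  args <- list(n_samples = 2, n_cancer_types = 2, cells_per_sample = 150,
               n_peaks = 300, n_genes = 80, n_motifs = 10,
               n_planted_links = 5, n_planted_programs = 2,
               program_gene_count = 15, n_planted_dars = 6,
               n_tumor_tfs = 2, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

tiny_cohort <- function() memo("tiny", simulate_cohort(tiny_config()))

# brute-force all-pairs overlap oracle
overlap_oracle <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) out[[length(out) + 1]] <- c(i, j, ov)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(i = integer(), j = integer(), overlap = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                 overlap = as.numeric(m[, 3]))
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                           seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(20:400, n, replace = TRUE)
  chrom <- sample(chroms, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + width,
                 id = region_id(chrom, start, start + width))
}

# step-up BH oracle, written directly from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exact rank-sum two-sided p by full enumeration of group-1 subsets
ranksum_enum_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(v), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# per-position naive motif scan oracle (single strand)
scan_oracle_strand <- function(seq, lo) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  w <- ncol(lo)
  if (length(codes) < w) return(-Inf)
  best <- -Inf
  for (s in seq_len(length(codes) - w + 1)) {
    sc <- 0
    for (k in seq_len(w)) {
      ck <- codes[s + k - 1]
      sc <- sc + if (is.na(ck)) 0 else lo[ck, k]
    }
    best <- max(best, sc)
  }
  best
}

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(30:80, 1), replace = TRUE),
          collapse = ""), character(1))
}
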