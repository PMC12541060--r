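#' Configuration for the synthetic paired cohort
#'
#' Defines the study conditions emulated by the generator: a multi-sample,
#' multi-cancer cohort of paired scATAC/scRNA cells spanning several cell
#' types, with planted peak-gene regulatory links, tumor-specific motif
#' activity with footprint dips, cell-type/cancer-specific accessible
#' regions, and intratumor expression programs.
#'
#' @param n_samples total samples, assigned round-robin to cancer types.
#' @param n_cancer_types number of cancer types.
#' @param cells_per_sample cells per sample.
#' @param n_peaks,n_genes,n_motifs feature counts.
#' @param n_chromosomes chromosomes the peaks are spread over.
#' @param peak_width,peak_spacing peak geometry (bp).
#' @param fraction_tumor_cells tumor fraction per sample; a fixed share of
#'   0.15 is normal epithelium and the rest is split over six stromal and
#'   immune types.
#' @param link_effect_size target grouped Pearson correlation of planted
#'   peak-gene links, in (0, 1].
#' @param n_planted_links number of planted distal peak-gene links.
#' @param n_planted_programs,program_gene_count intratumor expression
#'   programs planted in every sample's tumor cells.
#' @param tf_activity_shift accessibility (and TF-gene expression)
#'   multiplier in tumor cells for peaks matched to the true tumor motifs.
#' @param n_tumor_tfs number of true tumor-specific motifs.
#' @param n_planted_dars planted cancer-exclusive cell-type DAR peaks.
#' @param footprint_dip Tn5 insertion depletion depth at true motif sites
#'   in tumor cells, in `[0, 1]`.
#' @param sparsity,rna_sparsity target expected nonzero fraction of the
#'   ATAC and RNA count matrices.
#' @param degraded_fraction fraction of cells with diffuse (low TSS
#'   enrichment) fragment placement.
#' @param motif_match_prob per peak-motif match probability.
#' @param noise `"poisson"` for Poisson observation noise, `"none"` for the
#'   deterministic expected-count limit (counts are then non-integer and
#'   planted features carry no private stratum effects).
#' @param overdispersion gamma overdispersion of the Poisson rates
#'   (0 = pure Poisson).
#' @param seed master RNG seed.
#' @return `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 6, n_cancer_types = 3,
                              cells_per_sample = 2000, n_peaks = 2400,
                              n_genes = 600, n_motifs = 50,
                              n_chromosomes = 4, peak_width = 500,
                              peak_spacing = 50000,
                              fraction_tumor_cells = 0.4,
                              link_effect_size = 0.6, n_planted_links = 50,
                              n_planted_programs = 4,
                              program_gene_count = 100,
                              tf_activity_shift = 2, n_tumor_tfs = 5,
                              n_planted_dars = 40, footprint_dip = 0.5,
                              sparsity = 0.1, rna_sparsity = 0.15,
                              degraded_fraction = 0.05,
                              motif_match_prob = 0.03,
                              noise = c("poisson", "none"),
                              overdispersion = 0, seed = 42) {
  cfg <- list(
    n_samples = n_samples, n_cancer_types = n_cancer_types,
    cells_per_sample = cells_per_sample, n_peaks = n_peaks,
    n_genes = n_genes, n_motifs = n_motifs,
    n_chromosomes = n_chromosomes, peak_width = peak_width,
    peak_spacing = peak_spacing,
    fraction_tumor_cells = fraction_tumor_cells,
    link_effect_size = link_effect_size,
    n_planted_links = n_planted_links,
    n_planted_programs = n_planted_programs,
    program_gene_count = program_gene_count,
    tf_activity_shift = tf_activity_shift, n_tumor_tfs = n_tumor_tfs,
    n_planted_dars = n_planted_dars, footprint_dip = footprint_dip,
    sparsity = sparsity, rna_sparsity = rna_sparsity,
    degraded_fraction = degraded_fraction,
    motif_match_prob = motif_match_prob,
    noise = match.arg(noise), overdispersion = overdispersion,
    seed = seed)
  counts <- c("n_samples", "n_cancer_types", "cells_per_sample", "n_peaks",
              "n_genes", "n_motifs", "n_chromosomes", "peak_width",
              "peak_spacing")
  for (f in counts) if (cfg[[f]] < 1) stop("config error: ", f, " must be >= 1")
  if (link_effect_size <= 0 || link_effect_size > 1) {
    stop("config error: link_effect_size must lie in (0, 1]")
  }
  if (sparsity <= 0 || sparsity >= 1 || rna_sparsity <= 0 || rna_sparsity >= 1) {
    stop("config error: sparsity must lie in (0, 1)")
  }
  if (footprint_dip < 0 || footprint_dip > 1) {
    stop("config error: footprint_dip must lie in [0, 1]")
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_cell_types <- function() {
  c("tumor", "epithelial", "t_cell", "b_cell", "myeloid", "fibroblast",
    "endothelial", "plasma")
}

# latent scale magnitudes of the generative model (log scale)
sim_scales <- function() {
  list(marker_fraction = 1 / 8, marker_type = 1.35, marker_sample = 0.75,
       marker_stratum = 0.45, peak_int = 0.5, peak_type = 0.1,
       peak_sample = 0.06, peak_stratum = 0.08, gene_int = 0.5,
       gene_type = 0.05, gene_sample = 0.03,
       depth_sd = 0.3, dar_effect = 1.5, program_effect = 1.0,
       program_free = 0.2,
       shoulder_sd = 60)
}

# loading on the shared per-(sample, cell-type) latent that yields the
# target grouped correlation rho, given analytic metacell-level noise
# variances on the ATAC and RNA side
link_loading <- function(rho, nu_a, nu_g) {
  if (rho >= 1) return(Inf)
  r2 <- rho^2
  b2 <- (r2 * (nu_a + nu_g) +
           sqrt(r2^2 * (nu_a + nu_g)^2 + 4 * (1 - r2) * r2 * nu_a * nu_g)) /
    (2 * (1 - r2))
  sqrt(b2)
}

#' Simulate a paired scATAC/scRNA cohort with planted ground truth
#'
#' Cells belong to (sample x cell type) strata. Every peak and gene carries
#' small log-normal cell-type and sample effects, which collectively drive
#' the LSI separation that makes metacells stratum-pure. Planted peak-gene
#' links act through a per-stratum latent factor shared by the distal peak,
#' the gene and the gene's promoter peak, with the loading calibrated so
#' the grouped Pearson correlation has expectation close to
#' `link_effect_size`. Tumor cells multiply the accessibility of peaks
#' matched to the true tumor motifs by `tf_activity_shift` and carry a
#' synthetic footprint dip (and shoulder) in fragments at those motif
#' sites; each sample's tumor cells mix `n_planted_programs` nonnegative
#' expression programs. Non-planted peak-gene pairs are conditionally
#' independent given the stratum structure.
#'
#' @param config `simulation_config`.
#' @return `sim_cohort` list: `atac` (accessibility_matrix), `rna`
#'   (expression_matrix), `fragments` (tibble), `matches` (peak x motif
#'   logical matrix), `motif_sites` (tibble `motif`, `chrom`, `center`,
#'   `peak`), `truth` (list of truth tables), `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sc <- sim_scales()
  deterministic <- config$noise == "none"
  types <- sim_cell_types()
  n_types <- length(types)

  ## --- cohort layout -------------------------------------------------
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  cancers <- sprintf("cancer_%s", LETTERS[seq_len(config$n_cancer_types)])
  sample_cancer <- cancers[(seq_len(config$n_samples) - 1) %%
                             config$n_cancer_types + 1]
  frac <- c(config$fraction_tumor_cells, 0.15,
            rep((1 - config$fraction_tumor_cells - 0.15) / 6, 6))
  n_cells <- config$n_samples * config$cells_per_sample
  cell_sample <- rep(samples, each = config$cells_per_sample)
  per_type <- round(frac * config$cells_per_sample)
  per_type[1] <- config$cells_per_sample - sum(per_type[-1])
  cell_type <- rep(rep(types, per_type), config$n_samples)
  barcodes <- sprintf("%s_cell%04d", cell_sample,
                      unlist(lapply(seq_len(config$n_samples),
                                    function(i) seq_len(config$cells_per_sample))))
  cell_cancer <- sample_cancer[match(cell_sample, samples)]
  degraded <- runif(n_cells) < config$degraded_fraction
  meta <- tibble::tibble(barcode = barcodes, cell_type = cell_type,
                         cancer_type = cell_cancer, sample = cell_sample,
                         degraded = degraded)
  stratum <- paste(cell_sample, cell_type, sep = "|")
  strata <- unique(stratum)

  ## --- genome layout -------------------------------------------------
  per_chrom <- ceiling(config$n_peaks / config$n_chromosomes)
  chrom <- paste0("chr", rep(seq_len(config$n_chromosomes), each = per_chrom))
  chrom <- chrom[seq_len(config$n_peaks)]
  pos_in_chrom <- unlist(lapply(rle(chrom)$lengths, seq_len))
  start <- 10000 + (pos_in_chrom - 1) * config$peak_spacing
  peaks <- tibble::tibble(chrom = chrom, start = start,
                          end = start + config$peak_width,
                          id = region_id(chrom, start, start + config$peak_width))
  centers <- (peaks$start + peaks$end) / 2

  if (config$n_genes > config$n_peaks) {
    stop("config error: need at least as many peaks as genes (promoters)")
  }
  # promoter peaks evenly spread along the genome
  prom_idx <- sort(unlist(lapply(split(seq_len(config$n_peaks), chrom),
                                 function(ix) ix[round(seq(1, length(ix),
                                   length.out = min(length(ix),
                                     ceiling(config$n_genes / config$n_chromosomes))))])))
  prom_idx <- prom_idx[seq_len(min(config$n_genes, length(prom_idx)))]
  n_genes <- length(prom_idx)
  if (n_genes < config$n_genes) stop("config error: cannot place all genes")
  gene_names <- c(sprintf("TF%02d", seq_len(config$n_motifs)),
                  sprintf("gene%04d", seq_len(max(0, n_genes - config$n_motifs))))
  gene_names <- gene_names[seq_len(n_genes)]
  # shuffle so TF genes sit at random genomic positions
  gene_names <- sample(gene_names)
  genes <- tibble::tibble(gene = gene_names,
                          chrom = peaks$chrom[prom_idx],
                          tss = round(centers[prom_idx]),
                          strand = sample(c("+", "-"), n_genes, replace = TRUE),
                          promoter_peak = peaks$id[prom_idx],
                          promoter_idx = prom_idx)

  ## --- marker peaks ---------------------------------------------------
  # strongly stratum-structured lineage-marker peaks, chosen before motif
  # matching so motif sets stay free of the identity axis
  n_marker <- round(sim_scales()$marker_fraction * config$n_peaks)
  marker_idx <- sample(setdiff(seq_len(config$n_peaks), prom_idx), n_marker)
  is_marker <- seq_len(config$n_peaks) %in% marker_idx

  ## --- motifs and matches --------------------------------------------
  motifs <- sprintf("TF%02d", seq_len(config$n_motifs))
  matches <- matrix(runif(config$n_peaks * config$n_motifs) <
                      config$motif_match_prob,
                    config$n_peaks, config$n_motifs,
                    dimnames = list(peaks$id, motifs))
  matches[is_marker, ] <- FALSE
  for (m in seq_len(config$n_motifs)) {  # ensure a workable match count
    short <- 10 - sum(matches[, m])
    if (short > 0) {
      matches[sample(which(!matches[, m] & !is_marker), short), m] <- TRUE
    }
  }
  jitter <- round(runif(config$n_peaks * config$n_motifs, -100, 100))
  site_mat <- matrix(round(centers), config$n_peaks, config$n_motifs) + jitter
  sel <- which(matches)
  motif_sites <- tibble::tibble(
    motif = motifs[(sel - 1) %/% config$n_peaks + 1],
    peak = peaks$id[(sel - 1) %% config$n_peaks + 1],
    chrom = peaks$chrom[(sel - 1) %% config$n_peaks + 1],
    center = site_mat[sel])
  true_tfs <- sort(sample(motifs, min(config$n_tumor_tfs, config$n_motifs)))
  tf_peak <- rowSums(matches[, true_tfs, drop = FALSE]) > 0

  ## --- planted links -------------------------------------------------
  gene_class <- rep("null", n_genes)
  gene_class[genes$gene %in% motifs] <- "tf"
  free_genes <- which(gene_class == "null")
  # program genes: disjoint sets drawn from free genes
  need_prog <- config$n_planted_programs * config$program_gene_count
  if (need_prog + config$n_planted_links > length(free_genes)) {
    stop("config error: not enough genes for programs and links")
  }
  prog_genes_idx <- sample(free_genes, need_prog)
  gene_class[prog_genes_idx] <- "program"
  program_of_gene <- rep(NA_integer_, n_genes)
  program_of_gene[prog_genes_idx] <- rep(seq_len(config$n_planted_programs),
                                         each = config$program_gene_count)
  link_candidates <- which(gene_class == "null")
  # distal peak 30-200 kb from the TSS, not a promoter, not TF-shifted
  link_genes <- integer(0)
  link_peaks_idx <- integer(0)
  if (config$n_planted_links > 0) {
    cand <- sample(link_candidates)
    used_peaks <- rep(FALSE, config$n_peaks)
    used_peaks[prom_idx] <- TRUE
    for (g in cand) {
      if (length(link_genes) >= config$n_planted_links) break
      d <- abs(centers - genes$tss[g])
      ok <- which(peaks$chrom == genes$chrom[g] & d >= 30000 & d <= 120000 &
                    !used_peaks & !tf_peak & !is_marker)
      if (!length(ok)) next
      pk <- ok[sample.int(length(ok), 1)]
      used_peaks[pk] <- TRUE
      link_genes <- c(link_genes, g)
      link_peaks_idx <- c(link_peaks_idx, pk)
    }
    if (length(link_genes) < config$n_planted_links) {
      stop("config error: only ", length(link_genes),
           " plantable links; reduce n_planted_links or widen the genome")
    }
  }

  ## --- planted DARs --------------------------------------------------
  free_peaks <- setdiff(which(!tf_peak & !is_marker),
                        c(prom_idx, link_peaks_idx))
  if (config$n_planted_dars > length(free_peaks)) {
    stop("config error: not enough free peaks for planted DARs")
  }
  dar_peaks_idx <- sample(free_peaks, config$n_planted_dars)
  free_peaks <- setdiff(free_peaks, dar_peaks_idx)
  dar_type <- sample(types, config$n_planted_dars, replace = TRUE)
  dar_cancer <- sample(cancers, config$n_planted_dars, replace = TRUE)

  ## --- ATAC rates -----------------------------------------------------
  peak_int <- rnorm(config$n_peaks, 0, sc$peak_int)
  # marker peaks carry strong stratum structure (they drive the LSI
  # embedding, like lineage marker regions in real data); the remaining
  # peaks are close to noise at the metacell level
  type_sd <- ifelse(is_marker, sc$marker_type, sc$peak_type)
  sample_sd <- ifelse(is_marker, sc$marker_sample, sc$peak_sample)
  strat_sd <- ifelse(is_marker, sc$marker_stratum, sc$peak_stratum)
  peak_type_eff <- matrix(rnorm(config$n_peaks * n_types, 0, type_sd),
                          config$n_peaks, n_types, dimnames = list(NULL, types))
  peak_sample_eff <- matrix(rnorm(config$n_peaks * config$n_samples, 0,
                                  sample_sd),
                            config$n_peaks, config$n_samples,
                            dimnames = list(NULL, samples))
  depth <- rlnorm(n_cells, 0, sc$depth_sd)
  rna_depth <- rlnorm(n_cells, 0, sc$depth_sd)
  if (deterministic) depth <- rna_depth <- rep(1, n_cells)

  # analytic metacell-level noise for the link-loading calibration
  mu_a <- 50 * -log(1 - config$sparsity)
  mu_g <- 50 * -log(1 - config$rna_sparsity)
  nu_a <- sc$peak_type^2 + sc$peak_sample^2 + sc$peak_stratum^2 + 1 / mu_a
  nu_g <- sc$gene_type^2 + sc$gene_sample^2 + 1 / mu_g
  beta <- link_loading(config$link_effect_size, nu_a, nu_g)
  # k-NN metacells mix samples within a cell type, attenuating the shared
  # stratum latent; compensate with a fixed mixing factor
  beta <- beta / sqrt(0.6)

  # per-link latent over (sample, cell-type) strata
  n_links <- length(link_genes)
  u <- matrix(rnorm(n_links * length(strata)), n_links, length(strata),
              dimnames = list(NULL, strata))
  cell_stratum_idx <- match(stratum, strata)

  type_idx <- match(cell_type, types)
  sample_idx <- match(cell_sample, samples)
  # patient-by-cell-type regulatory variation: every peak gets its own
  # per-stratum effect, giving the null correlation structure a high
  # effective dimension
  peak_strat_eff <- matrix(rnorm(config$n_peaks * length(strata), 0,
                                 strat_sd),
                           config$n_peaks, length(strata))
  log_rate_a <- matrix(peak_int, config$n_peaks, n_cells) +
    peak_type_eff[, type_idx] + peak_sample_eff[, sample_idx] +
    peak_strat_eff[, cell_stratum_idx]
  # tumor motif-activity shift
  is_tumor <- cell_type == "tumor"
  if (any(tf_peak) && config$tf_activity_shift != 1) {
    log_rate_a[tf_peak, is_tumor] <- log_rate_a[tf_peak, is_tumor] +
      log(config$tf_activity_shift)
  }
  # planted DARs
  for (i in seq_along(dar_peaks_idx)) {
    on <- cell_type == dar_type[i] & cell_cancer == dar_cancer[i]
    log_rate_a[dar_peaks_idx[i], on] <- log_rate_a[dar_peaks_idx[i], on] +
      sc$dar_effect
  }
  # planted link latents on the distal and promoter peak
  if (n_links) {
    b_use <- if (deterministic) 1 else beta
    ucell <- u[, cell_stratum_idx, drop = FALSE]
    if (deterministic) {
      # deterministic limit: planted rows are pure latent + intercept
      log_rate_a[link_peaks_idx, ] <- matrix(peak_int[link_peaks_idx],
                                             n_links, n_cells) + b_use * ucell
      log_rate_a[prom_idx[link_genes], ] <-
        matrix(peak_int[prom_idx[link_genes]], n_links, n_cells) + b_use * ucell
    } else {
      log_rate_a[link_peaks_idx, ] <- log_rate_a[link_peaks_idx, ] + b_use * ucell
      log_rate_a[prom_idx[link_genes], ] <-
        log_rate_a[prom_idx[link_genes], ] + b_use * ucell
    }
  }
  rate_a <- exp(sweep(log_rate_a, 2, log(depth), "+"))
  rm(log_rate_a)
  rate_a <- rate_a * sparsity_scale(rate_a, config$sparsity)
  atac_counts <- draw_counts(rate_a, config)
  # per-peak GC content: in real data GC tracks accessibility bias, so the
  # strongly structured marker peaks occupy a distinct GC range and
  # background matching on (GC, mean accessibility) pairs like with like
  peaks$gc <- pmin(pmax(0.5 + 0.08 * is_marker +
                          rnorm(config$n_peaks, 0, 0.015), 0.3), 0.7)
  atac <- accessibility_matrix(atac_counts, peaks, barcodes, meta)
  rm(atac_counts)

  ## --- RNA rates ------------------------------------------------------
  gene_int <- rnorm(n_genes, 0, sc$gene_int)
  gene_type_eff <- matrix(rnorm(n_genes * n_types, 0, sc$gene_type),
                          n_genes, n_types)
  gene_sample_eff <- matrix(rnorm(n_genes * config$n_samples, 0,
                                  sc$gene_sample), n_genes, config$n_samples)
  log_rate_g <- matrix(gene_int, n_genes, n_cells) +
    gene_type_eff[, type_idx] + gene_sample_eff[, sample_idx]
  # TF gene expression shift in tumor cells
  tf_gene_rows <- match(true_tfs, genes$gene)
  if (config$tf_activity_shift != 1) {
    log_rate_g[tf_gene_rows, is_tumor] <- log_rate_g[tf_gene_rows, is_tumor] +
      log(config$tf_activity_shift)
  }
  # intratumor programs
  membership <- rep(NA_integer_, n_cells)
  if (config$n_planted_programs > 0) {
    membership[is_tumor] <- sample.int(config$n_planted_programs,
                                       sum(is_tumor), replace = TRUE)
    # a fifth of tumor cells stay outside every program (transitional or
    # cycling cells); within a program, cells are exchangeable up to a
    # small intensity jitter, so factorizations beyond the true rank can
    # only chase the unstructured cells and destabilize
    free_cells <- which(is_tumor & runif(n_cells) < sc$program_free)
    membership[free_cells] <- NA
    intensity <- runif(n_cells, 0.95, 1.05)
    for (p in seq_len(config$n_planted_programs)) {
      rows <- which(program_of_gene == p)
      on <- which(!is.na(membership) & membership == p)
      if (length(rows) && length(on)) {
        log_rate_g[rows, on] <- log_rate_g[rows, on] +
          sc$program_effect * rep(intensity[on], each = length(rows))
      }
    }
  }
  # planted link effect on gene expression
  if (n_links) {
    b_use <- if (deterministic) 1 else beta
    ucell <- u[, cell_stratum_idx, drop = FALSE]
    if (deterministic) {
      log_rate_g[link_genes, ] <- matrix(gene_int[link_genes], n_links,
                                         n_cells) + b_use * ucell
    } else {
      log_rate_g[link_genes, ] <- log_rate_g[link_genes, ] + b_use * ucell
    }
  }
  rate_g <- exp(sweep(log_rate_g, 2, log(rna_depth), "+"))
  rm(log_rate_g)
  rate_g <- rate_g * sparsity_scale(rate_g, config$rna_sparsity)
  rna_counts <- draw_counts(rate_g, config)
  rm(rate_g)
  rna <- expression_matrix(rna_counts,
                           genes[, c("gene", "chrom", "tss", "strand")],
                           barcodes, meta)
  rm(rna_counts)

  ## --- fragments ------------------------------------------------------
  fragments <- simulate_fragments(atac, meta, matches, motif_sites,
                                  true_tfs, config, sc)

  truth <- list(
    true_links = tibble::tibble(
      peak = peaks$id[link_peaks_idx], gene = genes$gene[link_genes],
      promoter_peak = genes$promoter_peak[link_genes],
      effect = config$link_effect_size),
    true_tumor_tfs = tibble::tibble(motif = true_tfs),
    true_programs = tidyr::crossing(
      sample = samples,
      tibble::tibble(program = program_of_gene[prog_genes_idx],
                     gene = genes$gene[prog_genes_idx])),
    true_dars = tibble::tibble(peak = peaks$id[dar_peaks_idx],
                               cell_type = dar_type,
                               cancer_type = dar_cancer),
    degraded_cells = barcodes[degraded]
  )
  structure(list(atac = atac, rna = rna, fragments = fragments,
                 matches = matches, motif_sites = motif_sites,
                 genes = genes, truth = truth, config = config),
            class = "sim_cohort")
}

# scalar multiplier making the expected nonzero fraction of Poisson counts
# with the given rates match the target sparsity (estimated on a subsample)
sparsity_scale <- function(rates, target) {
  v <- as.vector(rates)
  if (length(v) > 2e5) v <- v[round(seq(1, length(v), length.out = 2e5))]
  f <- function(s) mean(exp(-s * v)) - (1 - target)
  uniroot(f, lower = 1e-8, upper = 1e6, tol = 1e-6)$root
}

draw_counts <- function(rates, config) {
  if (config$noise == "none") return(Matrix::Matrix(rates, sparse = TRUE))
  if (config$overdispersion > 0) {
    shape <- 1 / config$overdispersion
    rates <- rates * matrix(rgamma(length(rates), shape, shape),
                            nrow(rates), ncol(rates))
  }
  counts <- rpois(length(rates), as.vector(rates))
  Matrix::Matrix(matrix(counts, nrow(rates), ncol(rates)), sparse = TRUE)
}

simulate_fragments <- function(atac, meta, matches, motif_sites, true_tfs,
                               config, sc) {
  tr <- Matrix::summary(atac$counts)
  p_idx <- rep(tr$i, tr$x)
  c_idx <- rep(tr$j, tr$x)
  n_frag <- length(p_idx)
  peaks <- atac$peaks
  pstart <- peaks$start[p_idx]
  pend <- peaks$end[p_idx]
  bc <- atac$cells[c_idx]
  is_tumor <- meta$cell_type[c_idx] == "tumor"
  is_degraded <- meta$degraded[c_idx]
  tf_peak <- rowSums(matches[, true_tfs, drop = FALSE]) > 0
  in_tf_peak <- tf_peak[p_idx]
  # primary site per peak for shoulder placement (first true-TF site)
  site_of_peak <- rep(NA_real_, nrow(peaks))
  ts <- motif_sites[motif_sites$motif %in% true_tfs, , drop = FALSE]
  first <- !duplicated(ts$peak)
  site_of_peak[match(ts$peak[first], peaks$id)] <- ts$center[first]
  mid <- runif(n_frag, pstart, pend)
  shoulder <- is_tumor & in_tf_peak & !is_degraded &
    !is.na(site_of_peak[p_idx]) & runif(n_frag) < 0.5
  if (any(shoulder)) {
    mid[shoulder] <- rnorm(sum(shoulder), site_of_peak[p_idx][shoulder],
                           sc$shoulder_sd)
    mid[shoulder] <- pmin(pmax(mid[shoulder], pstart[shoulder]),
                          pend[shoulder])
  }
  if (any(is_degraded)) {
    mid[is_degraded] <- runif(sum(is_degraded), pstart[is_degraded] - 1000,
                              pend[is_degraded] + 1000)
  }
  len <- ifelse(runif(n_frag) < 0.75,
                pmax(round(rnorm(n_frag, 75, 15)), 25),
                pmax(round(rnorm(n_frag, 210, 25)), 150))
  start <- pmax(round(mid - len / 2), 0)
  frags <- tibble::tibble(chrom = peaks$chrom[p_idx], start = start,
                          end = start + len, barcode = bc,
                          count = 1L)
  if (config$footprint_dip > 0 && nrow(ts)) {
    frags <- plant_footprint(frags, ts, config$footprint_dip,
                             barcodes = atac$cells[meta$cell_type == "tumor"])
  }
  frags[order(frags$chrom, frags$start, frags$end, frags$barcode), ]
}

#' Deplete Tn5 insertions at motif sites (footprint planting)
#'
#' For the given cells, every fragment end falling within +/- 10 bp of a
#' site center is relocated outside the protected zone with probability
#' `dip_depth`, scaling the insertion probability in the zone by
#' `1 - dip_depth` while conserving the total number of insertions.
#'
#' @param fragments fragment tibble.
#' @param motif_sites tibble with `chrom` and `center` columns.
#' @param dip_depth depletion depth in `[0, 1]`.
#' @param barcodes cells the footprint applies to (default: all).
#' @param zone protected half-width (bp).
#' @return modified fragment tibble.
#' @export
plant_footprint <- function(fragments, motif_sites, dip_depth,
                            barcodes = NULL, zone = 10) {
  stopifnot(dip_depth >= 0, dip_depth <= 1)
  if (dip_depth == 0 || !nrow(motif_sites) || !nrow(fragments)) {
    return(fragments)
  }
  active <- if (is.null(barcodes)) rep(TRUE, nrow(fragments))
  else fragments$barcode %in% barcodes
  for (side in c("start", "end")) {
    pos <- if (side == "start") fragments$start else fragments$end - 1
    hit_site <- rep(NA_real_, nrow(fragments))
    for (chr in unique(motif_sites$chrom)) {
      cs <- motif_sites$center[motif_sites$chrom == chr]
      on_chr <- which(fragments$chrom == chr & active)
      if (!length(on_chr)) next
      pts <- IRanges::IRanges(start = pos[on_chr] + 1L, width = 1L)
      win <- IRanges::IRanges(start = cs - zone + 1L, end = cs + zone + 1L)
      hits <- IRanges::findOverlaps(pts, win, select = "first")
      got <- which(!is.na(hits))
      hit_site[on_chr[got]] <- cs[hits[got]]
    }
    move <- which(!is.na(hit_site) & runif(nrow(fragments)) < dip_depth)
    if (!length(move)) next
    shift <- sample(c(-1, 1), length(move), replace = TRUE) *
      round(runif(length(move), zone + 1, zone + 90))
    newpos <- hit_site[move] + shift
    newpos <- pmax(newpos, 0)
    if (side == "start") {
      fragments$start[move] <- newpos
    } else {
      fragments$end[move] <- newpos + 1
    }
  }
  bad <- fragments$end <= fragments$start
  if (any(bad)) {  # keep fragments valid after relocation
    tmp <- fragments$start[bad]
    fragments$start[bad] <- fragments$end[bad] - 1
    fragments$end[bad] <- tmp + 1
  }
  fragments
}

#' @exportS3Method base::print
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort: ", ncol(x$atac$counts), " cells, ",
      nrow(x$atac$counts), " peaks, ", nrow(x$rna$counts), " genes, ",
      nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits exactly the formats the package readers consume: MatrixMarket
#' counts, BED peaks, barcode and metadata TSVs, a 5-column fragment file,
#' the peak-by-motif match matrix, motif sites, truth tables and the
#' configuration as YAML.
#'
#' @param cohort `sim_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  Matrix::writeMM(methods::as(cohort$atac$counts, "generalMatrix"), fp("atac.mtx"))
  writeLines(with(cohort$atac$peaks, paste(chrom, start, end, sep = "\t")),
             fp("peaks.bed"))
  writeLines(cohort$atac$cells, fp("barcodes.tsv"))
  utils::write.table(cohort$atac$cell_meta, fp("cell_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Matrix::writeMM(methods::as(cohort$rna$counts, "generalMatrix"), fp("rna.mtx"))
  utils::write.table(cohort$rna$genes, fp("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fragments(cohort$fragments, fp("fragments.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(cohort$matches * 1, sparse = TRUE),
                              "generalMatrix"), fp("matches.mtx"))
  writeLines(colnames(cohort$matches), fp("motifs.tsv"))
  utils::write.table(cohort$motif_sites, fp("motif_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir.create(fp("truth"), showWarnings = FALSE)
  for (nm in setdiff(names(cohort$truth), "degraded_cells")) {
    utils::write.table(cohort$truth[[nm]], fp("truth", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(cohort$truth$degraded_cells, fp("truth", "degraded_cells.tsv"))
  yaml::write_yaml(unclass(cohort$config), fp("config.yaml"))
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return `sim_cohort` list (fragment order and matrices as written).
#' @export
read_cohort <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  atac <- read_peak_matrix(fp("atac.mtx"), fp("peaks.bed"),
                           fp("barcodes.tsv"), fp("cell_meta.tsv"))
  genes <- tibble::as_tibble(utils::read.delim(fp("genes.tsv")))
  rna_counts <- methods::as(Matrix::readMM(fp("rna.mtx")), "CsparseMatrix")
  rna <- expression_matrix(rna_counts, genes[, c("gene", "chrom", "tss", "strand")],
                           atac$cells, atac$cell_meta)
  matches <- as.matrix(Matrix::readMM(fp("matches.mtx"))) > 0
  dimnames(matches) <- list(atac$peaks$id, readLines(fp("motifs.tsv")))
  cfg <- yaml::read_yaml(fp("config.yaml"))
  cfg$noise <- cfg$noise %||% "poisson"
  config <- do.call(simulation_config, cfg)
  truth <- list(
    true_links = tibble::as_tibble(utils::read.delim(fp("truth", "true_links.tsv"))),
    true_tumor_tfs = tibble::as_tibble(utils::read.delim(fp("truth", "true_tumor_tfs.tsv"))),
    true_programs = tibble::as_tibble(utils::read.delim(fp("truth", "true_programs.tsv"))),
    true_dars = tibble::as_tibble(utils::read.delim(fp("truth", "true_dars.tsv"))),
    degraded_cells = readLines(fp("truth", "degraded_cells.tsv"))
  )
  structure(list(atac = atac, rna = rna,
                 fragments = read_fragments(fp("fragments.tsv")),
                 matches = matches,
                 motif_sites = tibble::as_tibble(utils::read.delim(fp("motif_sites.tsv"))),
                 genes = genes, truth = truth, config = config),
            class = "sim_cohort")
}
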