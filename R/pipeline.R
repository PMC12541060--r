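#' Pipeline configuration
#'
#' Collects the stage parameters and per-stage seeds for [run_pipeline()].
#' One master seed expands deterministically into per-stage seeds.
#'
#' @param out_dir output directory for stage results and the manifest.
#' @param simulate `simulation_config` for the synthetic cohort (or `NULL`
#'   and supply `cohort_dir` with files readable by [read_cohort()]).
#' @param cohort_dir directory of an existing cohort.
#' @param qc named list of threshold tibbles per modality (see
#'   [qc_thresholds()]); scaled-down defaults matching the synthetic
#'   cohort's depth are used when omitted.
#' @param metacell_k,metacell_groups metacell size and seed-cell count.
#' @param coaccess_window,distance_penalty_scale co-accessibility controls.
#' @param link_window,n_null,fdr_cut,coaccess_cut,promoter_window linking
#'   controls; `cancer_overrides` is a named list of per-cancer `fdr_cut`
#'   values (the ovarian-cancer override lives here).
#' @param nmf_k_range,nmf_nrun,nmf_min_cells NMF program controls.
#' @param tumor_label,normal_label cell-type labels for the TF filter.
#' @param seed master seed.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("creglink_run_"),
                            simulate = simulation_config(),
                            cohort_dir = NULL, qc = NULL,
                            metacell_k = 50, metacell_groups = 200,
                            coaccess_window = 5e5,
                            distance_penalty_scale = 1,
                            link_window = 5e5, n_null = 1000,
                            fdr_cut = 0.1, coaccess_cut = 0.2,
                            promoter_window = 2000,
                            cancer_overrides = list(OC = 0.2),
                            nmf_k_range = 2:6, nmf_nrun = 30,
                            nmf_min_cells = 500, tumor_label = "tumor",
                            normal_label = "epithelial", seed = 1) {
  structure(list(
    out_dir = out_dir, simulate = simulate, cohort_dir = cohort_dir, qc = qc,
    metacell_k = metacell_k, metacell_groups = metacell_groups,
    coaccess_window = coaccess_window,
    distance_penalty_scale = distance_penalty_scale,
    link_window = link_window, n_null = n_null, fdr_cut = fdr_cut,
    coaccess_cut = coaccess_cut, promoter_window = promoter_window,
    cancer_overrides = cancer_overrides, nmf_k_range = nmf_k_range,
    nmf_nrun = nmf_nrun, nmf_min_cells = nmf_min_cells,
    tumor_label = tumor_label, normal_label = normal_label, seed = seed),
    class = "pipeline_config")
}

# peaks without sequence or GC annotation: neutral constant with ties
# broken by accessibility so equal-occupancy binning stays well defined
gc_content_stub <- function(x) {
  rep(0.5, nrow(x$counts)) + (row_totals(x$counts) %% 7) * 1e-3
}

# QC bounds matched to the synthetic cohort's desk-scale depth
scaled_qc_thresholds <- function() {
  tb <- qc_thresholds("atac")
  tb$lower <- c(20, NA, 1.5)
  tb$upper <- c(5000, 4, NA)
  tb
}

#' Run the integrated pipeline end-to-end
#'
#' Executes simulate (or load), QC, metacells, co-accessibility, peak-gene
#' links (per cancer type with override-aware FDR cutoffs), DARs,
#' cancer-specific and conserved regions, motif deviations, footprints, the
#' tumor-specific TF filter, and NMF meta-programs, writing per-stage
#' outputs under `config$out_dir` and returning a manifest of record
#' counts, seeds and timings. A stage failure aborts with the stage named;
#' outputs of completed stages remain on disk.
#'
#' @param config `pipeline_config`.
#' @return manifest tibble (stage, n_records, seed, elapsed_s).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage_i <- 0
  run_stage <- function(name, fun) {
    stage_i <<- stage_i + 1
    seed <- derive_seed(config$seed, stage_i)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(seed), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[name]] <<- tibble::tibble(
      stage = name, n_records = res$n, seed = seed,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    res$value
  }
  fp <- function(...) file.path(config$out_dir, ...)

  cohort <- run_stage("simulate", function(seed) {
    ch <- if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else simulate_cohort(config$simulate)
    list(value = ch, n = ncol(ch$atac$counts))
  })

  qc_res <- run_stage("qc", function(seed) {
    thr <- config$qc %||% list(atac = scaled_qc_thresholds())
    metrics <- count_metrics(cohort$atac)
    tssl <- tibble::tibble(chrom = cohort$rna$genes$chrom,
                           tss = cohort$rna$genes$tss)
    tssm <- tss_enrichment(cohort$fragments, tssl)
    nsm <- nucleosome_signal(cohort$fragments)
    metrics <- dplyr::left_join(metrics, tssm, by = "barcode")
    metrics <- dplyr::left_join(metrics, nsm, by = "barcode")
    metrics$tss_enrichment[is.na(metrics$tss_enrichment)] <- 0
    metrics$nucleosome_signal[is.na(metrics$nucleosome_signal)] <- 0
    res <- qc_filter(cohort$atac, metrics, thr$atac)
    utils::write.table(res$report, fp("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = res, n = ncol(res$filtered$counts))
  })
  atac <- qc_res$filtered
  keep <- match(atac$cells, cohort$rna$cells)
  rna <- subset_cells(cohort$rna, keep)

  metacells <- run_stage("metacells", function(seed) {
    emb <- lsi_embedding(atac)
    mm <- make_metacells(emb, k = config$metacell_k,
                         n_groups = config$metacell_groups, seed = seed)
    list(value = mm, n = length(mm$groups))
  })
  acc_agg <- aggregate_metacells(atac, metacells)
  expr_agg <- aggregate_metacells(rna, metacells)

  coaccess <- run_stage("coaccess", function(seed) {
    co <- coaccess_scores(acc_agg, atac$peaks,
                          window_size = config$coaccess_window,
                          distance_penalty_scale = config$distance_penalty_scale)
    utils::write.table(co, fp("coaccess.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(value = co, n = nrow(co))
  })

  networks <- run_stage("links", function(seed) {
    nets <- list()
    for (ca in unique(atac$cell_meta$cancer_type)) {
      cut <- config$cancer_overrides[[ca]] %||% config$fdr_cut
      if (!identical(cut, config$fdr_cut)) {
        message("links: cancer ", ca, " uses FDR cutoff ", cut)
      }
      net <- link_peaks(acc_agg, expr_agg, atac$peaks, rna$genes, coaccess,
                        window = config$link_window, n_null = config$n_null,
                        promoter_window = config$promoter_window,
                        fdr_cut = cut, coaccess_cut = config$coaccess_cut,
                        seed = seed)
      net$cancer_type <- ca
      nets[[ca]] <- net
      write_link_network(net, fp(paste0("links_", ca, ".tsv")))
    }
    list(value = nets, n = sum(vapply(nets, function(n) sum(n$reliable), 1L)))
  })

  dars <- run_stage("dars", function(seed) {
    out <- list()
    for (ca in unique(atac$cell_meta$cancer_type)) {
      idx <- which(atac$cell_meta$cancer_type == ca)
      sub <- subset_cells(atac, idx)
      d <- find_dars(sub)
      d$cancer_type <- ca
      out[[ca]] <- d
    }
    d <- dplyr::bind_rows(out)
    utils::write.table(d, fp("dars.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(value = d, n = nrow(d))
  })

  conserved <- run_stage("conserve", function(seed) {
    regions <- list()
    for (ca in names(networks)) {
      rg <- regulatory_regions_for_cell_type(
        networks[[ca]], dars[dars$cancer_type == ca, ], config$tumor_label)
      if (nrow(rg)) { rg$cancer_type <- ca; regions[[ca]] <- rg }
    }
    regions <- dplyr::bind_rows(regions)
    cons <- if (nrow(regions)) {
      conserved_regulatory_regions(
        regions, n_cancer_types = length(names(networks)))
    } else tibble::tibble()
    if (nrow(cons)) {
      writeLines(with(cons, paste(chrom, start, end, sep = "\t")),
                 fp("conserved.bed"))
    }
    list(value = cons, n = nrow(cons))
  })

  deviations <- run_stage("chromvar", function(seed) {
    gc <- atac$peaks$gc %||% gc_content_stub(atac)
    bg <- sample_background_peaks(gc, row_totals(atac$counts) /
                                    ncol(atac$counts), seed = seed)
    dv <- chromvar_deviations(atac$counts, cohort$matches, bg)
    list(value = dv, n = nrow(dv$z))
  })

  footprints <- run_stage("footprint", function(seed) {
    prof <- list()
    for (m in cohort$truth$true_tumor_tfs$motif) {
      sites <- cohort$motif_sites[cohort$motif_sites$motif == m, ]
      cells_t <- atac$cells[atac$cell_meta$cell_type == config$tumor_label]
      prof[[m]] <- footprint_profile(cohort$fragments, sites, cells_t)
    }
    list(value = prof, n = length(prof))
  })

  tf_table <- run_stage("tfspecific", function(seed) {
    tb <- tumor_specific_tfs(deviations, cohort$fragments,
                             cohort$motif_sites, rna, atac$cell_meta,
                             tumor_label = config$tumor_label,
                             normal_label = config$normal_label)
    utils::write.table(tb, fp("tumor_specific_tfs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = tb, n = sum(tb$selected))
  })

  nmf_out <- run_stage("nmf", function(seed) {
    rel <- relative_expression(rna, min_cells = config$nmf_min_cells,
                               tumor_label = config$tumor_label)
    fits <- list()
    for (s in names(rel)) {
      coph <- setNames(numeric(length(config$nmf_k_range)),
                       config$nmf_k_range)
      by_k <- list()
      for (k in config$nmf_k_range) {
        fit <- nmf_consensus(rel[[s]], k, nrun = config$nmf_nrun,
                             seed = derive_seed(seed, k))
        by_k[[as.character(k)]] <- fit
        coph[as.character(k)] <- fit$cophenetic
      }
      kstar <- select_k(coph)
      fits[[s]] <- by_k[[as.character(kstar)]]
    }
    meta <- rna$cell_meta
    expr_by_sample <- lapply(names(fits), function(s) {
      idx <- which(meta$sample == s & meta$cell_type == config$tumor_label)
      as.matrix(log_normalize(rna)[, idx, drop = FALSE])
    })
    names(expr_by_sample) <- names(fits)
    mp <- if (length(fits) >= 2) meta_programs(fits, expr_by_sample)
    else NULL
    if (!is.null(mp) && nrow(mp$signatures)) {
      utils::write.table(mp$signatures, fp("meta_programs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(value = list(fits = fits, meta = mp),
         n = if (is.null(mp)) 0L else length(unique(mp$members$meta_program)))
  })

  manifest <- dplyr::bind_rows(manifest)
  utils::write.table(manifest, fp("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(manifest, "results") <- list(
    cohort = cohort, atac = atac, rna = rna, metacells = metacells,
    coaccess = coaccess, networks = networks, dars = dars,
    conserved = conserved, deviations = deviations,
    footprints = footprints, tf_table = tf_table, nmf = nmf_out)
  manifest
}
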