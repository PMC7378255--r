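#' Canonical endothelial / pericyte / neural marker panel
#'
#' The compact marker panel used for per-panel enrichment reporting:
#' endothelial (CLDN5, CDH5, SLC2A1, ABCB1/Abcb1a, VWF, MFSD2A), pericyte
#' (ANPEP, CSPG4, RGS5, KCNJ8, ABCC9, PDGFRB) and neural (GABBR1, TUBB3,
#' AQP4) genes, with mouse symbols where the nomenclature differs.
#'
#' @return Tibble with `cell_type`, `human`, `mouse`.
#' @export
default_marker_panel <- function() {
  tibble::tribble(
    ~cell_type, ~human, ~mouse,
    "endothelial", "CLDN5", "Cldn5",
    "endothelial", "CDH5", "Cdh5",
    "endothelial", "SLC2A1", "Slc2a1",
    "endothelial", "ABCB1", "Abcb1a",
    "endothelial", "VWF", "Vwf",
    "endothelial", "MFSD2A", "Mfsd2a",
    "pericyte", "ANPEP", "Anpep",
    "pericyte", "CSPG4", "Cspg4",
    "pericyte", "RGS5", "Rgs5",
    "pericyte", "KCNJ8", "Kcnj8",
    "pericyte", "ABCC9", "Abcc9",
    "pericyte", "PDGFRB", "Pdgfrb",
    "neural", "GABBR1", "Gabbr1",
    "neural", "TUBB3", "Tubb3",
    "neural", "AQP4", "Aqp4"
  )
}

#' Marker-panel enrichment report
#'
#' For each panel gene: per-sample `log2(TPM + 1)`, the
#' microvessel-vs-whole-brain fold change and adjusted p, and a significance
#' flag at the threshold. Panel genes absent from the DE table are reported
#' as untested.
#'
#' @param de DE tibble from [differential_expression()].
#' @param tpm TPM expression tibble for the same samples.
#' @param panel Tibble with columns `gene`, `cell_type`.
#' @param padj_threshold Flag threshold (default 0.05).
#' @return Tibble: `gene`, `cell_type`, per-sample `log2(TPM+1)` columns,
#'   `log2fc`, `padj`, `significant`, `status`.
#' @export
marker_panel_report <- function(de, tpm, panel, padj_threshold = 0.05) {
  if (nrow(panel) == 0L) {
    return(tibble::tibble(gene = character(0), cell_type = character(0)))
  }
  samples <- count_sample_cols(tpm)
  idx_t <- match(panel$gene, tpm$gene)
  idx_d <- match(panel$gene, de$gene)
  out <- tibble::tibble(gene = panel$gene, cell_type = panel$cell_type)
  for (s in samples) {
    v <- tpm[[s]][idx_t]
    out[[paste0("log2tpm_", s)]] <- log2(ifelse(is.na(v), 0, v) + 1)
  }
  out$log2fc <- de$log2fc[idx_d]
  out$padj <- de$padj[idx_d]
  out$significant <- !is.na(out$padj) & out$padj < padj_threshold &
    out$log2fc > 0
  out$status <- ifelse(is.na(idx_d), "untested", de$status[idx_d])
  out
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, in order: study simulation, quantification (FPKM/TPM),
#' marker-panel report, pericyte/endothelial mixture scan (mouse
#' microvessels vs mouse reference profiles), paired
#' microvessel-vs-whole-brain differential expression per species,
#' sample clustering and PCA, cross-species differential expression over
#' the homology table, the three species filters, pericyte subtraction with
#' the human-specific intersection, and pre-ranked enrichment over the
#' planted marker sets. All tables are written as TSV under `out_dir`
#' together with a JSON run manifest (config snapshot, seed, per-stage
#' timings, md5 of every output).
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param gsea_n_perm Permutations for the enrichment stage (default 200).
#' @param padj_threshold,tpm_threshold,alpha_step Analysis thresholds:
#'   adjusted-p cut (0.05), endothelial-reference exclusion TPM (1), and
#'   mixture-scan grid step (0.01).
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         gsea_n_perm = 200, padj_threshold = 0.05,
                         tpm_threshold = 1, alpha_step = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  files <- character(0)
  stage <- function(name, expr) {
    s <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "; completed stages: ", paste(names(timings), collapse = ", "),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    val
  }
  emit <- function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path, progress = FALSE)
    files <<- c(files, path)
    path
  }

  study <- stage("simulate", simulate_study(config))
  tpm_h <- stage("quantify_human", tpm_from_counts(study$human$counts))
  tpm_m <- stage("quantify_mouse", tpm_from_counts(study$mouse$counts))
  emit(tpm_h, "tpm_human"); emit(tpm_m, "tpm_mouse")

  de_h <- stage("de_human", differential_expression(
    study$human$counts, study$human$metadata,
    padj_threshold = padj_threshold))
  de_m <- stage("de_mouse", differential_expression(
    study$mouse$counts, study$mouse$metadata,
    padj_threshold = padj_threshold))
  emit(de_h, "de_microvessel_human"); emit(de_m, "de_microvessel_mouse")

  panel <- dplyr::bind_rows(purrr::imap(study$truth$markers, function(m, type) {
    tibble::tibble(gene = utils::head(m$human, 3), cell_type = type)
  }))
  panel_report <- stage("marker_panel",
                        marker_panel_report(de_h, tpm_h, panel,
                                            padj_threshold))
  emit(panel_report, "marker_panel_report")

  ec_ref_m <- stage("reference_profiles", average_reference_profile(
    study$reference$mouse_endothelial, "endothelial"))
  pc_ref_m <- average_reference_profile(study$reference$mouse_pericyte,
                                        "pericyte")
  ec_ref_h <- average_reference_profile(study$reference$human_endothelial,
                                        "endothelial")

  mv_m <- study$mouse$metadata$sample[
    study$mouse$metadata$compartment == "microvessel"]
  scan <- stage("mixture_scan", scan_mixture_ratio(
    tpm_m[, c("gene", mv_m)], pc_ref_m, ec_ref_m, step = alpha_step))
  emit(tidy(scan), "mixture_scan_grid")
  emit(glance(scan), "mixture_scan_summary")

  qc <- stage("cluster_pca", {
    list(cluster_h = hier_cluster(tpm_h, "samples"),
         pca_h = pca_summary(tpm_h),
         cluster_m = hier_cluster(tpm_m, "samples"),
         pca_m = pca_summary(tpm_m))
  })
  emit(tidy(qc$pca_h), "pca_human_coordinates")
  emit(glance(qc$pca_h), "pca_human_variance")

  mv_h <- study$human$metadata$sample[
    study$human$metadata$compartment == "microvessel"]
  xs <- stage("cross_species", {
    collapsed <- collapse_homologs(study$homology,
                                   tpm_h[, c("gene", mv_h)],
                                   tpm_m[, c("gene", mv_m)])
    pseudo <- reverse_counts(
      collapsed,
      study$human$counts[, c("gene", "length_kb")])
    de <- cross_species_de(pseudo, padj_threshold = padj_threshold)
    list(collapsed = collapsed, pseudo = pseudo, de = de)
  })
  emit(xs$de, "de_cross_species")

  filt <- stage("species_filters", {
    list(
      a1_human = approach1(xs$de, de_h, "human", padj_threshold),
      a1_mouse = approach1(xs$de, de_m, "mouse", padj_threshold),
      a2_human = approach2(xs$de, de_h, "human", padj_threshold),
      a2_mouse = approach2(xs$de, de_m, "mouse", padj_threshold),
      a3 = approach3(de_m, de_h, study$homology, padj_threshold)
    )
  })
  emit(filt$a1_human, "approach1_human"); emit(filt$a1_mouse, "approach1_mouse")
  emit(filt$a2_human, "approach2_human"); emit(filt$a2_mouse, "approach2_mouse")
  emit(filt$a3$mouse_only, "approach3_mouse_only")
  emit(filt$a3$human_only, "approach3_human_only")

  peri <- stage("pericyte_subtraction", subtract_endothelial(
    de_h, ec_ref_h, tpm_threshold, padj_threshold))
  peri_human <- stage("human_specific_pericyte",
                      human_specific_pericyte(peri, filt$a1_human))
  emit(peri, "pericyte_partition")
  emit(peri_human, "pericyte_human_specific")

  gsea <- stage("gsea", {
    ranked <- rank_genes(de_h)
    sets <- purrr::map(study$truth$markers, "human")
    names(sets) <- paste0(names(sets), "_markers")
    gmt_path <- file.path(out_dir, "marker_sets.gmt")
    write_gmt(sets, gmt_path)
    files <- c(files, gmt_path)
    gsea_preranked(ranked, read_gmt(gmt_path), n_perm = gsea_n_perm,
                   seed = derive_seed(config$seed, 71L))
  })
  emit(gsea, "gsea_results")

  set_sizes <- list(
    approach1_human = nrow(filt$a1_human),
    approach1_mouse = nrow(filt$a1_mouse),
    approach2_human = nrow(filt$a2_human),
    approach2_mouse = nrow(filt$a2_mouse),
    approach3_mouse_only = nrow(filt$a3$mouse_only),
    approach3_human_only = nrow(filt$a3$human_only),
    putative_pericyte = sum(peri$class == "putative_pericyte"),
    human_specific_pericyte = nrow(peri_human)
  )
  jsonlite::write_json(set_sizes, file.path(out_dir, "set_sizes.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(out_dir, "set_sizes.json"))

  manifest <- list(
    config = config[setdiff(names(config), "")],
    seed = config$seed,
    thresholds = list(padj = padj_threshold, tpm = tpm_threshold,
                      alpha_step = alpha_step, gsea_n_perm = gsea_n_perm),
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files)),
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(study = study, tpm = list(human = tpm_h, mouse = tpm_m),
                 de = list(human = de_h, mouse = de_m),
                 panel_report = panel_report, mixture_scan = scan, qc = qc,
                 cross_species = xs, filters = filt,
                 pericyte = list(partition = peri, human_specific = peri_human),
                 gsea = gsea, set_sizes = set_sizes, manifest = manifest))
}
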