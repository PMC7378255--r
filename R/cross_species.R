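#' Read a mouse-human homology table
#'
#' @param path TSV with columns `human_symbol`, `mouse_symbol`, one row per
#'   homolog pair.
#' @return Classified homology tibble (see [classify_homology()]).
#' @export
read_homology <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("human_symbol", "mouse_symbol") %in% names(tbl))) {
    stop("homology table needs columns human_symbol, mouse_symbol")
  }
  classify_homology(tbl)
}

#' Classify homolog pairs by multiplicity
#'
#' Annotates each (human, mouse) pair as `one_to_one`, `one_to_many_mouse`
#' (one human gene, several mouse homologs) or `one_to_many_human` (one
#' mouse gene, several human homologs). Pairs belonging to a many:many
#' component cannot be resolved by the collapsing rules and raise an error
#' naming the component.
#'
#' @param ht Tibble with columns `human_symbol`, `mouse_symbol`.
#' @return The same tibble with a `homology_class` column, deduplicated.
#' @export
classify_homology <- function(ht) {
  ht <- dplyr::distinct(tibble::as_tibble(ht),
                        .data$human_symbol, .data$mouse_symbol)
  n_mouse <- table(ht$human_symbol)
  n_human <- table(ht$mouse_symbol)
  mult_h <- as.integer(n_mouse[ht$human_symbol])
  mult_m <- as.integer(n_human[ht$mouse_symbol])
  conflict <- mult_h > 1L & mult_m > 1L
  if (any(conflict)) {
    bad <- ht[conflict, ]
    stop("many:many homology component(s) cannot be collapsed: ",
         paste(paste0(bad$human_symbol, "~", bad$mouse_symbol), collapse = ", "))
  }
  ht$homology_class <- dplyr::case_when(
    mult_h > 1L ~ "one_to_many_mouse",
    mult_m > 1L ~ "one_to_many_human",
    TRUE ~ "one_to_one"
  )
  ht
}

#' Collapse homologs into aligned cross-species TPM rows
#'
#' Applies the homology collapsing rules to produce one aligned row per
#' retained mouse-human comparison: 1:1 pairs pass through (`direct`); for a
#' human gene with several mouse homologs the mouse TPM values are summed
#' per sample (`summed_mouse`); for a mouse gene with several human
#' homologs, the human homolog with the highest mean TPM is retained alone
#' when the runner-up is negligible or much lower (`max_human`), otherwise
#' each similarly-expressed human homolog is compared individually against
#' the same mouse gene (`split_comparison`). Pairs whose symbols are absent
#' from either expression table are dropped and counted in the audit.
#'
#' @param ht Classified homology tibble (from [classify_homology()]).
#' @param human_tpm,mouse_tpm TPM expression tibbles (`gene` plus sample
#'   columns) for each species.
#' @param negligible_tpm Mean-TPM level below which a runner-up human
#'   homolog is considered unexpressed (default 1).
#' @param similar_ratio A runner-up within this fraction of the top human
#'   homolog's mean TPM counts as "similar expression" (default 0.2).
#' @return Tibble with `human_symbol`, `mouse_symbol`, `provenance`, the
#'   human sample columns and the mouse sample columns; attribute `"audit"`
#'   holds per-class and dropped counts summing to the table size.
#' @export
collapse_homologs <- function(ht, human_tpm, mouse_tpm,
                              negligible_tpm = 1, similar_ratio = 0.2) {
  h_samples <- count_sample_cols(human_tpm)
  m_samples <- count_sample_cols(mouse_tpm)
  h_mat <- as.matrix(human_tpm[, h_samples, drop = FALSE])
  rownames(h_mat) <- human_tpm$gene
  m_mat <- as.matrix(mouse_tpm[, m_samples, drop = FALSE])
  rownames(m_mat) <- mouse_tpm$gene

  present <- ht$human_symbol %in% rownames(h_mat) &
    ht$mouse_symbol %in% rownames(m_mat)
  dropped <- sum(!present)
  use <- ht[present, ]

  rows <- list()
  audit <- c(direct = 0L, summed_mouse = 0L, max_human = 0L,
             split_comparison = 0L, dropped = dropped)
  emit <- function(hs, ms_label, hvec, mvec, prov) {
    tibble::tibble(human_symbol = hs, mouse_symbol = ms_label,
                   provenance = prov,
                   !!!stats::setNames(as.list(hvec), h_samples),
                   !!!stats::setNames(as.list(mvec), m_samples))
  }

  o2o <- use[use$homology_class == "one_to_one", ]
  if (nrow(o2o) > 0L) {
    rows <- c(rows, purrr::map(seq_len(nrow(o2o)), function(i) {
      emit(o2o$human_symbol[i], o2o$mouse_symbol[i],
           h_mat[o2o$human_symbol[i], ], m_mat[o2o$mouse_symbol[i], ],
           "direct")
    }))
    audit["direct"] <- nrow(o2o)
  }

  otm <- use[use$homology_class == "one_to_many_mouse", ]
  for (hs in unique(otm$human_symbol)) {
    ms <- sort(otm$mouse_symbol[otm$human_symbol == hs])
    mvec <- colSums(m_mat[ms, , drop = FALSE])
    rows <- c(rows, list(emit(hs, paste(ms, collapse = "+"),
                              h_mat[hs, ], mvec, "summed_mouse")))
    audit["summed_mouse"] <- audit["summed_mouse"] + length(ms)
  }

  oth <- use[use$homology_class == "one_to_many_human", ]
  for (ms in unique(oth$mouse_symbol)) {
    hs_all <- sort(oth$human_symbol[oth$mouse_symbol == ms])
    means <- rowMeans(h_mat[hs_all, , drop = FALSE])
    ord <- order(-means, hs_all)
    hs_all <- hs_all[ord]; means <- means[ord]
    runner_up <- if (length(means) > 1L) means[2] else 0
    if (runner_up < negligible_tpm || runner_up < similar_ratio * means[1]) {
      rows <- c(rows, list(emit(hs_all[1], ms, h_mat[hs_all[1], ],
                                m_mat[ms, ], "max_human")))
      audit["max_human"] <- audit["max_human"] + length(hs_all)
    } else {
      keep <- means >= negligible_tpm & means >= similar_ratio * means[1]
      for (hs in hs_all[keep]) {
        rows <- c(rows, list(emit(hs, ms, h_mat[hs, ], m_mat[ms, ],
                                  "split_comparison")))
      }
      audit["split_comparison"] <- audit["split_comparison"] + length(hs_all)
    }
  }

  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        .data$human_symbol, .data$mouse_symbol)
  if (dropped > 0L) {
    message(dropped, " homolog pair(s) dropped: symbol absent from an expression table")
  }
  attr(out, "audit") <- audit
  attr(out, "human_samples") <- h_samples
  attr(out, "mouse_samples") <- m_samples
  out
}

#' Reverse-calculate pseudo-counts from TPM using human gene lengths
#'
#' Mouse and human homologs differ in transcript length, so raw counts are
#' not comparable across species. TPM rows are instead converted back to an
#' unnormalised count scale with the human gene length:
#' `raw_ij = TPM_ij * L_human_i`, then each sample is rescaled to a common
#' target depth and rounded to integers for count-based testing.
#'
#' @param xsm Collapsed cross-species tibble from [collapse_homologs()].
#' @param human_lengths Tibble with `gene`, `length_kb` for human genes.
#' @param target_depth Common library size after rescaling (default 2e7,
#'   roughly a 20-million-read library).
#' @return Tibble with `human_symbol`, `mouse_symbol`, `provenance`,
#'   `length_kb` and integer pseudo-count sample columns; sample/species
#'   attributes carried over.
#' @export
reverse_counts <- function(xsm, human_lengths, target_depth = 2e7) {
  if (target_depth <= 0) stop("target_depth must be positive")
  len <- human_lengths$length_kb[match(xsm$human_symbol, human_lengths$gene)]
  missing <- is.na(len)
  if (any(missing)) {
    message(sum(missing), " row(s) dropped: no human gene length")
    xsm <- xsm[!missing, ]
    len <- len[!missing]
  }
  samples <- c(attr(xsm, "human_samples"), attr(xsm, "mouse_samples")) %||%
    setdiff(names(xsm), c("human_symbol", "mouse_symbol", "provenance"))
  out <- tibble::tibble(human_symbol = xsm$human_symbol,
                        mouse_symbol = xsm$mouse_symbol,
                        provenance = xsm$provenance,
                        length_kb = len)
  zero_depth <- character(0)
  for (s in samples) {
    raw <- xsm[[s]] * len
    tot <- sum(raw)
    if (tot == 0) {
      zero_depth <- c(zero_depth, s)
      out[[s]] <- rep(0L, length(raw))
    } else {
      out[[s]] <- as.integer(round(raw * target_depth / tot))
    }
  }
  if (length(zero_depth) > 0L) {
    warning("all-zero sample(s) in reverse-count input: ",
            paste(zero_depth, collapse = ", "))
  }
  attr(out, "human_samples") <- attr(xsm, "human_samples")
  attr(out, "mouse_samples") <- attr(xsm, "mouse_samples")
  out
}

#' Cross-species differential expression on reverse-calculated counts
#'
#' Runs the negative-binomial Wald machinery unpaired (species admits no
#' pairing), contrasting human over mouse microvessel samples; positive
#' `log2fc` means human-enriched.
#'
#' @param pseudo Pseudo-count tibble from [reverse_counts()].
#' @param human_samples,mouse_samples Sample column names per species;
#'   default to the attributes set by [reverse_counts()].
#' @param padj_threshold Significance threshold (default 0.05).
#' @return DE tibble keyed by `human_symbol` (with `mouse_symbol` and
#'   `provenance` carried along).
#' @export
cross_species_de <- function(pseudo,
                             human_samples = attr(pseudo, "human_samples"),
                             mouse_samples = attr(pseudo, "mouse_samples"),
                             padj_threshold = 0.05) {
  if (is.null(human_samples) || is.null(mouse_samples)) {
    stop("human_samples and mouse_samples must be supplied")
  }
  key <- paste0(pseudo$human_symbol, "~", pseudo$mouse_symbol)
  counts <- tibble::tibble(gene = key, length_kb = pseudo$length_kb)
  for (s in c(human_samples, mouse_samples)) counts[[s]] <- pseudo[[s]]
  meta <- tibble::tibble(
    sample = c(human_samples, mouse_samples),
    species = c(rep("human", length(human_samples)),
                rep("mouse", length(mouse_samples))),
    compartment = "microvessel",
    pair_id = NA_character_
  )
  de <- differential_expression(counts, meta, contrast = c("human", "mouse"),
                                group_var = "species", paired = FALSE,
                                padj_threshold = padj_threshold)
  de$human_symbol <- pseudo$human_symbol[match(de$gene, key)]
  de$mouse_symbol <- pseudo$mouse_symbol[match(de$gene, key)]
  de$provenance <- pseudo$provenance[match(de$gene, key)]
  attr(de, "padj_threshold") <- padj_threshold
  de
}
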