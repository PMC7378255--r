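#' Species-enriched genes also microvessel-enriched in their own species
#'
#' The most stringent species filter: keeps genes enriched in one species'
#' microvessels over the other species that are *also* microvessel-enriched
#' over whole brain within that species, attributing the species difference
#' to vascular rather than parenchymal expression.
#'
#' @param xs_de Cross-species DE tibble (from [cross_species_de()]).
#' @param mv_de Within-species microvessel-vs-whole-brain DE tibble for the
#'   species of interest.
#' @param species `"human"` or `"mouse"`: which species' enrichment to
#'   filter (human-enriched genes have positive cross-species `log2fc`).
#' @param padj_threshold Threshold applied to both tables (default 0.05).
#' @return Gene-set report tibble: `gene` (symbol in the filtered species),
#'   `homolog`, `xs_log2fc`, `xs_padj`, `mv_log2fc`, `mv_padj`.
#' @export
approach1 <- function(xs_de, mv_de, species = c("human", "mouse"),
                      padj_threshold = 0.05) {
  species <- match.arg(species)
  sel <- species_enriched(xs_de, species, padj_threshold)
  mv_enr <- mv_de[!is.na(mv_de$padj) & mv_de$padj < padj_threshold &
                    mv_de$log2fc > 0, ]
  out <- dplyr::inner_join(sel, mv_enr[, c("gene", "log2fc", "padj")],
                           by = "gene", suffix = c("", ".mv"))
  if (nrow(out) == 0L) warning("approach 1 intersection is empty")
  report <- tibble::tibble(gene = out$gene, homolog = out$homolog,
                           xs_log2fc = out$xs_log2fc, xs_padj = out$xs_padj,
                           mv_log2fc = out$log2fc, mv_padj = out$padj)
  dplyr::arrange(report, .data$gene)
}

#' Species-enriched genes with no compartment enrichment in their species
#'
#' The less stringent species filter: keeps species-enriched genes that show
#' *no* microvessel or whole-brain enrichment within the species
#' (`padj >= threshold`, or untested/absent from the full table — such genes
#' are retained and flagged). Captures species differences expressed in both
#' vasculature and parenchyma, which the stricter intersection filter
#' discards.
#'
#' @inheritParams approach1
#' @param mv_de_full Full (unthresholded) microvessel-vs-whole-brain DE
#'   table for the species.
#' @return Gene-set report tibble with `gene`, `homolog`, `xs_log2fc`,
#'   `xs_padj`, `mv_padj`, `mv_status` (`not_compartment_enriched` or
#'   `untested`).
#' @export
approach2 <- function(xs_de, mv_de_full, species = c("human", "mouse"),
                      padj_threshold = 0.05) {
  species <- match.arg(species)
  sel <- species_enriched(xs_de, species, padj_threshold)
  idx <- match(sel$gene, mv_de_full$gene)
  mv_padj <- mv_de_full$padj[idx]
  untested <- is.na(idx) | is.na(mv_padj)
  keep <- untested | mv_padj >= padj_threshold
  if (any(is.na(idx))) {
    message(sum(is.na(idx)), " gene(s) absent from the compartment table; treated as untested")
  }
  report <- tibble::tibble(
    gene = sel$gene[keep], homolog = sel$homolog[keep],
    xs_log2fc = sel$xs_log2fc[keep], xs_padj = sel$xs_padj[keep],
    mv_padj = mv_padj[keep],
    mv_status = ifelse(untested[keep], "untested", "not_compartment_enriched")
  )
  dplyr::arrange(report, .data$gene)
}

#' Direct comparison of the two species' microvessel-enriched lists
#'
#' Complements the homology-mediated filters: a mouse gene is "mouse-only"
#' when it is microvessel-enriched in mouse while its human homolog (if one
#' exists) is not microvessel-enriched in human; genes without a known
#' homolog are kept and flagged, since catching them is the point of the
#' direct comparison. Symmetric for human.
#'
#' @param mouse_mv_de,human_mv_de Within-species microvessel-vs-whole-brain
#'   DE tibbles.
#' @param ht Classified homology tibble.
#' @param padj_threshold Threshold for "enriched" (default 0.05).
#' @return List with tibbles `mouse_only` and `human_only`, each with
#'   `gene`, `homolog` (NA when none) and `homolog_less` flag.
#' @export
approach3 <- function(mouse_mv_de, human_mv_de, ht, padj_threshold = 0.05) {
  enr <- function(de) {
    de$gene[!is.na(de$padj) & de$padj < padj_threshold & de$log2fc > 0]
  }
  m_enr <- enr(mouse_mv_de)
  h_enr <- enr(human_mv_de)
  one_side <- function(genes, other_enr, to_other) {
    homolog <- to_other[genes]
    enriched_other <- vapply(homolog, function(hh) {
      !is.na(hh) && any(strsplit(hh, ",", fixed = TRUE)[[1]] %in% other_enr)
    }, logical(1))
    keep <- is.na(homolog) | !enriched_other
    tibble::tibble(gene = genes[keep], homolog = unname(homolog[keep]),
                   homolog_less = is.na(homolog[keep])) |>
      dplyr::arrange(.data$gene)
  }
  m2h <- tapply(ht$human_symbol, ht$mouse_symbol,
                function(x) paste(sort(unique(x)), collapse = ","))
  h2m <- tapply(ht$mouse_symbol, ht$human_symbol,
                function(x) paste(sort(unique(x)), collapse = ","))
  mouse_map <- stats::setNames(as.character(m2h[m_enr]), m_enr)
  human_map <- stats::setNames(as.character(h2m[h_enr]), h_enr)
  list(mouse_only = one_side(m_enr, h_enr, mouse_map),
       human_only = one_side(h_enr, m_enr, human_map))
}

#' Subtractive identification of putative pericyte genes
#'
#' Partitions the human microvessel-enriched gene list against a purified
#' endothelial reference profile: genes at `tpm_threshold` TPM or greater in
#' the reference are considered endothelial-derived and excluded; the
#' remainder are putative pericyte genes. Enriched genes absent from the
#' reference universe count as 0 TPM and are flagged.
#'
#' @param mv_de Human microvessel-vs-whole-brain DE tibble.
#' @param ec_reference Endothelial reference profile
#'   (from [average_reference_profile()]).
#' @param tpm_threshold Exclusion boundary; `TPM >= threshold` is
#'   endothelial-derived (default 1).
#' @param padj_threshold Enrichment threshold on the DE table (default 0.05).
#' @return Tibble with one row per microvessel-enriched gene: `gene`,
#'   `tpm_ec`, `class` (`endothelial_derived` / `putative_pericyte`),
#'   `missing_in_reference`, `mv_log2fc`, `mv_padj`.
#' @export
subtract_endothelial <- function(mv_de, ec_reference, tpm_threshold = 1,
                                 padj_threshold = 0.05) {
  if (tpm_threshold <= 0) stop("tpm_threshold must be positive")
  enr <- mv_de[!is.na(mv_de$padj) & mv_de$padj < padj_threshold &
                 mv_de$log2fc > 0, ]
  tpm_ec <- ec_reference$tpm[match(enr$gene, ec_reference$gene)]
  missing <- is.na(tpm_ec)
  tpm_ec[missing] <- 0
  tibble::tibble(
    gene = enr$gene,
    tpm_ec = tpm_ec,
    class = ifelse(tpm_ec >= tpm_threshold, "endothelial_derived",
                   "putative_pericyte"),
    missing_in_reference = missing,
    mv_log2fc = enr$log2fc,
    mv_padj = enr$padj
  ) |> dplyr::arrange(.data$gene)
}

#' Human-enriched putative pericyte genes
#'
#' Intersects the putative pericyte list with the human-enriched vascular
#' gene report, ranking the result by cross-species fold change (human over
#' mouse microvessels), descending.
#'
#' @param pericyte_report Output of [subtract_endothelial()].
#' @param human_vascular Human-side report from [approach1()].
#' @return Tibble with `gene`, `tpm_ec`, `xs_log2fc`, `xs_padj`,
#'   `mv_log2fc`, `mv_padj`, sorted by `xs_log2fc` descending.
#' @export
human_specific_pericyte <- function(pericyte_report, human_vascular) {
  peri <- pericyte_report[pericyte_report$class == "putative_pericyte", ]
  out <- dplyr::inner_join(
    peri[, c("gene", "tpm_ec", "mv_log2fc", "mv_padj")],
    human_vascular[, c("gene", "xs_log2fc", "xs_padj")],
    by = "gene"
  )
  dplyr::arrange(out, dplyr::desc(.data$xs_log2fc), .data$gene)
}

# rows of a cross-species DE table enriched in the given species,
# keyed by that species' symbol
species_enriched <- function(xs_de, species, padj_threshold) {
  sign_ok <- if (species == "human") xs_de$log2fc > 0 else xs_de$log2fc < 0
  sel <- xs_de[!is.na(xs_de$padj) & xs_de$padj < padj_threshold & sign_ok, ]
  if (species == "human") {
    tibble::tibble(gene = sel$human_symbol, homolog = sel$mouse_symbol,
                   xs_log2fc = sel$log2fc, xs_padj = sel$padj)
  } else {
    # summed-mouse rows carry "+"-joined symbols; expand so each mouse gene
    # can be matched against the within-species compartment table
    tibble::tibble(gene = sel$mouse_symbol, homolog = sel$human_symbol,
                   xs_log2fc = sel$log2fc, xs_padj = sel$padj) |>
      tidyr::separate_rows("gene", sep = "\\+")
  }
}
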