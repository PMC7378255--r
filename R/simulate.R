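#' Configuration for a synthetic microvessel study
#'
#' Describes a two-species paired microvessel / whole-brain study with the
#' statistical structure the analysis assumes: four cell types (endothelial,
#' pericyte, neuron, astrocyte), microvessel samples dominated by a roughly
#' 1:1 endothelial/pericyte mixture plus parenchymal contamination,
#' whole-brain samples dominated by parenchyma with a small vascular
#' fraction, negative-binomial count noise, planted cell-type markers,
#' planted species differences (vascular-restricted and pan-tissue), and a
#' homology table with 1:1, 1:many and unmapped cases.
#'
#' @param n_genes Number of base gene entities (default 2000).
#' @param n_pairs Paired microvessel/whole-brain replicates per species
#'   (default 3 biological replicates).
#' @param library_size Expected reads per bulk sample (default 2e6).
#' @param dispersion Negative-binomial dispersion of bulk counts
#'   (default 0.1).
#' @param mv_vascular,mv_pericyte_share Microvessel vascular weight
#'   (default 0.85) and its pericyte share (default 0.40/0.85); remaining
#'   mass is parenchymal contamination. Defaults give composition
#'   endothelial 0.45, pericyte 0.40, parenchyma 0.15.
#' @param wb_vascular Whole-brain vascular weight (default 0.10; parenchyma
#'   0.90), split between endothelial and pericyte in the microvessel
#'   vascular proportions.
#' @param parenchyma_neuron_share Neuron share of the parenchymal weight
#'   (default 0.7; astrocytes take the rest).
#' @param n_markers Named integer vector of planted marker genes per cell
#'   type (default 50 each).
#' @param marker_fold Multiplicative up-regulation of a marker in its home
#'   cell type (default 8); expression in other cell types is suppressed by
#'   `marker_leakage`.
#' @param marker_leakage Fraction of baseline a marker keeps outside its
#'   home type (default 1e-4).
#' @param n_species_vascular,n_species_global Planted human-up species
#'   differences restricted to vascular signatures / present in all
#'   signatures (default 40 each).
#' @param n_species_pericyte Number of pericyte markers additionally
#'   up-regulated in the human pericyte signature (human-specific pericyte
#'   genes; default 10, must not exceed the pericyte marker count).
#' @param species_fold Fold size of planted species differences (default 8).
#' @param homology_fractions Named fractions of base genes per homology
#'   class (`one_to_one`, `one_to_many_mouse`, `one_to_many_human`,
#'   `unmapped`; default 0.92/0.02/0.02/0.04).
#' @param n_reference_cells Single cells per reference profile (default 30).
#' @param reference_library Expected reads per reference cell (default 1e5).
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   in kilobases (default around 2 kb).
#' @param seed Integer seed recorded in every output.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_pairs = 3,
                              library_size = 2e6, dispersion = 0.1,
                              mv_vascular = 0.85,
                              mv_pericyte_share = 0.40 / 0.85,
                              wb_vascular = 0.10,
                              parenchyma_neuron_share = 0.7,
                              n_markers = c(endothelial = 50, pericyte = 50,
                                            neuron = 50, astrocyte = 50),
                              marker_fold = 8, marker_leakage = 1e-4,
                              n_species_vascular = 40,
                              n_species_global = 40,
                              n_species_pericyte = 10, species_fold = 8,
                              homology_fractions = c(one_to_one = 0.92,
                                                     one_to_many_mouse = 0.02,
                                                     one_to_many_human = 0.02,
                                                     unmapped = 0.04),
                              n_reference_cells = 30,
                              reference_library = 1e5,
                              length_meanlog = log(2), length_sdlog = 0.5,
                              seed = 1) {
  stopifnot(n_genes > 0, n_pairs > 0, library_size > 0, dispersion >= 0,
            mv_vascular > 0, mv_vascular <= 1,
            mv_pericyte_share >= 0, mv_pericyte_share <= 1,
            wb_vascular >= 0, wb_vascular < 1)
  if (abs(sum(homology_fractions) - 1) > 1e-8) {
    stop("homology_fractions must sum to 1")
  }
  if (sum(n_markers) + n_species_vascular + n_species_global > n_genes) {
    stop("planted gene counts exceed n_genes")
  }
  if (n_species_pericyte > n_markers[["pericyte"]]) {
    stop("n_species_pericyte cannot exceed the pericyte marker count")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# composition vectors over the four cell types implied by a config
sim_compositions <- function(cfg) {
  ec_share <- 1 - cfg$mv_pericyte_share
  mv <- c(endothelial = cfg$mv_vascular * ec_share,
          pericyte = cfg$mv_vascular * cfg$mv_pericyte_share,
          neuron = (1 - cfg$mv_vascular) * cfg$parenchyma_neuron_share,
          astrocyte = (1 - cfg$mv_vascular) * (1 - cfg$parenchyma_neuron_share))
  wb <- c(endothelial = cfg$wb_vascular * ec_share,
          pericyte = cfg$wb_vascular * cfg$mv_pericyte_share,
          neuron = (1 - cfg$wb_vascular) * cfg$parenchyma_neuron_share,
          astrocyte = (1 - cfg$wb_vascular) * (1 - cfg$parenchyma_neuron_share))
  list(microvessel = mv, whole_brain = wb)
}

#' Cell-type signature construction for a synthetic study
#'
#' Draws long-tailed (log-normal) baseline abundances shared across cell
#' types and species, plants cell-type markers (multiplicative
#' up-regulation in the home type, near-silencing elsewhere) and human-up
#' species differences (vascular-restricted or pan-tissue), builds the
#' homology table with the configured class mix, and normalises every
#' signature to TPM (sums to 1e6).
#'
#' @param cfg A [simulation_config()].
#' @return List with `human`/`mouse` (each: `genes`, `lengths_kb`,
#'   `signatures` gene-by-cell-type TPM matrix), `homology` (classified
#'   tibble) and `truth` (planted marker and species-difference
#'   assignments).
#' @export
make_signatures <- function(cfg) {
  n <- cfg$n_genes
  classes <- rep(names(cfg$homology_fractions),
                 times = round(cfg$homology_fractions * n))
  classes <- c(classes, rep("one_to_one", n - length(classes)))[seq_len(n)]
  # unmapped entities alternate between human-only and mouse-only genes
  unm <- which(classes == "unmapped")
  human_only <- unm[seq_along(unm) %% 2L == 1L]
  mouse_only <- setdiff(unm, human_only)

  base_id <- sprintf("G%05d", seq_len(n))
  baseline <- stats::rlnorm(n, meanlog = 2, sdlog = 1)
  lengths <- stats::rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)

  types <- c("endothelial", "pericyte", "neuron", "astrocyte")
  # planted genes drawn from 1:1 entities, non-overlapping
  o2o <- which(classes == "one_to_one")
  need <- sum(cfg$n_markers) + cfg$n_species_vascular + cfg$n_species_global
  picked <- sample(o2o, need)
  marker_idx <- list()
  off <- 0L
  for (t in types) {
    marker_idx[[t]] <- picked[off + seq_len(cfg$n_markers[[t]])]
    off <- off + cfg$n_markers[[t]]
  }
  sp_vasc <- picked[off + seq_len(cfg$n_species_vascular)]
  sp_glob <- picked[off + cfg$n_species_vascular + seq_len(cfg$n_species_global)]

  base_sig <- function() {
    sig <- matrix(baseline, nrow = n, ncol = length(types),
                  dimnames = list(base_id, types))
    for (t in types) {
      idx <- marker_idx[[t]]
      sig[idx, ] <- sig[idx, ] * cfg$marker_leakage
      sig[idx, t] <- baseline[idx] * cfg$marker_fold
    }
    sig
  }
  human_sig <- base_sig()
  mouse_sig <- base_sig()
  human_sig[sp_vasc, c("endothelial", "pericyte")] <-
    human_sig[sp_vasc, c("endothelial", "pericyte")] * cfg$species_fold
  human_sig[sp_glob, ] <- human_sig[sp_glob, ] * cfg$species_fold
  # human-specific pericyte genes: pericyte markers in both species, but
  # stronger in the human pericyte signature
  sp_peri <- if (cfg$n_species_pericyte > 0) {
    sample(marker_idx[["pericyte"]], cfg$n_species_pericyte)
  } else integer(0)
  human_sig[sp_peri, "pericyte"] <- human_sig[sp_peri, "pericyte"] *
    cfg$species_fold

  # expand base entities into species gene universes + homology rows
  h_rows <- list(); m_rows <- list(); hom <- list()
  for (i in seq_len(n)) {
    hsym <- paste0("GENE", i); msym <- paste0("Gene", i)
    cl <- classes[i]
    if (i %in% human_only) {
      h_rows[[length(h_rows) + 1]] <- list(sym = hsym, base = i, frac = 1)
    } else if (i %in% mouse_only) {
      m_rows[[length(m_rows) + 1]] <- list(sym = msym, base = i, frac = 1)
    } else if (cl == "one_to_many_mouse") {
      # one human gene, two mouse homologs splitting the abundance
      h_rows[[length(h_rows) + 1]] <- list(sym = hsym, base = i, frac = 1)
      for (suf in c("a", "b")) {
        m_rows[[length(m_rows) + 1]] <-
          list(sym = paste0(msym, suf), base = i, frac = 0.5)
        hom[[length(hom) + 1]] <-
          tibble::tibble(human_symbol = hsym, mouse_symbol = paste0(msym, suf))
      }
    } else if (cl == "one_to_many_human") {
      # one mouse gene, two human homologs; alternate between a dominant
      # homolog with a negligible runner-up and a similarly-expressed pair
      m_rows[[length(m_rows) + 1]] <- list(sym = msym, base = i, frac = 1)
      fracs <- if (i %% 2L == 0L) c(A = 0.95, B = 0.02) else c(A = 0.55, B = 0.45)
      for (suf in names(fracs)) {
        h_rows[[length(h_rows) + 1]] <-
          list(sym = paste0(hsym, suf), base = i, frac = fracs[[suf]])
        hom[[length(hom) + 1]] <-
          tibble::tibble(human_symbol = paste0(hsym, suf), mouse_symbol = msym)
      }
    } else {
      h_rows[[length(h_rows) + 1]] <- list(sym = hsym, base = i, frac = 1)
      m_rows[[length(m_rows) + 1]] <- list(sym = msym, base = i, frac = 1)
      hom[[length(hom) + 1]] <-
        tibble::tibble(human_symbol = hsym, mouse_symbol = msym)
    }
  }
  expand <- function(rows, sig, jitter_len) {
    syms <- vapply(rows, `[[`, character(1), "sym")
    base <- vapply(rows, `[[`, integer(1), "base")
    frac <- vapply(rows, `[[`, numeric(1), "frac")
    s <- sig[base, , drop = FALSE] * frac
    rownames(s) <- syms
    s <- sweep(s, 2, colSums(s), "/") * 1e6
    len <- lengths[base]
    if (jitter_len) len <- len * exp(stats::rnorm(length(len), 0, 0.1))
    list(genes = syms, base = base, lengths_kb = len, signatures = s)
  }
  human <- expand(h_rows, human_sig, jitter_len = FALSE)
  mouse <- expand(m_rows, mouse_sig, jitter_len = TRUE)

  sym_of <- function(idx, prefix) paste0(prefix, idx)
  truth <- list(
    markers = purrr::map(marker_idx, function(idx) {
      list(human = sym_of(idx, "GENE"), mouse = sym_of(idx, "Gene"))
    }),
    species_vascular = tibble::tibble(human_symbol = sym_of(sp_vasc, "GENE"),
                                      mouse_symbol = sym_of(sp_vasc, "Gene")),
    species_global = tibble::tibble(human_symbol = sym_of(sp_glob, "GENE"),
                                    mouse_symbol = sym_of(sp_glob, "Gene")),
    species_pericyte = tibble::tibble(
      human_symbol = sym_of(sp_peri, "GENE"),
      mouse_symbol = sym_of(sp_peri, "Gene")),
    classes = classes
  )
  list(human = human, mouse = mouse,
       homology = classify_homology(dplyr::bind_rows(hom)), truth = truth)
}

#' Simulate one bulk (or single-cell) count vector
#'
#' Expected expression is the TPM-space convex combination of the cell-type
#' signatures under the given composition; expected counts are the
#' length-weighted TPM rescaled to the library size; observed counts are
#' negative-binomial draws at the given dispersion (Poisson when
#' `dispersion = 0`).
#'
#' @param signatures Gene-by-cell-type TPM matrix.
#' @param composition Named weights over the signature columns, summing
#'   to 1.
#' @param lengths_kb Per-gene transcript lengths (kilobases).
#' @param library_size Expected total reads.
#' @param dispersion NB dispersion (`var = mu + dispersion * mu^2`).
#' @return Integer count vector named by gene.
#' @export
simulate_sample <- function(signatures, composition, lengths_kb,
                            library_size, dispersion) {
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  composition <- composition[colnames(signatures)]
  tpm <- drop(signatures %*% composition)
  w <- tpm * lengths_kb
  mu <- w / sum(w) * library_size
  counts <- if (dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  stats::setNames(counts, rownames(signatures))
}

#' Simulate a complete two-species microvessel study
#'
#' Emits everything the pipeline consumes: paired microvessel/whole-brain
#' bulk count tables for both species, noisy single-cell reference tables
#' (mouse endothelial and pericyte for the mixture scan, human endothelial
#' for the pericyte subtraction), the homology table, and the ground truth
#' needed to score every downstream stage.
#'
#' @param cfg A [simulation_config()].
#' @return List with `human` and `mouse` (each `counts` tibble +
#'   `metadata`), `reference` (named list of single-cell count tibbles),
#'   `homology`, and `truth` (planted assignments, per-sample pericyte
#'   fraction `alpha`, seed).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  sig <- make_signatures(cfg)
  comps <- sim_compositions(cfg)
  alpha_truth <- unname(comps$microvessel["pericyte"] /
                          (comps$microvessel["pericyte"] +
                             comps$microvessel["endothelial"]))

  species_tables <- function(sp) {
    s <- sig[[sp]]
    samples <- list(); meta <- list()
    for (p in seq_len(cfg$n_pairs)) {
      for (cp in c("microvessel", "whole_brain")) {
        nm <- sprintf("%s_%s_%d", sp, ifelse(cp == "microvessel", "mv", "wb"), p)
        lib <- cfg$library_size * exp(stats::rnorm(1, 0, 0.2))
        samples[[nm]] <- simulate_sample(s$signatures, comps[[cp]],
                                         s$lengths_kb, lib, cfg$dispersion)
        meta[[nm]] <- tibble::tibble(sample = nm, species = sp,
                                     compartment = cp,
                                     pair_id = sprintf("%s_p%d", sp, p))
      }
    }
    counts <- tibble::tibble(gene = s$genes, length_kb = s$lengths_kb,
                             !!!purrr::map(samples, as.integer))
    metadata <- dplyr::bind_rows(meta)
    counts <- validate_counts(counts, metadata)
    list(counts = counts, metadata = metadata)
  }
  human <- species_tables("human")
  mouse <- species_tables("mouse")

  reference_table <- function(sp, type) {
    s <- sig[[sp]]
    comp <- stats::setNames(as.numeric(colnames(s$signatures) == type),
                            colnames(s$signatures))
    cells <- purrr::map(seq_len(cfg$n_reference_cells), function(j) {
      as.integer(simulate_sample(s$signatures, comp, s$lengths_kb,
                                 cfg$reference_library, cfg$dispersion))
    })
    names(cells) <- sprintf("%s_%s_cell_%d", sp, substr(type, 1, 4),
                            seq_len(cfg$n_reference_cells))
    tibble::tibble(gene = s$genes, length_kb = s$lengths_kb, !!!cells)
  }
  reference <- list(
    mouse_endothelial = reference_table("mouse", "endothelial"),
    mouse_pericyte = reference_table("mouse", "pericyte"),
    human_endothelial = reference_table("human", "endothelial"),
    human_pericyte = reference_table("human", "pericyte")
  )

  truth <- c(sig$truth,
             list(alpha = alpha_truth, compositions = comps,
                  signatures = list(human = sig$human$signatures,
                                    mouse = sig$mouse$signatures),
                  seed = cfg$seed))
  list(human = human, mouse = mouse, reference = reference,
       homology = sig$homology, truth = truth, config = cfg)
}
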