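# in-code fixture builders shared across test files

toy_counts <- function(counts_mat, lengths_kb,
                       genes = paste0("g", seq_len(nrow(counts_mat))),
                       samples = paste0("s", seq_len(ncol(counts_mat)))) {
  tbl <- tibble::tibble(gene = genes, length_kb = lengths_kb)
  for (j in seq_along(samples)) tbl[[samples[j]]] <- counts_mat[, j]
  tbl
}

toy_metadata <- function(samples, species = "mouse",
                         compartment = "microvessel",
                         pair_id = paste0("p", seq_along(samples))) {
  tibble::tibble(sample = samples, species = species,
                 compartment = compartment, pair_id = pair_id)
}

toy_profile <- function(tpm, genes = paste0("g", seq_along(tpm)),
                        cell_type = "endothelial") {
  out <- tibble::tibble(gene = genes, length_kb = 1, tpm = tpm)
  attr(out, "cell_type") <- cell_type
  attr(out, "n_cells") <- 1L
  out
}

# paired two-compartment NB study with planted fold changes; returns the
# count tibble (metadata attached) and the per-gene truth
nb_paired_study <- function(n_genes, n_pairs, dispersion = 0.1,
                            frac_de = 0, log2fc = 0, base_meanlog = 4,
                            library_factor = NULL, seed = 1) {
  set.seed(seed)
  base <- stats::rlnorm(n_genes, base_meanlog, 1)
  is_de <- rep(FALSE, n_genes)
  if (frac_de > 0) {
    is_de[sample.int(n_genes, round(frac_de * n_genes))] <- TRUE
  }
  fold <- ifelse(is_de, 2^log2fc, 1)
  samples <- character(0)
  tbl <- tibble::tibble(gene = paste0("g", seq_len(n_genes)), length_kb = 2)
  meta <- list()
  for (p in seq_len(n_pairs)) {
    pair_eff <- exp(stats::rnorm(1, 0, 0.2))
    for (cp in c("microvessel", "whole_brain")) {
      nm <- sprintf("%s_%d", ifelse(cp == "microvessel", "mv", "wb"), p)
      lib <- if (is.null(library_factor)) 1 else library_factor[[nm]]
      mu <- base * pair_eff * lib * (if (cp == "microvessel") fold else 1)
      tbl[[nm]] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      meta[[nm]] <- toy_metadata(nm, compartment = cp,
                                 pair_id = paste0("p", p))
      samples <- c(samples, nm)
    }
  }
  attr(tbl, "metadata") <- dplyr::bind_rows(meta)
  list(counts = tbl, is_de = is_de)
}

# literal step-up BH: for each i, min over j >= i of m*p_(j)/j (capped)
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# brute-force running-sum ES by direct enumeration
es_brute <- function(scores, hits, weight_exponent = 1) {
  n <- length(scores)
  w <- abs(scores)^weight_exponent
  wsum <- sum(w[hits])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) w[i] / wsum else -1 / (n - sum(hits))
    if (abs(run) > abs(best)) best <- run
  }
  best
}
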