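#' Rank genes for pre-ranked enrichment
#'
#' Scores each tested gene as `-log10(p) * sign(log2fc)`, so
#' high-confidence microvessel-enriched genes sit at the top of the list and
#' high-confidence depleted genes at the bottom. Untested genes are omitted;
#' `p = 0` is clamped to the smallest positive double before the log. Ties
#' are broken by gene identifier.
#'
#' @param de DE tibble (from [differential_expression()]).
#' @return Tibble with `gene`, `score`, ordered by score descending.
#' @export
rank_genes <- function(de) {
  d <- de[!is.na(de$wald_p) & !is.na(de$log2fc), ]
  score <- -log10(pmax(d$wald_p, .Machine$double.xmin)) * sign(d$log2fc)
  out <- tibble::tibble(gene = d$gene, score = score)
  out[order(-out$score, out$gene), ]
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1))
}

# ES from sorted hit positions: increments |score|^w / W at hits, constant
# decrement 1/(N - k) at misses; extremum of the running sum, which is only
# attained immediately before or after a hit
es_from_positions <- function(pos, hit_weights, n_total) {
  k <- length(pos)
  w_sum <- sum(hit_weights)
  if (w_sum == 0) hit_weights <- rep(1 / k, k) * (w_sum <- 1)
  miss_dec <- if (n_total > k) 1 / (n_total - k) else 0
  cw <- cumsum(hit_weights) / w_sum
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * miss_dec
  after <- cw - (pos - seq_len(k)) * miss_dec
  vals <- c(before, after)
  vals[which.max(abs(vals))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^w / sum(|score|^w)` at set
#' members and `-1/(N - N_hit)` at non-members; the enrichment score is the
#' extremum of the running sum (signed, in `[-1, 1]`).
#'
#' @param ranked Ranked tibble from [rank_genes()].
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Weight on `|score|`; 1 gives the classic weighted
#'   statistic, 0 the unweighted Kolmogorov-Smirnov form.
#' @return List with `es` and `running` (tibble `position`, `gene`, `hit`,
#'   `running_sum`).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) stop("gene set does not intersect the ranked list")
  w <- abs(ranked$score)^weight_exponent
  w_hit_sum <- sum(w[hit])
  inc <- if (w_hit_sum > 0) w * hit / w_hit_sum else hit / sum(hit)
  dec <- (!hit) / max(n - sum(hit), 1)
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(
    es = es,
    running = tibble::tibble(position = seq_len(n), gene = ranked$gene,
                             hit = hit, running_sum = running)
  )
}

#' Pre-ranked gene-set enrichment with permutation p-values
#'
#' Computes the enrichment score of each set against the ranked list and a
#' nominal p-value by gene-label permutation: random same-size sets drawn
#' from the ranked universe, `p = (1 + #{|ES*| >= |ES|}) / (1 + n_perm)`.
#' Gene-set permutation is used because the ranking metric is derived from
#' the differential-expression output, leaving no phenotype labels to
#' permute. FDR q-values are not computed; nominal p-values are reported.
#'
#' @param ranked Ranked tibble from [rank_genes()].
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed; identical seed and inputs give identical
#'   output.
#' @param min_size,max_size Sets outside these bounds (after intersection
#'   with the ranked universe) are skipped with a message.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Tibble with `gene_set`, `size`, `es`, `nominal_p`, `n_perm`.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, seed = 1,
                           min_size = 5, max_size = 500,
                           weight_exponent = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  n <- nrow(ranked)
  w_all <- abs(ranked$score)^weight_exponent
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  skipped <- character(0)
  res <- purrr::imap(gene_sets, function(members, name) {
    pos <- sort(which(ranked$gene %in% members))
    k <- length(pos)
    if (k < min_size || k > max_size) {
      skipped <<- c(skipped, name)
      return(NULL)
    }
    es <- es_from_positions(pos, w_all[pos], n)
    perm_ge <- 0L
    for (b in seq_len(n_perm)) {
      ppos <- sort(sample.int(n, k))
      if (abs(es_from_positions(ppos, w_all[ppos], n)) >= abs(es)) {
        perm_ge <- perm_ge + 1L
      }
    }
    tibble::tibble(gene_set = name, size = k, es = es,
                   nominal_p = (1 + perm_ge) / (1 + n_perm), n_perm = n_perm)
  })
  if (length(skipped) > 0L) {
    message(length(skipped), " set(s) outside size bounds skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  dplyr::bind_rows(purrr::compact(res))
}

#' Hierarchical clustering on one-minus-Pearson distance
#'
#' Average-linkage (UPGMA) agglomeration on the distance
#' `d = 1 - r_pearson` between samples (or genes). Genes can optionally be
#' normalised first as the z-score of `log2(TPM + 1)`, the convention used
#' for row-normalised expression heat maps.
#'
#' @param expr Expression tibble (`gene`, optional `length_kb`, sample
#'   columns).
#' @param axis Cluster `"samples"` (default) or `"genes"`.
#' @param normalize `"none"` or `"zscore_log"` (per-gene z-score of
#'   `log2(x + 1)` before computing correlations).
#' @return List with `hclust` (a [stats::hclust] object) and `leaf_order`
#'   (labels in dendrogram order).
#' @export
hier_cluster <- function(expr, axis = c("samples", "genes"),
                         normalize = c("none", "zscore_log")) {
  axis <- match.arg(axis)
  normalize <- match.arg(normalize)
  m <- as.matrix(expr[, count_sample_cols(expr), drop = FALSE])
  rownames(m) <- expr$gene
  if (normalize == "zscore_log") {
    lm2 <- log2(m + 1)
    mu <- rowMeans(lm2)
    s <- apply(lm2, 1, stats::sd)
    keep <- s > 0
    m <- (lm2[keep, , drop = FALSE] - mu[keep]) / s[keep]
  }
  items <- if (axis == "samples") m else t(m)
  sds <- apply(items, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s): ", paste(colnames(items)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(items))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, leaf_order = hc$labels[hc$order])
}

#' PCA of samples on expression values
#'
#' Gene-centred (unscaled) principal component analysis of samples; TPM is
#' the conventional input, with an optional `log2(x + 1)` transform.
#'
#' @param expr Expression tibble.
#' @param log_transform Apply `log2(x + 1)` first (default `FALSE`).
#' @param n_components Number of components to keep (default: all
#'   available).
#' @return A `pca_summary` object: list with `coordinates` (tibble
#'   `sample`, `PC1`, ...), `variance_explained` (fractions), `sdev`.
#' @export
pca_summary <- function(expr, log_transform = FALSE, n_components = NULL) {
  samples <- count_sample_cols(expr)
  if (length(samples) < 2L) stop("PCA needs at least 2 samples")
  m <- as.matrix(expr[, samples, drop = FALSE])
  if (log_transform) m <- log2(m + 1)
  x <- t(m)  # samples as rows, genes as variables
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) ncol(pc$x) else min(n_components, ncol(pc$x))
  coords <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  coords <- dplyr::bind_cols(tibble::tibble(sample = samples), coords)
  out <- list(coordinates = coords, variance_explained = var_frac[seq_len(k)],
              sdev = pc$sdev)
  class(out) <- "pca_summary"
  out
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("PCA of", nrow(x$coordinates), "samples;",
      "PC1 =", sprintf("%.1f%%,", 100 * x$variance_explained[1]),
      "PC2 =", if (length(x$variance_explained) > 1) {
        sprintf("%.1f%%", 100 * x$variance_explained[2])
      } else "-", "\n")
  invisible(x)
}

#' Tidy PCA coordinates
#'
#' @param x A `pca_summary` object.
#' @param ... Unused.
#' @return The coordinates tibble.
#' @method tidy pca_summary
#' @export
tidy.pca_summary <- function(x, ...) x$coordinates

#' Variance explained per component
#'
#' @param x A `pca_summary` object.
#' @param ... Unused.
#' @return Tibble with `component`, `variance_fraction`.
#' @method glance pca_summary
#' @export
glance.pca_summary <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$variance_explained)),
                 variance_fraction = x$variance_explained)
}

#' Scatter plot of the first two principal components
#'
#' @param object A `pca_summary` object.
#' @param metadata Optional sample sheet; points are coloured by
#'   compartment and shaped by species when present.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_summary
#' @export
autoplot.pca_summary <- function(object, metadata = NULL, ...) {
  d <- object$coordinates
  if (!"PC2" %in% names(d)) d$PC2 <- 0
  aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if (!is.null(metadata)) {
    d <- dplyr::left_join(d, metadata, by = "sample")
    aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2,
                        colour = .data$compartment, shape = .data$species)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * object$variance_explained[min(2, length(object$variance_explained))])
    ) +
    ggplot2::theme_minimal()
}
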