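#' Median-of-ratios size factors
#'
#' Per-sample scale factors estimated as the median, over genes with
#' all-positive counts, of the ratio of the gene's count to its geometric
#' mean across samples; the factors themselves are rescaled to geometric
#' mean 1. When no gene is positive in every sample the ratio set falls back
#' to genes positive in at least half of the samples (a message records the
#' fallback), with each gene's geometric mean taken over its positive
#' entries.
#'
#' @param counts Count tibble (`gene`, `length_kb`, sample columns).
#' @return Tibble with columns `sample`, `size_factor` (all positive,
#'   geometric mean 1).
#' @export
estimate_size_factors <- function(counts) {
  m <- as.matrix(counts[, count_sample_cols(counts), drop = FALSE])
  if (any(colSums(m) == 0)) stop("every sample needs at least one nonzero count")
  logm <- log(m)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    loggeo <- rowMeans(logm[all_pos, , drop = FALSE])
    sf <- apply(logm[all_pos, , drop = FALSE], 2, function(col) {
      exp(stats::median(col - loggeo))
    })
  } else {
    message("no gene positive in all samples; falling back to genes positive in >= half")
    ok <- rowSums(m > 0) >= ncol(m) / 2
    if (!any(ok)) stop("too few genes with positive counts to estimate size factors")
    sub <- m[ok, , drop = FALSE]
    loggeo <- apply(sub, 1, function(r) mean(log(r[r > 0])))
    sf <- vapply(seq_len(ncol(sub)), function(j) {
      r <- sub[, j]
      exp(stats::median(log(r[r > 0]) - loggeo[r > 0]))
    }, numeric(1))
  }
  sf <- sf / exp(mean(log(sf)))
  tibble::tibble(sample = count_sample_cols(counts), size_factor = unname(sf))
}

#' Method-of-moments per-gene dispersion
#'
#' Estimates the negative-binomial dispersion of each gene from normalized
#' counts as `alpha = max((s^2 - mu) / mu^2, alpha_floor)`. The estimator is
#' deliberately design-blind: a between-group mean shift inflates the
#' apparent dispersion of genuinely differential genes, which costs some
#' power but keeps the Wald test conservative; no shrinkage toward a trend
#' is applied. Genes with zero mean are returned with `NA` dispersion.
#'
#' @param counts Count tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param alpha_floor Lower bound absorbing under-dispersion (default 1e-8).
#' @return Tibble with `gene`, `base_mean`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, size_factors, alpha_floor = 1e-8) {
  samples <- count_sample_cols(counts)
  if (length(samples) < 2L) stop("dispersion estimation needs >= 2 samples")
  m <- as.matrix(counts[, samples, drop = FALSE])
  sf <- size_factors$size_factor[match(samples, size_factors$sample)]
  k <- sweep(m, 2, sf, "/")
  mu <- rowMeans(k)
  s2 <- apply(k, 1, stats::var)
  alpha <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, alpha_floor), NA_real_)
  tibble::tibble(gene = counts$gene, base_mean = mu, dispersion = alpha)
}

#' Group-aware, median-floored dispersion for two-group testing
#'
#' Applies the method-of-moments estimator of [estimate_dispersion()]
#' within each condition group (so a genuine between-group fold change is
#' not absorbed into the variance), pools the group estimates weighted by
#' their residual degrees of freedom, and floors every gene at the
#' cross-gene median of the pooled estimates. The floor is the minimal
#' stabilisation that keeps the Wald test calibrated with few replicates:
#' with 2-4 residual degrees of freedom per gene, a sizeable fraction of
#' per-gene estimates collapse toward zero by chance and would otherwise
#' produce arbitrarily large Wald statistics.
#'
#' @param counts Count tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param condition Group label per sample column.
#' @param alpha_floor Absolute lower bound (default 1e-8).
#' @return Tibble with `gene`, `base_mean`, `dispersion`,
#'   `dispersion_raw`.
#' @export
moderated_dispersion <- function(counts, size_factors, condition,
                                 alpha_floor = 1e-8) {
  samples <- count_sample_cols(counts)
  if (length(condition) != length(samples)) {
    stop("condition must have one label per sample column")
  }
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in unique(condition)) {
    idx <- samples[condition == g]
    if (length(idx) < 2L) next
    d <- estimate_dispersion(counts[, c("gene", "length_kb", idx)],
                             size_factors[size_factors$sample %in% idx, ],
                             alpha_floor = alpha_floor)
    ok <- !is.na(d$dispersion)
    w <- length(idx) - 1
    num[ok] <- num[ok] + w * d$dispersion[ok]
    den[ok] <- den[ok] + w
  }
  if (all(den == 0)) stop("no condition group has >= 2 samples")
  raw <- ifelse(den > 0, num / den, NA_real_)
  floor_val <- stats::median(raw, na.rm = TRUE)
  m <- as.matrix(counts[, samples, drop = FALSE])
  sf <- size_factors$size_factor[match(samples, size_factors$sample)]
  tibble::tibble(gene = counts$gene,
                 base_mean = rowMeans(sweep(m, 2, sf, "/")),
                 dispersion = pmax(raw, floor_val),
                 dispersion_raw = raw)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1 and mapped back to
#' input order; `NA` entries are passed through and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  ord <- ok[order(p[ok])]
  adj <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  out[ord] <- adj
  out
}

# NB log-link IRLS with fixed dispersion; returns last-coefficient estimate
# and SE (natural-log scale), or NULL on non-convergence
fit_nb_gene <- function(y, X, log_sf, alpha, max_iter = 50L, tol = 1e-8) {
  beta <- tryCatch(qr.solve(X, log((y + 0.5) / exp(log_sf))),
                   error = function(e) rep(0, ncol(X)))
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta + log_sf)
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) {
      eta <- pmin(pmax(drop(X %*% beta), -30), 30)
      mu <- exp(eta + log_sf)
      w <- mu / (1 + alpha * mu)
      xtwx <- crossprod(X, X * w)
      cov <- tryCatch(solve(xtwx), error = function(e) NULL)
      if (is.null(cov)) return(NULL)
      return(list(beta = unname(beta), se = unname(sqrt(diag(cov)))))
    }
  }
  NULL
}

#' Paired negative-binomial Wald test
#'
#' Per gene, fits a log-link negative-binomial regression
#' `mu = sf * exp(b0 + pair effects + b_c * condition)` by iteratively
#' reweighted least squares at fixed per-gene dispersion, and tests
#' `b_c = 0` with a Wald z statistic against the standard normal. Pairing is
#' encoded as fixed-effect indicators. The reported fold change is
#' `log2fc = b_c / ln 2` for the contrast group over the reference group.
#'
#' Genes with all-zero counts are skipped (`status = "low_count_skipped"`).
#' Genes with complete separation (one group entirely zero) are refit with a
#' 0.5 pseudocount added to that gene's counts and flagged
#' (`status = "pseudocount"`). Non-converging fits are flagged with absent
#' p-values.
#'
#' @param counts Count tibble for the samples under test.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param dispersions Tibble from [estimate_dispersion()].
#' @param condition Factor/character vector, one label per sample column;
#'   must have exactly two levels.
#' @param contrast Length-2 character: `c(test_group, reference_group)`;
#'   positive `log2fc` means enrichment in the test group.
#' @param pairing Optional vector of pair identifiers, one per sample column.
#' @return Tibble with `gene`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `wald_p`, `padj`, `status`.
#' @export
wald_test_nb <- function(counts, size_factors, dispersions, condition,
                         contrast, pairing = NULL) {
  samples <- count_sample_cols(counts)
  condition <- as.character(condition)
  if (length(condition) != length(samples)) {
    stop("condition must have one label per sample column")
  }
  if (!setequal(unique(condition), contrast) || length(contrast) != 2L) {
    stop("contrast must name exactly the two condition levels")
  }
  cond <- factor(condition, levels = c(contrast[2], contrast[1]))
  if (!is.null(pairing)) {
    pairing <- as.character(pairing)
    tab <- table(pairing, cond)
    if (any(tab == 0)) stop("every pair needs a sample in both conditions")
    X <- stats::model.matrix(~ factor(pairing) + cond)
  } else {
    X <- stats::model.matrix(~ cond)
  }
  m <- as.matrix(counts[, samples, drop = FALSE])
  sf <- size_factors$size_factor[match(samples, size_factors$sample)]
  log_sf <- log(sf)
  disp <- dispersions$dispersion[match(counts$gene, dispersions$gene)]
  base_mean <- rowMeans(sweep(m, 2, sf, "/"))
  grp_test <- cond == contrast[1]
  ln2 <- log(2)

  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    out <- tibble::tibble(gene = counts$gene[i], base_mean = base_mean[i],
                          log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                          wald_p = NA_real_, status = "tested")
    if (all(y == 0) || is.na(disp[i])) {
      out$status <- "low_count_skipped"
      return(out)
    }
    separated <- all(y[grp_test] == 0) || all(y[!grp_test] == 0)
    if (separated) {
      y <- y + 0.5
      out$status <- "pseudocount"
    }
    fit <- fit_nb_gene(y, X, log_sf, disp[i])
    if (is.null(fit)) {
      out$status <- "not_converged"
      return(out)
    }
    j <- ncol(X)
    out$log2fc <- fit$beta[j] / ln2
    out$se <- fit$se[j] / ln2
    out$stat <- fit$beta[j] / fit$se[j]
    out$wald_p <- 2 * stats::pnorm(-abs(out$stat))
    out
  })
  res$padj <- bh_adjust(res$wald_p)
  attr(res, "contrast") <- contrast
  res
}

#' Differential expression between two sample groups
#'
#' Orchestrates size-factor estimation, group-aware method-of-moments
#' dispersion, the (optionally paired) negative-binomial Wald test, and
#' Benjamini-Hochberg adjustment. A gene is called enriched in the test
#' group when `padj < padj_threshold` and `log2fc > 0`, depleted when
#' `padj < padj_threshold` and `log2fc < 0`.
#'
#' @param counts Count tibble (`gene`, `length_kb`, sample columns).
#' @param metadata Sample sheet tibble (`sample` plus the grouping columns);
#'   defaults to the `"metadata"` attribute of `counts`.
#' @param contrast Length-2 character `c(test_group, reference_group)` of
#'   levels of `group_var`.
#' @param group_var Metadata column holding the contrast groups
#'   (default `"compartment"`).
#' @param paired Include fixed-effect pair indicators (default `TRUE`).
#' @param pair_var Metadata column holding pair identifiers.
#' @param padj_threshold Significance threshold on adjusted p (default 0.05).
#' @return DE tibble (see [wald_test_nb()]) with an added `enriched` /
#'   `depleted` call column `direction`; attributes `contrast` and
#'   `padj_threshold`.
#' @export
differential_expression <- function(counts, metadata = NULL,
                                    contrast = c("microvessel", "whole_brain"),
                                    group_var = "compartment", paired = TRUE,
                                    pair_var = "pair_id",
                                    padj_threshold = 0.05) {
  if (is.null(metadata)) metadata <- attr(counts, "metadata")
  if (is.null(metadata)) stop("sample metadata required")
  keep <- metadata$sample[metadata[[group_var]] %in% contrast]
  samples <- intersect(count_sample_cols(counts), keep)
  if (length(samples) < 2L) stop("contrast selects fewer than 2 samples")
  sub <- counts[, c("gene", "length_kb", samples)]
  meta <- metadata[match(samples, metadata$sample), ]
  condition <- meta[[group_var]]
  pairing <- if (paired) meta[[pair_var]] else NULL
  sf <- estimate_size_factors(sub)
  disp <- moderated_dispersion(sub, sf, condition)
  res <- wald_test_nb(sub, sf, disp, condition, contrast, pairing)
  res$direction <- dplyr::case_when(
    !is.na(res$padj) & res$padj < padj_threshold & res$log2fc > 0 ~ "enriched",
    !is.na(res$padj) & res$padj < padj_threshold & res$log2fc < 0 ~ "depleted",
    TRUE ~ "ns"
  )
  attr(res, "contrast") <- contrast
  attr(res, "padj_threshold") <- padj_threshold
  res
}

#' Volcano plot of a differential-expression table
#'
#' @param de DE tibble from [differential_expression()].
#' @param padj_threshold Threshold used to colour calls (default: the
#'   table's own).
#' @return A ggplot.
#' @export
plot_volcano <- function(de, padj_threshold = NULL) {
  if (is.null(padj_threshold)) {
    padj_threshold <- attr(de, "padj_threshold") %||% 0.05
  }
  d <- dplyr::filter(de, !is.na(.data$wald_p))
  d$neglog10p <- -log10(pmax(d$wald_p, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$neglog10p,
                                  colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(enriched = "#c0392b",
                                            depleted = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p (Wald)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
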