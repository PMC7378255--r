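#' Blend two reference TPM profiles
#'
#' Convex combination of pericyte and endothelial reference profiles,
#' `TPM_alpha = alpha * TPM_peri + (1 - alpha) * TPM_endo`, on the
#' intersection of their gene universes. `alpha` is the fraction of
#' transcripts attributed to pericytes.
#'
#' @param peri,endo Reference profiles (tibbles with `gene` and `tpm`
#'   columns, as from [average_reference_profile()]).
#' @param alpha Pericyte fraction in `[0, 1]`.
#' @return Tibble with columns `gene`, `tpm`.
#' @export
blend_references <- function(peri, endo, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  shared <- intersect(peri$gene, endo$gene)
  if (length(shared) == 0L) stop("reference profiles share no genes")
  p <- peri$tpm[match(shared, peri$gene)]
  e <- endo$tpm[match(shared, endo$gene)]
  tibble::tibble(gene = shared, tpm = alpha * p + (1 - alpha) * e)
}

#' Correlate two expression vectors
#'
#' Pearson or Spearman correlation on raw (untransformed) values over the
#' full shared gene universe, zeros included. The p-value comes from the
#' Student-t transform of the coefficient with `n - 2` degrees of freedom;
#' Spearman ranks use average ranks for ties.
#'
#' @param x,y Numeric vectors aligned on the same gene universe.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble with `estimate`, `p_value`, `n`, `method`.
#' @export
correlate_expression <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("x has zero variance; correlation undefined")
  if (stats::sd(y) == 0) stop("y has zero variance; correlation undefined")
  r <- stats::cor(x, y, method = method)
  r <- min(1, max(-1, r))
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(estimate = r, p_value = p, n = n, method = method)
}

#' Scan pericyte/endothelial blend ratios against a bulk sample
#'
#' Evaluates the Pearson (and Spearman) correlation between a bulk
#' microvessel TPM vector and reference blends over a grid of pericyte
#' fractions `alpha in {0, step, ..., 1}`, and reports the
#' correlation-maximising blend. When replicate columns are supplied the
#' bulk vector is their arithmetic mean, computed before scanning.
#'
#' Correlations are computed on raw TPM over the intersection of the bulk
#' and reference gene universes, undetected transcripts retained; at exact
#' ties in the Pearson curve the smallest `alpha` wins.
#'
#' @param bulk Either a TPM expression tibble (`gene` plus one or more
#'   replicate columns) or a named numeric TPM vector.
#' @param peri,endo Reference profiles (see [average_reference_profile()]).
#' @param step Grid spacing, in `(0, 0.5]`; default 0.01 (compositions are
#'   reported to the nearest percent).
#' @return A `mixture_scan` object: list with `grid` (tibble of `alpha`,
#'   `r_p`, `p_p`, `r_s`), `alpha_hat`, `r_p_max`, `r_s_at_argmax`,
#'   `n_genes_used`.
#' @export
scan_mixture_ratio <- function(bulk, peri, endo, step = 0.01) {
  if (step <= 0 || step > 0.5) stop("step must lie in (0, 0.5]")
  if (is.data.frame(bulk)) {
    reps <- setdiff(names(bulk), c("gene", "length_kb", "tpm"))
    vals <- if (length(reps) > 0L) {
      rowMeans(as.matrix(bulk[, reps, drop = FALSE]))
    } else {
      bulk$tpm
    }
    bulk_vec <- stats::setNames(vals, bulk$gene)
  } else {
    if (is.null(names(bulk))) stop("bulk vector must be named by gene")
    bulk_vec <- bulk
  }
  shared <- Reduce(intersect, list(names(bulk_vec), peri$gene, endo$gene))
  if (length(shared) < 3L) stop("fewer than 3 genes shared by bulk and references")
  b <- bulk_vec[shared]
  p <- peri$tpm[match(shared, peri$gene)]
  e <- endo$tpm[match(shared, endo$gene)]
  alphas <- seq(0, 1, by = step)
  if (alphas[length(alphas)] < 1) alphas <- c(alphas, 1)

  grid <- purrr::map_dfr(alphas, function(a) {
    blend <- a * p + (1 - a) * e
    cp <- correlate_expression(b, blend, "pearson")
    cs <- correlate_expression(b, blend, "spearman")
    tibble::tibble(alpha = a, r_p = cp$estimate, p_p = cp$p_value,
                   r_s = cs$estimate)
  })
  i_hat <- which.max(grid$r_p)  # first maximum at exact ties
  out <- list(
    grid = grid,
    alpha_hat = grid$alpha[i_hat],
    r_p_max = grid$r_p[i_hat],
    r_s_at_argmax = grid$r_s[i_hat],
    n_genes_used = length(shared)
  )
  class(out) <- "mixture_scan"
  out
}

#' @export
print.mixture_scan <- function(x, ...) {
  cat("Mixture-ratio scan over", nrow(x$grid), "blends of",
      x$n_genes_used, "shared genes\n")
  cat(sprintf("  alpha_hat (pericyte fraction): %.2f\n", x$alpha_hat))
  cat(sprintf("  r_p at optimum: %.3f   r_s at optimum: %.3f\n",
              x$r_p_max, x$r_s_at_argmax))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mixture scan into its correlation grid
#'
#' @param x A `mixture_scan` object.
#' @param ... Unused.
#' @return The grid tibble (`alpha`, `r_p`, `p_p`, `r_s`).
#' @method tidy mixture_scan
#' @export
tidy.mixture_scan <- function(x, ...) x$grid

#' One-row summary of a mixture scan
#'
#' @param x A `mixture_scan` object.
#' @param ... Unused.
#' @return Tibble with `alpha_hat`, `r_p_max`, `r_s_at_argmax`,
#'   `n_genes_used`.
#' @method glance mixture_scan
#' @export
glance.mixture_scan <- function(x, ...) {
  tibble::tibble(alpha_hat = x$alpha_hat, r_p_max = x$r_p_max,
                 r_s_at_argmax = x$r_s_at_argmax,
                 n_genes_used = x$n_genes_used)
}

#' Plot the Pearson correlation curve of a mixture scan
#'
#' @param object A `mixture_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mixture_scan
#' @export
autoplot.mixture_scan <- function(object, ...) {
  grid <- object$grid
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$alpha, y = .data$r_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$alpha_hat, linetype = "dashed") +
    ggplot2::labs(
      x = "pericyte fraction of blended reference",
      y = "Pearson r vs bulk microvessel TPM",
      title = sprintf("Optimal blend: %.0f%% pericyte (r_p = %.2f)",
                      100 * object$alpha_hat, object$r_p_max)
    ) +
    ggplot2::theme_minimal()
}
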