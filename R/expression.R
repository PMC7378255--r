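#' Read a gene-level count table
#'
#' Reads a tab-separated count table whose first column holds gene
#' identifiers, second column per-gene transcript length in kilobases, and
#' remaining columns integer read counts, one column per sample. When a
#' metadata path is supplied the sample sheet is read, validated against the
#' count columns, and attached as the `"metadata"` attribute.
#'
#' Genes with missing or non-positive length are dropped with a warning
#' reporting how many rows were removed; alignment and length estimation are
#' upstream concerns, so length is treated as opaque input.
#'
#' @param path Path to the count TSV (columns: gene, length_kb, samples...).
#' @param metadata_path Optional path to a sample sheet TSV with columns
#'   `sample`, `species`, `compartment`, `pair_id`.
#' @return A tibble with columns `gene`, `length_kb` and one integer column
#'   per sample; metadata (if given) attached as attribute `"metadata"`.
#' @export
read_counts <- function(path, metadata_path = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 3L) {
    stop("count table must have columns gene, length_kb and at least one sample; got ",
         paste(names(tbl), collapse = ", "))
  }
  names(tbl)[1:2] <- c("gene", "length_kb")
  meta <- if (!is.null(metadata_path)) read_sample_metadata(metadata_path) else NULL
  validate_counts(tbl, metadata = meta)
}

#' Read a sample metadata sheet
#'
#' @param path TSV with columns `sample`, `species`, `compartment`, `pair_id`.
#' @return A tibble with those columns.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample", "species", "compartment", "pair_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample)) {
    stop("duplicated sample identifier in metadata: ",
         paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
  }
  bad_sp <- setdiff(unique(meta$species), c("human", "mouse"))
  if (length(bad_sp) > 0L) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "))
  }
  bad_cp <- setdiff(unique(meta$compartment),
                    c("microvessel", "whole_brain", "reference"))
  if (length(bad_cp) > 0L) {
    stop("unknown compartment label(s): ", paste(bad_cp, collapse = ", "))
  }
  tibble::as_tibble(meta)
}

#' Validate (and canonicalise) a count tibble
#'
#' Enforces the count-matrix contract: unique gene identifiers, integer-valued
#' non-negative counts, strictly positive lengths (offending genes dropped
#' with a warning), and, when metadata is supplied, metadata for every sample
#' column.
#'
#' @param counts Tibble with columns `gene`, `length_kb`, then sample columns.
#' @param metadata Optional sample sheet tibble; attached as attribute.
#' @return The validated tibble.
#' @export
validate_counts <- function(counts, metadata = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("gene", "length_kb") %in% names(counts))) {
    stop("count table must contain 'gene' and 'length_kb' columns")
  }
  dup <- unique(counts$gene[duplicated(counts$gene)])
  if (length(dup) > 0L) {
    stop("duplicated gene identifier(s): ", paste(dup, collapse = ", "))
  }
  sample_cols <- count_sample_cols(counts)
  for (s in sample_cols) {
    v <- counts[[s]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("non-numeric or missing count in sample column '", s, "'")
    }
    if (any(v < 0)) stop("negative count in sample column '", s, "'")
    if (any(abs(v - round(v)) > 1e-8)) {
      stop("non-integer count in sample column '", s, "'")
    }
  }
  bad_len <- is.na(counts$length_kb) | counts$length_kb <= 0
  if (any(bad_len)) {
    warning(sum(bad_len), " gene(s) dropped for missing or non-positive length")
    counts <- counts[!bad_len, , drop = FALSE]
  }
  if (!is.null(metadata)) {
    unknown <- setdiff(sample_cols, metadata$sample)
    if (length(unknown) > 0L) {
      stop("sample column(s) absent from metadata: ",
           paste(unknown, collapse = ", "))
    }
    attr(counts, "metadata") <- metadata
  }
  counts
}

# sample columns of a counts/expression tibble = everything except annotation
count_sample_cols <- function(tbl) {
  setdiff(names(tbl), c("gene", "length_kb"))
}

#' Compute FPKM from counts
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM_i = counts_i / (L_i * sum(counts)) * 1e6` per sample, with `L_i` the
#' transcript length in kilobases. Samples with zero total counts are emitted
#' as all-zero columns and recorded in the `"zero_depth"` attribute.
#'
#' @param counts Validated count tibble (`gene`, `length_kb`, samples).
#' @return Expression tibble of the same shape with attribute `unit = "FPKM"`.
#' @export
compute_fpkm <- function(counts) {
  counts <- tibble::as_tibble(counts)
  samples <- count_sample_cols(counts)
  out <- counts
  zero_depth <- character(0)
  for (s in samples) {
    tot <- sum(counts[[s]])
    if (tot == 0) {
      zero_depth <- c(zero_depth, s)
      out[[s]] <- rep(0, nrow(counts))
    } else {
      out[[s]] <- counts[[s]] / (counts$length_kb * tot) * 1e6
    }
  }
  if (length(zero_depth) > 0L) {
    warning("zero-depth sample(s) emitted as all-zero: ",
            paste(zero_depth, collapse = ", "))
  }
  attr(out, "unit") <- "FPKM"
  attr(out, "zero_depth") <- zero_depth
  attr(out, "metadata") <- attr(counts, "metadata")
  out
}

#' Compute TPM from FPKM
#'
#' Transcripts per million: `TPM_i = FPKM_i / sum(FPKM) * 1e6` per sample, so
#' every non-degenerate column sums to exactly one million.
#'
#' @param fpkm Expression tibble with unit FPKM (as from [compute_fpkm()]).
#' @return Expression tibble with attribute `unit = "TPM"`.
#' @export
compute_tpm <- function(fpkm) {
  unit <- attr(fpkm, "unit")
  if (!is.null(unit) && !identical(unit, "FPKM")) {
    stop("compute_tpm() expects FPKM input, got unit '", unit, "'")
  }
  fpkm <- tibble::as_tibble(fpkm)
  samples <- count_sample_cols(fpkm)
  out <- fpkm
  zero_depth <- character(0)
  for (s in samples) {
    tot <- sum(fpkm[[s]])
    if (tot == 0) {
      zero_depth <- c(zero_depth, s)
      out[[s]] <- rep(0, nrow(fpkm))
    } else {
      out[[s]] <- fpkm[[s]] / tot * 1e6
    }
  }
  attr(out, "unit") <- "TPM"
  attr(out, "zero_depth") <- zero_depth
  attr(out, "metadata") <- attr(fpkm, "metadata")
  out
}

#' Counts to TPM in one step
#'
#' Convenience composition of [compute_fpkm()] then [compute_tpm()].
#'
#' @inheritParams compute_fpkm
#' @return TPM expression tibble.
#' @export
tpm_from_counts <- function(counts) {
  compute_tpm(compute_fpkm(counts))
}

#' Average single cells into a reference TPM profile
#'
#' Raw counts are averaged across all cells of the table, then length
#' normalised into a single TPM vector summing to one million — the reference
#' construction used for purified endothelial and pericyte profiles.
#'
#' @param counts Count tibble whose sample columns are single cells of one
#'   cell type.
#' @param cell_type Label for the profile (e.g. `"endothelial"`,
#'   `"pericyte"`).
#' @return Tibble with columns `gene`, `length_kb`, `tpm`; attributes
#'   `cell_type` and `n_cells`.
#' @export
average_reference_profile <- function(counts, cell_type) {
  counts <- tibble::as_tibble(counts)
  cells <- count_sample_cols(counts)
  if (length(cells) == 0L) stop("no cell columns to average")
  avg <- rowMeans(as.matrix(counts[, cells, drop = FALSE]))
  pseudo <- tibble::tibble(
    gene = counts$gene,
    length_kb = counts$length_kb,
    mean_count = avg
  )
  fpkm <- pseudo$mean_count / (pseudo$length_kb * sum(pseudo$mean_count)) * 1e6
  tpm <- fpkm / sum(fpkm) * 1e6
  out <- tibble::tibble(gene = counts$gene, length_kb = counts$length_kb, tpm = tpm)
  attr(out, "cell_type") <- cell_type
  attr(out, "n_cells") <- length(cells)
  out
}

#' Write an expression or count tibble to TSV
#'
#' Mirrors the input layout; the unit (if any) is recorded in a leading
#' comment line.
#'
#' @param x Expression or count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  unit <- attr(x, "unit")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(unit)) writeLines(paste0("# unit: ", unit), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
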