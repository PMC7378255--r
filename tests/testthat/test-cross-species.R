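xsp_fixture <- function() {
  ht <- tibble::tibble(
    human_symbol = c("H1", "H2", "H2", "H3", "H4", "H5", "H6"),
    mouse_symbol = c("m1", "m2", "m3", "m4", "m4", "m5", "m6"))
  human_tpm <- tibble::tibble(
    gene = c("H1", "H2", "H3", "H4", "H5", "H6"),
    hs1 = c(10, 8, 40, 35, 3, 12),
    hs2 = c(10, 8, 40, 35, 3, 12))
  mouse_tpm <- tibble::tibble(
    gene = c("m1", "m2", "m3", "m4", "m5", "m6"),
    ms1 = c(9, 5, 7, 20, 4, 11),
    ms2 = c(9, 5, 7, 20, 4, 11))
  list(ht = classify_homology(ht), h = human_tpm, m = mouse_tpm)
}

test_that("homology classes follow pair multiplicity", {
  fx <- xsp_fixture()
  cls <- fx$ht
  expect_equal(cls$homology_class[cls$human_symbol == "H1"], "one_to_one")
  expect_equal(unique(cls$homology_class[cls$human_symbol == "H2"]),
               "one_to_many_mouse")
  expect_equal(unique(cls$homology_class[cls$mouse_symbol == "m4"]),
               "one_to_many_human")
})

test_that("many:many components are rejected with the component named", {
  bad <- tibble::tibble(human_symbol = c("Ha", "Ha", "Hb"),
                        mouse_symbol = c("ma", "mb", "ma"))
  expect_error(classify_homology(bad), "Ha~ma")
})

test_that("collapsing applies the sum / max / split rules", {
  fx <- xsp_fixture()
  xsp <- collapse_homologs(fx$ht, fx$h, fx$m, negligible_tpm = 1,
                           similar_ratio = 0.2)
  summed <- xsp[xsp$human_symbol == "H2", ]
  expect_equal(summed$provenance, "summed_mouse")
  expect_equal(summed$ms1, 5 + 7)

  # H3 (40) vs H4 (35) are similar at ratio 0.2 -> two split rows on m4
  split_rows <- xsp[xsp$mouse_symbol == "m4", ]
  expect_equal(nrow(split_rows), 2)
  expect_setequal(split_rows$provenance, rep("split_comparison", 2))
  expect_setequal(split_rows$human_symbol, c("H3", "H4"))

  direct <- xsp[xsp$human_symbol == "H1", ]
  expect_equal(direct$provenance, "direct")
  expect_equal(direct$ms1, 9)
})

test_that("a negligible runner-up keeps only the top human homolog", {
  fx <- xsp_fixture()
  fx$h$hs1[fx$h$gene == "H4"] <- 0
  fx$h$hs2[fx$h$gene == "H4"] <- 0
  xsp <- collapse_homologs(fx$ht, fx$h, fx$m)
  rows <- xsp[xsp$mouse_symbol == "m4", ]
  expect_equal(rows$human_symbol, "H3")
  expect_equal(rows$provenance, "max_human")
})

test_that("every homology entry is accounted for in exactly one class", {
  fx <- xsp_fixture()
  fx$h <- fx$h[fx$h$gene != "H6", ]  # force a dropped pair
  xsp <- collapse_homologs(fx$ht, fx$h, fx$m)
  audit <- attr(xsp, "audit")
  expect_equal(sum(audit), nrow(fx$ht))
  expect_equal(unname(audit["dropped"]), 1L)
})

test_that("collapsing is invariant to homology row order", {
  fx <- xsp_fixture()
  a <- collapse_homologs(fx$ht, fx$h, fx$m)
  set.seed(1)
  shuffled <- classify_homology(fx$ht[sample.int(nrow(fx$ht)), 1:2])
  b <- collapse_homologs(shuffled, fx$h, fx$m)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("reverse counts match the hand example", {
  xsm <- tibble::tibble(human_symbol = c("H1", "H2"),
                        mouse_symbol = c("m1", "m2"),
                        provenance = "direct",
                        s1 = c(5e5, 5e5))
  attr(xsm, "human_samples") <- "s1"
  attr(xsm, "mouse_samples") <- character(0)
  lens <- tibble::tibble(gene = c("H1", "H2"), length_kb = c(1, 2))
  pc <- reverse_counts(xsm, lens, target_depth = 300)
  expect_equal(pc$s1, c(100L, 200L))
})

test_that("TPM survives the reverse-count round trip", {
  set.seed(8)
  n <- 300
  tpm <- rexp(n); tpm <- tpm / sum(tpm) * 1e6
  lens <- runif(n, 0.5, 5)
  genes <- paste0("H", seq_len(n))
  xsm <- tibble::tibble(human_symbol = genes, mouse_symbol = genes,
                        provenance = "direct", s1 = tpm)
  attr(xsm, "human_samples") <- "s1"
  attr(xsm, "mouse_samples") <- character(0)
  len_tbl <- tibble::tibble(gene = genes, length_kb = lens)

  # before rounding: TPM ratios are exactly preserved
  raw <- tpm * lens
  tpm_back_exact <- (raw / lens) / sum(raw / lens) * 1e6
  expect_equal(tpm_back_exact, tpm, tolerance = 1e-6)

  pc <- reverse_counts(xsm, len_tbl, target_depth = 1e7)
  counts <- toy_counts(matrix(pc$s1, ncol = 1), lens, genes = genes)
  tpm_back <- tpm_from_counts(counts)$s1
  expect_lt(max(abs(tpm_back - tpm) / pmax(tpm, 1)), 1e-2)
})

test_that("rows without a human length are dropped and zero samples flagged", {
  xsm <- tibble::tibble(human_symbol = c("H1", "H2"),
                        mouse_symbol = c("m1", "m2"),
                        provenance = "direct", s1 = c(0, 0))
  attr(xsm, "human_samples") <- "s1"
  attr(xsm, "mouse_samples") <- character(0)
  lens <- tibble::tibble(gene = "H1", length_kb = 1)
  expect_message(expect_warning(pc <- reverse_counts(xsm, lens), "all-zero"),
                 "dropped")
  expect_equal(pc$s1, 0L)
})

test_that("cross-species DE detects a planted human excess and stays null otherwise", {
  set.seed(21)
  n <- 300
  genes_h <- paste0("H", seq_len(n)); genes_m <- paste0("m", seq_len(n))
  base <- rlnorm(n, 4, 1)
  up <- seq_len(20)  # planted 8-fold human excess
  make_cols <- function(mu, k, prefix) {
    cols <- purrr::map(seq_len(k), function(i) {
      as.numeric(rnbinom(n, mu = mu, size = 10))
    })
    names(cols) <- paste0(prefix, seq_len(k))
    cols
  }
  mu_h <- base; mu_h[up] <- mu_h[up] * 8
  hs <- make_cols(mu_h, 3, "hs"); ms <- make_cols(base, 3, "ms")
  to_tpm <- function(v) v / sum(v) * 1e6
  xsm <- tibble::tibble(human_symbol = genes_h, mouse_symbol = genes_m,
                        provenance = "direct",
                        !!!purrr::map(c(hs, ms), to_tpm))
  attr(xsm, "human_samples") <- names(hs)
  attr(xsm, "mouse_samples") <- names(ms)
  lens <- tibble::tibble(gene = genes_h, length_kb = rep(2, n))
  pc <- reverse_counts(xsm, lens, target_depth = 1e6)
  de <- cross_species_de(pc)
  called_up <- de$human_symbol[de$direction == "enriched"]
  expect_gt(mean(genes_h[up] %in% called_up), 0.8)
  null_calls <- sum(de$direction != "ns" & !de$human_symbol %in% genes_h[up])
  expect_lt(null_calls / (n - 20), 0.02)
})
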