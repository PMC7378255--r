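test_that("size factors: symmetry, closed-form doubling, degenerate single sample", {
  set.seed(1)
  m <- matrix(rpois(200, 40) + 1L, ncol = 2)
  same <- toy_counts(cbind(m[, 1], m[, 1]), rep(1, 100))
  sf <- estimate_size_factors(same)
  expect_equal(sf$size_factor, c(1, 1))

  doubled <- toy_counts(cbind(m[, 1], 2L * m[, 1]), rep(1, 100))
  sf2 <- estimate_size_factors(doubled)
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1], 2)
  expect_equal(exp(mean(log(sf2$size_factor))), 1)

  single <- toy_counts(m[, 1, drop = FALSE], rep(1, 100))
  expect_equal(estimate_size_factors(single)$size_factor, 1)
})

test_that("size factors fall back when no gene is positive everywhere", {
  m <- matrix(c(5L, 0L, 3L, 0L,
                0L, 8L, 0L, 6L), nrow = 4)
  tbl <- toy_counts(m, rep(1, 4))
  expect_message(sf <- estimate_size_factors(tbl), "falling back")
  expect_true(all(sf$size_factor > 0))
})

test_that("dispersion floors Poisson-like and constant genes", {
  set.seed(2)
  n <- 60
  tbl <- toy_counts(cbind(matrix(rpois(50 * n, 100), ncol = n)),
                    rep(1, 50))
  sf <- estimate_size_factors(tbl)
  d <- estimate_dispersion(tbl, sf)
  expect_lt(median(d$dispersion), 0.02)

  flat <- toy_counts(matrix(rep(10L, 4), nrow = 1), 1,
                     samples = paste0("s", 1:4))
  sf_flat <- tibble::tibble(sample = paste0("s", 1:4), size_factor = rep(1, 4))
  expect_equal(estimate_dispersion(flat, sf_flat)$dispersion, 1e-8)
})

test_that("method of moments recovers a planted NB dispersion at n = 50", {
  set.seed(3)
  n <- 50; g <- 400
  tbl <- toy_counts(matrix(rnbinom(g * n, mu = 200, size = 1 / 0.2), ncol = n),
                    rep(1, g))
  sf <- estimate_size_factors(tbl)
  d <- estimate_dispersion(tbl, sf)
  expect_lt(abs(median(d$dispersion) - 0.2), 0.05)
})

test_that("BH adjustment matches the hand example and passes NAs through", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals independent step-up implementations on random vectors", {
  set.seed(4)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- bh_adjust(p)
    expect_identical(got, bh_brute(p))
    expect_equal(got, p.adjust(p, "BH"))
  }
})

test_that("null gene gives zero fold change and p near 1; skipped genes flagged", {
  counts <- toy_counts(
    rbind(rep(20L, 6), c(0L, 0L, 0L, 0L, 0L, 0L)),
    c(1, 1), samples = c("mv_1", "wb_1", "mv_2", "wb_2", "mv_3", "wb_3"))
  meta <- tibble::tibble(
    sample = c("mv_1", "wb_1", "mv_2", "wb_2", "mv_3", "wb_3"),
    species = "mouse",
    compartment = rep(c("microvessel", "whole_brain"), 3),
    pair_id = rep(paste0("p", 1:3), each = 2))
  de <- differential_expression(counts, meta)
  expect_equal(de$log2fc[1], 0, tolerance = 1e-6)
  expect_gt(de$wald_p[1], 0.99)
  expect_equal(de$status[2], "low_count_skipped")
  expect_true(is.na(de$padj[2]))
})

test_that("exact doubling in every pair converges to log2fc = 1 as dispersion -> 0", {
  samples <- paste0(rep(c("mv", "wb"), 3), "_", rep(1:3, each = 2))
  # mv = 2x wb within each pair (pairs at 40, 80, 120 baseline)
  counts <- toy_counts(matrix(c(80L, 40L, 160L, 80L, 240L, 120L), nrow = 1),
                       1, samples = samples)
  meta <- tibble::tibble(sample = samples, species = "mouse",
                         compartment = rep(c("microvessel", "whole_brain"), 3),
                         pair_id = rep(paste0("p", 1:3), each = 2))
  sf <- tibble::tibble(sample = samples, size_factor = rep(1, 6))
  disp <- tibble::tibble(gene = "g1", dispersion = 1e-10)
  res <- wald_test_nb(counts, sf, disp, meta$compartment,
                      c("microvessel", "whole_brain"), meta$pair_id)
  expect_equal(res$log2fc, 1, tolerance = 1e-6)
})

test_that("swapping contrast groups negates log2fc and keeps p-values", {
  study <- nb_paired_study(150, 4, frac_de = 0.1, log2fc = 2, seed = 5)
  a <- differential_expression(study$counts,
                               contrast = c("microvessel", "whole_brain"))
  b <- differential_expression(study$counts,
                               contrast = c("whole_brain", "microvessel"))
  tested <- a$status == "tested" & b$status == "tested"
  expect_equal(a$log2fc[tested], -b$log2fc[tested], tolerance = 1e-6)
  expect_equal(a$wald_p[tested], b$wald_p[tested], tolerance = 1e-6)
})

test_that("separated genes are refit with a pseudocount and flagged", {
  samples <- paste0(rep(c("mv", "wb"), 3), "_", rep(1:3, each = 2))
  counts <- toy_counts(rbind(c(50L, 0L, 70L, 0L, 60L, 0L),
                             rep(30L, 6)),
                       c(1, 1), samples = samples)
  meta <- tibble::tibble(sample = samples, species = "human",
                         compartment = rep(c("microvessel", "whole_brain"), 3),
                         pair_id = rep(paste0("p", 1:3), each = 2))
  de <- differential_expression(counts, meta)
  expect_equal(de$status[1], "pseudocount")
  expect_gt(de$log2fc[1], 3)
})

test_that("wald fold change approaches the normalized group-mean ratio at low dispersion", {
  set.seed(6)
  samples <- paste0(rep(c("mv", "wb"), 4), "_", rep(1:4, each = 2))
  mv <- rpois(4, 400); wb <- rpois(4, 100)
  counts <- toy_counts(matrix(as.integer(rbind(mv, wb)), nrow = 1), 1,
                       samples = samples)
  meta <- tibble::tibble(sample = samples, species = "human",
                         compartment = rep(c("microvessel", "whole_brain"), 4),
                         pair_id = rep(paste0("p", 1:4), each = 2))
  sf <- tibble::tibble(sample = samples, size_factor = rep(1, 8))
  disp <- tibble::tibble(gene = "g1", dispersion = 1e-12)
  res <- wald_test_nb(counts, sf, disp, meta$compartment,
                      c("microvessel", "whole_brain"), NULL)
  expect_equal(res$log2fc, log2(mean(mv) / mean(wb)), tolerance = 1e-4)
})
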