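test_that("ranking metric matches hand arithmetic and orders descending", {
  de <- tibble::tibble(gene = c("a", "b", "c"),
                       log2fc = c(-2, 3, 0.5),
                       wald_p = c(0.01, 1, 0.001),
                       status = "tested")
  rk <- rank_genes(de)
  expect_equal(rk$score[rk$gene == "a"], -2)
  expect_equal(rk$score[rk$gene == "b"], 0)
  expect_equal(rk$gene, c("c", "b", "a"))  # 3, 0, -2

  de0 <- tibble::tibble(gene = "z", log2fc = 2, wald_p = 0, status = "tested")
  expect_true(is.finite(rank_genes(de0)$score))
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5", "g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  writeLines("broken\tonly_two_fields", path)
  expect_error(read_gmt(path), "malformed")
})

test_that("enrichment score matches brute-force enumeration on small lists", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    ranked <- tibble::tibble(gene = paste0("g", 1:n),
                             score = sort(rnorm(n), decreasing = TRUE))
    k <- sample(1:n, 1)
    members <- sample(ranked$gene, k)
    w <- sample(c(0, 1), 1)
    if (k == n) next  # degenerate covered below
    got <- enrichment_score(ranked, members, w)$es
    expect_equal(got, es_brute(ranked$score, ranked$gene %in% members, w))
    expect_true(got >= -1 && got <= 1)
  }
})

test_that("degenerate and symmetric enrichment cases behave", {
  ranked <- tibble::tibble(gene = c("a", "b", "c"), score = c(3, 1, -2))
  expect_equal(enrichment_score(ranked, c("a", "b", "c"))$es, 1)

  top <- enrichment_score(ranked, "a", weight_exponent = 0)
  # brute force: +1 at position 1, then -1/2 twice; extremum is +1
  expect_equal(top$es, 1)

  rev_ranked <- ranked[3:1, ]
  es_f <- enrichment_score(ranked, "a")$es
  es_r <- enrichment_score(rev_ranked, "a")$es
  expect_equal(es_f, -es_r)

  expect_error(enrichment_score(ranked, "zz"), "does not intersect")
})

test_that("hit-position shortcut agrees with the full running sum", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    ranked <- tibble::tibble(gene = paste0("g", 1:n),
                             score = sort(rnorm(n), decreasing = TRUE))
    k <- sample(2:min(20, n - 1), 1)
    members <- sample(ranked$gene, k)
    full <- enrichment_score(ranked, members)$es
    pos <- sort(which(ranked$gene %in% members))
    fast <- vesselmix:::es_from_positions(pos, abs(ranked$score[pos]), n)
    expect_equal(fast, full)
  }
})

test_that("preranked GSEA flags a planted top set and is seed-reproducible", {
  set.seed(35)
  n <- 500
  ranked <- tibble::tibble(gene = paste0("g", 1:n),
                           score = sort(rnorm(n, sd = 2), decreasing = TRUE))
  sets <- list(planted_top = ranked$gene[1:15],
               random_set = sample(ranked$gene, 15))
  res <- gsea_preranked(ranked, sets, n_perm = 200, seed = 9)
  expect_lte(res$nominal_p[res$gene_set == "planted_top"], 0.05)
  expect_true(all(res$es >= -1 & res$es <= 1))
  res2 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 9)
  expect_identical(res, res2)

  small <- list(tiny = ranked$gene[1:2])
  expect_message(out <- gsea_preranked(ranked, small, n_perm = 100, seed = 1),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("clustering reproduces hand-computed UPGMA merges", {
  # identical samples merge at height 0; anti-correlated at height 2
  expr <- tibble::tibble(gene = paste0("g", 1:4),
                         a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                         c = c(4, 3, 2, 1))
  hc <- hier_cluster(expr, axis = "samples")
  expect_equal(min(hc$hclust$height), 0, tolerance = 1e-12)
  expect_equal(max(hc$hclust$height), 2, tolerance = 1e-12)

  # 3-item brute force: merge the closest pair, then average distances
  set.seed(37)
  m <- matrix(rnorm(30), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  expr3 <- tibble::tibble(gene = paste0("g", 1:10), x = m[, 1], y = m[, 2],
                          z = m[, 3])
  d <- 1 - cor(m)
  pairs <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  dv <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  first <- pairs[[which.min(dv)]]
  rest <- setdiff(c("x", "y", "z"), first)
  second_height <- mean(d[rest, first])
  hc3 <- hier_cluster(expr3, axis = "samples")$hclust
  expect_equal(sort(hc3$height), sort(c(min(dv), second_height)))

  const <- tibble::tibble(gene = paste0("g", 1:3), a = c(1, 1, 1), b = 1:3)
  expect_error(hier_cluster(const, axis = "samples"), "zero-variance.*a")
})

test_that("clustering and PCA are invariant to gene row order", {
  set.seed(39)
  expr <- tibble::tibble(gene = paste0("g", 1:50),
                         a = rnorm(50), b = rnorm(50), c = rnorm(50),
                         d = rnorm(50))
  perm <- expr[sample.int(50), ]
  expect_equal(hier_cluster(expr)$hclust$height,
               hier_cluster(perm)$hclust$height)
  expect_equal(pca_summary(expr)$variance_explained,
               pca_summary(perm)$variance_explained)
})

test_that("PCA matches brute-force eigendecomposition and handles rank-1 data", {
  set.seed(41)
  expr <- tibble::tibble(gene = paste0("g", 1:6),
                         s1 = rnorm(6), s2 = rnorm(6), s3 = rnorm(6),
                         s4 = rnorm(6))
  p <- pca_summary(expr)
  x <- t(as.matrix(expr[, -1]))
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))$values
  expect_equal(p$variance_explained[1:3], (ev / sum(ev))[1:3],
               tolerance = 1e-8)

  # samples on a line in gene space -> PC1 explains everything
  line <- tibble::tibble(gene = paste0("g", 1:5),
                         s1 = 1:5, s2 = 2 * (1:5), s3 = 3 * (1:5))
  pl <- pca_summary(line)
  expect_equal(pl$variance_explained[1], 1)

  dup <- tibble::tibble(gene = paste0("g", 1:5),
                        s1 = rnorm(5), s2 = rnorm(5))
  dup$s3 <- dup$s1
  pd <- pca_summary(dup)
  expect_equal(unlist(pd$coordinates[1, -1]), unlist(pd$coordinates[3, -1]))
})
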