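test_that("ranking metric follows the signed -log10 p rule with flooring", {
  s <- tibble::tibble(gene = c("a", "b", "c"),
                      log2FC = c(2, -1, 3),
                      pvalue = c(0.01, 1, 0))
  m <- ranking_metric(s)$metric
  expect_equal(m[1], 2)
  expect_equal(m[2], 0)
  expect_equal(m[3], 300)
  s$pvalue[1] <- NA
  expect_error(ranking_metric(s), class = "dlamreg_input_error")
})

test_that("self-comparison RRHO puts all signal in concordant quadrants", {
  pair <- sim_signature_pair(n_genes = 1200, concordance = 0.8, seed = 3)
  rr <- rrho_map(pair$sig_a, pair$sig_a)
  px <- rr$pixels
  disc <- px[px$quadrant %in% c("up_down", "down_up"), ]
  expect_true(all(disc$padj >= 0.5))
  for (q in c("up_up", "down_down")) {
    w <- rr$warmest[[q]]
    # warmest concordant pixel lies on the grid diagonal
    expect_equal(w$i, w$j)
    expect_lt(w$padj, 1e-10)
  }

  neg <- pair$sig_a
  neg$log2FC <- -neg$log2FC
  rr2 <- rrho_map(pair$sig_a, neg)
  px2 <- rr2$pixels
  conc <- px2[px2$quadrant %in% c("up_up", "down_down"), ]
  disc2 <- px2[px2$quadrant %in% c("up_down", "down_up"), ]
  expect_true(all(conc$padj >= 0.5))
  expect_lt(min(disc2$padj), 1e-10)
})

test_that("RRHO pixels match direct hypergeometric counting", {
  pair <- sim_signature_pair(n_genes = 800, concordance = 0.5, seed = 4)
  rr <- rrho_map(pair$sig_a, pair$sig_b)
  px <- rr$pixels
  N <- rr$n_common

  # rebuild the sublists exactly as the map does
  a <- dlamreg:::metric_order(ranking_metric(pair$sig_a))
  b <- dlamreg:::metric_order(ranking_metric(pair$sig_b))
  lists <- list(
    a_up = a$gene[a$metric > 0], a_down = rev(a$gene[a$metric < 0]),
    b_up = b$gene[b$metric > 0], b_down = rev(b$gene[b$metric < 0]))
  pick <- function(q) {
    switch(q, up_up = c("a_up", "b_up"), down_down = c("a_down", "b_down"),
           up_down = c("a_up", "b_down"), down_up = c("a_down", "b_up"))
  }
  set.seed(9)
  for (row in sample(nrow(px), 20)) {
    p <- px[row, ]
    ls <- pick(p$quadrant)
    ga <- head(lists[[ls[1]]], p$size_a)
    gb <- head(lists[[ls[2]]], p$size_b)
    k <- length(intersect(ga, gb))
    expect_identical(k, p$overlap)
    expect_equal(p$pvalue,
                 hyper_tail_oracle(k, N, p$size_a, p$size_b),
                 tolerance = 1e-10)
  }

  # warmest-pixel overlap lists are subsets of both sublists and reproduce
  # the reported pixel p
  w <- rr$warmest$up_up
  expect_true(all(w$genes %in% lists$a_up))
  expect_true(all(w$genes %in% lists$b_up))
  expect_equal(w$pvalue,
               hyper_tail_oracle(length(w$genes), N, w$size_a, w$size_b),
               tolerance = 1e-10)
})

test_that("RRHO grid dimensions follow the step rule", {
  pair <- sim_signature_pair(n_genes = 600, concordance = 0.5, seed = 6)
  rr <- rrho_map(pair$sig_a, pair$sig_b, step = 25)
  px <- rr$pixels[rr$pixels$quadrant == "up_up", ]
  expect_identical(max(px$i), as.integer(ceiling(rr$lengths$a_up / 25)))
  expect_identical(max(px$j), as.integer(ceiling(rr$lengths$b_up / 25)))
  expect_error(rrho_map(pair$sig_a[1:50, ], pair$sig_b),
               class = "dlamreg_input_error")
})

test_that("restricted overlap test matches closed forms", {
  u <- paste0("g", 1:10)
  r <- restricted_overlap_test(u[1:5], u[1:5], 10)
  expect_equal(r$pvalue, 1 / choose(10, 5), tolerance = 1e-12)
  expect_identical(r$overlap, 5L)

  full <- restricted_overlap_test(u, u, 10)
  expect_equal(full$pvalue, 1)
  expect_identical(full$overlap, 10L)

  set.seed(7)
  A <- paste0("g", sample(517, 60))
  B <- paste0("g", sample(517, 80))
  r2 <- restricted_overlap_test(A, B, 517)
  expect_equal(r2$pvalue, hyper_tail_oracle(r2$overlap, 517, 60, 80),
               tolerance = 1e-10)
  expect_error(restricted_overlap_test(paste0("g", 1:20), "g1", 10),
               class = "dlamreg_input_error")
})

test_that("spearman comparison handles the degenerate and null cases", {
  s <- tibble::tibble(gene = paste0("g", 1:50), log2FC = rnorm(50),
                      pvalue = runif(50))
  expect_equal(spearman_compare(s, s)$rho, 1)
  rev <- s
  rev$log2FC <- -s$log2FC
  expect_equal(spearman_compare(s, rev)$rho, -1)

  set.seed(8)
  cover <- vapply(1:50, function(i) {
    pair <- sim_signature_pair(n_genes = 2000, concordance = 0, seed = i)
    r <- spearman_compare(pair$sig_a, pair$sig_b)
    c(r$rho, r$conf.low <= 0 && r$conf.high >= 0)
  }, numeric(2))
  expect_true(all(abs(cover[1, ]) < 0.08))
  expect_gte(mean(cover[2, ]), 0.9)

  const <- s
  const$log2FC <- 1
  expect_error(spearman_compare(s, const), class = "dlamreg_input_error")

  # invariance under strictly monotone transforms
  tr <- s
  tr$log2FC <- exp(s$log2FC)
  expect_equal(spearman_compare(s, tr)$rho, 1)
})

test_that("GSEA enrichment score matches the hand-unrolled running sum", {
  set.seed(10)
  metric <- sort(rnorm(12, sd = 2), decreasing = TRUE)
  names(metric) <- paste0("g", 1:12)
  hits <- c("g2", "g5", "g11")
  res <- gsea_preranked(metric, list(s = hits), n_perm = 50, min_size = 3,
                        seed = 1)
  expect_equal(res$es, gsea_es_oracle(metric, hits), tolerance = 1e-12)

  # and for 20 random small cases
  for (i in 1:20) {
    m <- sort(rnorm(30, sd = 2), decreasing = TRUE)
    names(m) <- paste0("x", 1:30)
    h <- sample(names(m), 6)
    r <- gsea_preranked(m, list(s = h), n_perm = 10, min_size = 3, seed = i)
    expect_equal(r$es, gsea_es_oracle(m, h), tolerance = 1e-10)
  }
})

test_that("GSEA agrees with fgsea on the enrichment score", {
  set.seed(11)
  metric <- sort(rnorm(200, sd = 2), decreasing = TRUE)
  names(metric) <- paste0("g", 1:200)
  sets <- list(a = sample(names(metric), 15),
               b = sample(names(metric), 25))
  mine <- gsea_preranked(metric, sets, n_perm = 10, seed = 2)
  for (nm in names(sets)) {
    fes <- fgsea::calcGseaStat(metric,
                               selectedStats = which(names(metric) %in%
                                                       sets[[nm]]),
                               gseaParam = 1)
    expect_equal(mine$es[mine$geneset == nm], fes, tolerance = 1e-10)
  }
})

test_that("a geneset of the top-ranked genes is maximally enriched", {
  set.seed(12)
  metric <- sort(rnorm(500, sd = 2), decreasing = TRUE)
  names(metric) <- paste0("g", 1:500)
  res <- gsea_preranked(metric, list(top = names(metric)[1:10]),
                        n_perm = 1000, seed = 3)
  expect_gt(res$es, 0.9)
  expect_lte(res$pvalue, 1 / 1001)
  expect_gt(res$nes, 1)
  expect_identical(sort(res$leading_edge[[1]]),
                   sort(names(metric)[1:10]))
})

test_that("ES with weight 0 is invariant under monotone metric transforms", {
  set.seed(13)
  metric <- sort(rexp(100), decreasing = TRUE)
  names(metric) <- paste0("g", 1:100)
  h <- sample(names(metric), 10)
  a <- gsea_preranked(metric, list(s = h), n_perm = 10, weight = 0,
                      seed = 4)
  metric2 <- sort(metric^3 + 1, decreasing = TRUE)
  b <- gsea_preranked(metric2, list(s = h), n_perm = 10, weight = 0,
                      seed = 4)
  expect_equal(a$es, b$es, tolerance = 1e-12)

  # undersized genesets are skipped with a warning
  expect_warning(
    empty <- gsea_preranked(metric, list(tiny = h[1:2]), n_perm = 10,
                            seed = 5),
    "skipped")
  expect_identical(nrow(empty), 0L)
})
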