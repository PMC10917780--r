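test_that("MI estimator is symmetric, rank-invariant and zero under independence", {
  set.seed(1)
  x <- rnorm(400); y <- 0.7 * x + rnorm(400, sd = 0.5)
  expect_lt(abs(estimate_mi(x, y) - estimate_mi(y, x)), 1e-12)
  expect_equal(estimate_mi(exp(x), y^3 - 2 * y), estimate_mi(x, y^3 - 2 * y))

  nulls <- replicate(100, estimate_mi(rnorm(1000), rnorm(1000)))
  expect_lt(mean(nulls), 0.02)

  expect_gt(estimate_mi(x, x), estimate_mi(x, sample(x)))
  expect_error(estimate_mi(1:20, 1:19), class = "dlamreg_input_error")
  expect_error(estimate_mi(1:10, 1:10), class = "dlamreg_input_error")
})

test_that("MI estimator recovers the Gaussian closed form", {
  set.seed(2)
  for (rho in c(0, 0.5, 0.9)) {
    truth <- -0.5 * log(1 - rho^2)
    est <- replicate(5, {
      x <- rnorm(5000)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(5000)
      estimate_mi(x, y)
    })
    expect_lt(max(abs(est - truth)), 0.1)
  }
})

test_that("MI threshold is monotone in p and deterministic", {
  sim <- sim_scrna(n_cells = 600, n_genes = 150, n_tfs = 10,
                   n_dlam_genes = 25, module_size = 5, seed = 3)
  mc <- make_metacells(sim$counts, sub_size = 120, seed = 3)
  t8 <- mi_threshold(mc$values, target_p = 1e-8, n_null = 2e4, seed = 5)
  t4 <- mi_threshold(mc$values, target_p = 1e-4, n_null = 2e4, seed = 5)
  expect_gt(t8, t4)
  expect_identical(t8, mi_threshold(mc$values, target_p = 1e-8,
                                    n_null = 2e4, seed = 5))
  expect_error(mi_threshold(mc$values, n_null = 100),
               class = "dlamreg_input_error")
})

test_that("network inference respects the threshold limits", {
  sim <- sim_scrna(n_cells = 300, n_genes = 80, n_tfs = 8,
                   n_dlam_genes = 12, module_size = 4, seed = 4)
  mc <- make_metacells(sim$counts, sub_size = 80, min_nonzero_frac = 0.5,
                       seed = 4)
  set.seed(4)
  expect_identical(nrow(infer_network(mc$values, sim$truth$regulators,
                                      Inf)), 0L)
  set.seed(4)
  full <- infer_network(mc$values, sim$truth$regulators, 0, dpi = FALSE)
  n_genes <- nrow(mc$values)
  n_regs <- sum(sim$truth$regulators %in% rownames(mc$values))
  expect_identical(nrow(full), n_regs * (n_genes - 1L))
  expect_error(infer_network(mc$values, c("nope"), 0),
               class = "dlamreg_input_error")
})

test_that("inferred edges are enriched for planted edges", {
  sim <- sim_scrna(n_cells = 1000, n_genes = 200, n_tfs = 10,
                   n_dlam_genes = 30, module_size = 6, seed = 6)
  mc <- make_metacells(sim$counts, sub_size = 150, seed = 6)
  thr <- mi_threshold(mc$values, n_null = 2e4, seed = 6)
  set.seed(6)
  net <- infer_network(mc$values, sim$truth$regulators, thr)
  tkey <- paste(sim$truth$true_edges$tf, sim$truth$true_edges$target)
  key <- paste(net$regulator, net$target)
  n_regs <- length(sim$truth$regulators)
  n_pairs <- n_regs * (nrow(mc$values) - 1)
  tab <- matrix(c(sum(key %in% tkey), sum(!key %in% tkey),
                  sum(!tkey %in% key),
                  n_pairs - length(union(key, tkey))), 2, 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  expect_lt(p, 1e-6)
})

test_that("MI ranking separates planted edges from non-edges", {
  sim <- sim_scrna(seed = 19)  # generator defaults
  mc <- make_metacells(sim$counts, seed = 19)
  set.seed(19)
  all_pairs <- infer_network(mc$values, sim$truth$regulators, 0,
                             dpi = FALSE)
  tkey <- paste(sim$truth$true_edges$tf, sim$truth$true_edges$target)
  is_true <- paste(all_pairs$regulator, all_pairs$target) %in% tkey
  r <- rank(all_pairs$mi)
  auc <- (mean(r[is_true]) - (sum(is_true) + 1) / 2) / sum(!is_true)
  expect_gt(auc, 0.9)
})

test_that("DPI removes the weakest edge of the worked triangle", {
  edges <- tibble::tibble(
    regulator = c("r1", "r2", "r1"),
    target = c("t", "t", "r2"),
    mi = c(0.3, 0.4, 0.5))
  out <- apply_dpi(edges, regulators = c("r1", "r2"))
  expect_identical(nrow(out), 2L)
  expect_false(any(out$regulator == "r1" & out$target == "t"))
})

test_that("DPI is the identity without closed triangles and never adds edges", {
  edges <- tibble::tibble(regulator = c("r1", "r2"),
                          target = c("tA", "tB"), mi = c(0.2, 0.9))
  expect_identical(apply_dpi(edges, regulators = c("r1", "r2")), edges)
  expect_identical(nrow(apply_dpi(edges[0, ])), 0L)
})

test_that("DPI matches the exhaustive triplet-scan oracle on random graphs", {
  set.seed(7)
  for (rep in 1:100) {
    g <- random_edge_graph()
    regs <- unique(g$regulator)
    mine <- apply_dpi(g, regulators = regs)
    oracle <- dpi_oracle(g, regs)
    okey <- function(e) sort(paste(e$regulator, e$target))
    expect_identical(okey(mine), okey(oracle))
  }
})

test_that("Poisson consolidation matches closed-form tails", {
  # support 1 with rate 2: P(Poisson(2) >= 1) = 1 - exp(-2)
  expect_equal(ppois(0, 2, lower.tail = FALSE), 1 - exp(-2),
               tolerance = 1e-12)
  sim <- sim_scrna(n_cells = 500, n_genes = 100, n_tfs = 8,
                   n_dlam_genes = 15, module_size = 5, seed = 8)
  mc <- make_metacells(sim$counts, sub_size = 100, seed = 8)
  thr <- mi_threshold(mc$values, n_null = 2e4, seed = 8)
  net <- bootstrap_network(mc$values, sim$truth$regulators, thr,
                           n_bootstraps = 30, seed = 8)
  expect_s3_class(net, "dlam_grn")
  expect_equal(net$edges$pvalue,
               ppois(net$edges$support - 1, net$lambda,
                     lower.tail = FALSE))
  expect_true(all(net$edges$fdr < net$fdr))
  # an edge seen in every bootstrap survives; an edge seen once at this
  # rate cannot
  expect_true(all(net$edges$support > 1 | net$lambda < 1))

  # nested FDR cutoffs give nested edge sets
  strict <- consolidate_pool(net$pool, 30, fdr = 0.01)
  loose <- consolidate_pool(net$pool, 30, fdr = 0.05)
  skey <- paste(strict$edges$regulator, strict$edges$target)
  lkey <- paste(loose$edges$regulator, loose$edges$target)
  expect_true(all(skey %in% lkey))

  # planted edges attract more support than decoy-to-foreign pairs
  tr <- sim$truth
  pool <- net$pool
  pkey <- paste(pool$regulator, pool$target)
  tkey <- paste(tr$true_edges$tf, tr$true_edges$target)
  planted_support <- pool$support[pkey %in% tkey]
  other_support <- pool$support[!pkey %in% tkey]
  expect_gt(median(planted_support), median(other_support))
})

test_that("bootstrap networks are deterministic under a fixed seed", {
  sim <- sim_scrna(n_cells = 300, n_genes = 80, n_tfs = 6,
                   n_dlam_genes = 12, module_size = 4, seed = 9)
  mc <- make_metacells(sim$counts, sub_size = 80, min_nonzero_frac = 0.5,
                       seed = 9)
  thr <- mi_threshold(mc$values, n_null = 2e4, seed = 9)
  a <- bootstrap_network(mc$values, sim$truth$regulators, thr,
                         n_bootstraps = 10, seed = 11)
  b <- bootstrap_network(mc$values, sim$truth$regulators, thr,
                         n_bootstraps = 10, seed = 11)
  expect_identical(a$edges, b$edges)
})

test_that("meta-network reduces to single-network consolidation and pools support", {
  sim <- sim_scrna(n_cells = 400, n_genes = 80, n_tfs = 6,
                   n_dlam_genes = 12, module_size = 4, seed = 10)
  mc <- make_metacells(sim$counts, sub_size = 100, min_nonzero_frac = 0.5,
                       seed = 10)
  thr <- mi_threshold(mc$values, n_null = 2e4, seed = 10)
  net <- bootstrap_network(mc$values, sim$truth$regulators, thr,
                           n_bootstraps = 20, seed = 10)

  meta1 <- meta_network(list(net))
  expect_equal(meta1$edges, net$edges)

  meta2 <- meta_network(list(net, net))
  expect_identical(meta2$pool$support, 2L * net$pool$support)
  expect_equal(meta2$lambda, 2 * net$lambda)
  # doubling all counts and the rate: verify retention by direct Poisson test
  p2 <- ppois(2 * net$pool$support - 1, 2 * net$lambda,
              lower.tail = FALSE)
  expect_equal(sort(meta2$pool$support[p.adjust(p2, "BH") < 0.05]),
               sort(meta2$edges$support))
  expect_error(meta_network(list()), class = "dlamreg_input_error")
})
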