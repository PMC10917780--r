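toy_motif <- function(width = 6) {
  bases <- c("A", "C", "G", "T")
  cons <- rep(bases, length.out = width)
  mat <- matrix(0.05, width, 4, dimnames = list(NULL, bases))
  mat[cbind(seq_len(width), match(cons, bases))] <- 0.85
  list(motif = new_motif("toy", mat), consensus = paste(cons, collapse = ""))
}

test_that("promoters are symmetric TSS windows, clipped at zero", {
  tss <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                        tss = c(5000, 1000), strand = c("+", "-"))
  p <- make_promoters(tss)
  expect_equal(p$start, c(3000, 0))
  expect_equal(p$end, c(7000, 3000))
  expect_error(make_promoters(tss, flank = 0), class = "dlamreg_input_error")
  expect_error(make_promoters(dplyr::bind_rows(tss, tss[1, ])),
               class = "dlamreg_input_error")
})

test_that("scanner finds a planted consensus on both strands", {
  tm <- toy_motif()
  bg <- strsplit("ACCAGTATCCAGTAACCAGTATCCAGT", "")[[1]]
  s <- paste0("CCCCCCC", tm$consensus, "CCCCCCCCCC")
  hits <- scan_motif(s, tm$motif, threshold = 0.9 * tm$motif$max_score)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset, 7L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$score, tm$motif$max_score, tolerance = 1e-9)

  rc <- dlamreg:::revcomp(s)
  hits_rc <- scan_motif(rc, tm$motif, threshold = 0.9 * tm$motif$max_score)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score, tolerance = 1e-12)
  # offset maps to the mirrored position
  expect_identical(hits_rc$offset, nchar(s) - 7L - 6L)

  # shorter-than-motif sequences and N windows yield no hits, not errors
  expect_identical(nrow(scan_motif("ACG", tm$motif)), 0L)
  withN <- paste0("CCC", substr(tm$consensus, 1, 5), "N", "CCC")
  expect_identical(nrow(scan_motif(withN, tm$motif,
                                   threshold = 0.5 * tm$motif$max_score)), 0L)
})

test_that("scanner agrees exactly with the brute-force oracle", {
  tm <- toy_motif(5)
  set.seed(8)
  seqs <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, character(1))
  thr <- 0.5 * tm$motif$max_score
  mine <- scan_motif(seqs, tm$motif, threshold = thr)
  oracle <- scan_oracle(seqs, tm$motif, thr)
  ord <- function(df) df[order(df$seq_index, df$offset, df$strand), ]
  m <- ord(as.data.frame(mine[, c("seq_index", "offset", "strand", "score")]))
  o <- ord(oracle)
  expect_equal(m$seq_index, o$seq_index)
  expect_equal(m$offset, o$offset)
  expect_equal(m$strand, o$strand)
  expect_equal(m$score, o$score, tolerance = 1e-10)
})

test_that("proxy-binding sites are the peaks containing hits", {
  genes <- sprintf("g%02d", 1:40)
  fx <- sim_cistrome(genes, genes[1:15], embed_prob = 1, seed = 3)
  pbs <- proxy_binding_sites(fx$peaks, fx$sequences, fx$motif,
                             threshold = 0.9 * fx$motif$max_score)
  expect_true(all(genes[1:15] %in% pbs$peaks$name))
  expect_true(all(pbs$peaks$name %in% fx$peaks$name))
  expect_error(proxy_binding_sites(fx$peaks, fx$sequences[-1], fx$motif),
               class = "dlamreg_input_error")

  # with no embedding and a stringent threshold, false peaks are bounded
  # by the per-offset tail expectation
  fx0 <- sim_cistrome(genes, genes[1:15], embed_prob = 0, seed = 3)
  thr <- 0.95 * fx0$motif$max_score
  pbs0 <- proxy_binding_sites(fx0$peaks, fx0$sequences, fx0$motif,
                              threshold = thr)
  w <- nrow(fx0$motif$mat)
  # per-offset bound: hit needs >= w-1 consensus matches; each offset/strand
  # succeeds with probability <= w * 0.25^(w-1)
  n_windows <- sum(nchar(fx0$sequences) - w + 1) * 2
  p_hit <- w * 0.25^(w - 1)
  expect_lte(nrow(pbs0$peaks), max(5, 10 * n_windows * p_hit))
})

test_that("proxy-bound gene fraction counts 1-bp overlaps, half-open", {
  promoters <- tibble::tibble(gene = paste0("g", 1:4), chrom = "chr1",
                              start = c(0, 100, 200, 300) * 100,
                              end = c(0, 100, 200, 300) * 100 + 4000)
  pbs <- tibble::tibble(chrom = "chr1",
                        start = c(3999, 13900), end = c(4050, 14100))
  out <- proxy_bound_fraction(paste0("g", 1:4), promoters, pbs)
  expect_equal(out$fraction, 0.5)
  expect_identical(out$genes$bound, c(TRUE, TRUE, FALSE, FALSE))

  # touching the exclusive end only does not count
  pbs2 <- tibble::tibble(chrom = "chr1", start = 4000, end = 4100)
  out2 <- proxy_bound_fraction("g1", promoters, pbs2)
  expect_equal(out2$fraction, 0)

  out3 <- proxy_bound_fraction("g1", promoters, pbs2[0, ])
  expect_equal(out3$fraction, 0)
  expect_error(proxy_bound_fraction("gX", promoters, pbs),
               class = "dlamreg_input_error")
})

test_that("bound fraction grows as the scan threshold is lowered", {
  genes <- sprintf("g%02d", 1:30)
  fx <- sim_cistrome(genes, genes[1:10], embed_prob = 1, seed = 5)
  prom <- make_promoters(fx$tss)
  fr <- vapply(c(0.95, 0.7, 0.4), function(f) {
    pbs <- proxy_binding_sites(fx$peaks, fx$sequences, fx$motif,
                               threshold = f * fx$motif$max_score)
    proxy_bound_fraction(genes, prom, pbs)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("position histogram bins hits around region centers", {
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  # hit centered exactly at the region center
  hits <- tibble::tibble(seq_index = 1L, offset = 497L, strand = "+",
                         score = 1, width = 6L)
  h <- motif_position_histogram(regions, hits, window = 2000, bin = 20)
  expect_identical(nrow(h), 100L)
  expect_identical(sum(h$count), 1L)
  expect_identical(h$count[h$bin_start == 0], 1L)
  expect_error(motif_position_histogram(regions, hits, window = 2000,
                                        bin = 30),
               class = "dlamreg_input_error")

  # hits outside the window are dropped
  far <- tibble::tibble(seq_index = 1L, offset = 0L, strand = "+",
                        score = 1, width = 6L)
  wide <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  h2 <- motif_position_histogram(wide, far, window = 2000, bin = 20)
  expect_identical(sum(h2$count), 0L)
})

test_that("uniform hits give Poisson-consistent bin counts", {
  set.seed(12)
  n_regions <- 60
  regions <- tibble::tibble(chrom = "chr1",
                            start = seq(0, by = 4000,
                                        length.out = n_regions))
  regions$end <- regions$start + 2000
  hits <- tibble::tibble(
    seq_index = rep(seq_len(n_regions), each = 40),
    offset = sample(0L:1993L, n_regions * 40, replace = TRUE),
    strand = "+", score = 1, width = 6L)
  h <- motif_position_histogram(regions, hits, window = 2000, bin = 20)
  lambda <- sum(h$count) / nrow(h)
  band <- qpois(c(0.005, 0.995), lambda)
  expect_gt(mean(h$count >= band[1] & h$count <= band[2]), 0.95)
})

test_that("region exclusion drops overlapping intervals only", {
  exclusions <- tibble::tibble(
    chrom = c("chr19", "chr6"),
    start = c(45000000, 28477797), end = c(45800000, 33448354))
  ivs <- tibble::tibble(
    chrom = c("chr19", "chr19", "chr6", "chr2"),
    start = c(45100000, 44000000, 30000000, 45100000),
    end = c(45100500, 44000500, 30000500, 45100500))
  out <- exclude_regions(ivs, exclusions)
  expect_identical(out$chrom, c("chr19", "chr2"))
  expect_identical(out$start[1], 44000000)
  expect_identical(exclude_regions(ivs, exclusions[0, ]), ivs)
})
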