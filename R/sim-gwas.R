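#' Simulate GWAS summary statistics with planted heritability enrichment
#'
#' Draws standardized Gaussian genotype dosages with AR(1) correlation
#' `ld_rho` inside blocks of `block_size` SNPs (independent across blocks),
#' plants per-SNP causal effect variance equal to `enrichment` times the
#' genome-average per-SNP heritability inside the annotation, simulates a
#' phenotype with total SNP heritability `h2`, and computes the per-SNP
#' chi-square of the marginal regression of phenotype on genotype.
#'
#' @param m_snps Number of SNPs.
#' @param n_individuals GWAS cohort size.
#' @param block_size SNPs per LD block (last block may be shorter).
#' @param ld_rho AR(1) correlation within blocks. A scalar in \[0, 1) gives
#'   every block the same correlation; a length-2 range (the default) draws
#'   each block's correlation uniformly from it, mimicking the variable LD
#'   strength of real genomes.
#' @param annotation Binary membership vector of length `m_snps`; by default
#'   a random 10\% of SNPs.
#' @param enrichment Fold per-SNP heritability inside the annotation,
#'   relative to the genome-wide average h2 / m. Must satisfy
#'   `enrichment * mean(annotation) <= 1`.
#' @param h2 Total SNP heritability in \[0, 1\].
#' @param spacing Base pairs between consecutive SNPs.
#' @param seed Integer seed.
#'
#' @return List with `sumstats` (tibble: SNP, CHR, BP, CHI2, N),
#'   `genotypes` (n x m standardized dosage matrix, also usable as the LD
#'   reference panel), `positions`, `block_size` and `truth`
#'   (a `dlam_gwas_truth`: causal_effects, annotation_membership,
#'   planted_enrichment, h2_total, n_individuals).
#' @export
sim_gwas <- function(m_snps = 2000, n_individuals = 1000, block_size = 20,
                     ld_rho = c(0.1, 0.95), annotation = NULL,
                     enrichment = 10, h2 = 0.5, spacing = 1000, seed = 1) {
  check_count(m_snps, "m_snps", 2)
  check_count(n_individuals, "n_individuals", 10)
  check_count(block_size, "block_size")
  if (!length(ld_rho) %in% c(1, 2) || any(ld_rho < 0) || any(ld_rho >= 1)) {
    stop_input("`ld_rho` must be a scalar or range inside [0, 1)")
  }
  if (h2 < 0 || h2 > 1) stop_input("`h2` must lie in [0, 1]")
  if (enrichment <= 0) stop_input("`enrichment` must be positive")
  set.seed(substream_seed(seed, 5L))

  if (is.null(annotation)) {
    annotation <- integer(m_snps)
    annotation[sample(m_snps, max(1, round(0.1 * m_snps)))] <- 1L
  }
  if (length(annotation) != m_snps) {
    stop_input("`annotation` must have one entry per SNP")
  }
  annotation <- as.integer(annotation != 0)
  m_in <- sum(annotation)
  if (m_in == 0) stop_input("annotation covers no SNP")
  if (enrichment * m_in / m_snps > 1 + 1e-12) {
    stop_input("`enrichment` too large: annotation would exceed total h2")
  }

  n <- n_individuals
  n_blocks <- ceiling(m_snps / block_size)
  rho_block <- if (length(ld_rho) == 1) {
    rep(ld_rho, n_blocks)
  } else {
    runif(n_blocks, ld_rho[1], ld_rho[2])
  }
  X <- matrix(rnorm(n * m_snps), n, m_snps)
  for (j in seq_len(m_snps)[-1]) {
    if ((j - 1) %% block_size != 0) {
      b <- (j - 1) %/% block_size + 1
      X[, j] <- rho_block[b] * X[, j - 1] +
        sqrt(1 - rho_block[b]^2) * X[, j]
    }
  }
  # standardize columns (1/n variance) so X' y / n is a correlation scale
  X <- scale_cols(X)

  v_in <- enrichment * h2 / m_snps
  v_out <- if (m_in < m_snps) {
    (1 - enrichment * m_in / m_snps) * h2 / (m_snps - m_in)
  } else 0
  v <- ifelse(annotation == 1L, v_in, max(v_out, 0))
  beta <- rnorm(m_snps, sd = sqrt(v))
  g <- as.vector(X %*% beta)
  y <- g + rnorm(n, sd = sqrt(max(1 - h2, 0)))

  yc <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  r <- as.vector(crossprod(X, yc)) / n
  chi2 <- (n - 2) * r^2 / pmax(1 - r^2, .Machine$double.eps)

  pos <- seq_len(m_snps) * spacing
  sumstats <- tibble(SNP = sprintf("rs%06d", seq_len(m_snps)), CHR = "chr1",
                     BP = pos, CHI2 = chi2, N = n)
  truth <- structure(
    list(causal_effects = beta, annotation_membership = annotation,
         planted_enrichment = enrichment, h2_total = h2,
         n_individuals = n),
    class = "dlam_gwas_truth")
  list(sumstats = sumstats, genotypes = X, positions = pos,
       block_size = block_size, truth = truth)
}

# Standardize columns to mean 0, variance 1 with a 1/n denominator.
scale_cols <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))
  if (any(s == 0)) stop_input("monomorphic column (zero variance)")
  sweep(Xc, 2, s, "/")
}
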