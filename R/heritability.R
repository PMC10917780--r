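#' Binary SNP membership in a set of intervals
#'
#' Membership uses half-open intervals: a SNP at position `p` belongs to
#' `[start, end)` when `start <= p < end`.
#'
#' @param chrom,pos SNP chromosome names and 0-based positions.
#' @param intervals Interval tibble (chrom, start, end).
#' @return Integer vector of 0/1 memberships.
#' @export
snps_in_intervals <- function(chrom, pos, intervals) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  if (length(chrom) != length(pos)) stop_input("chrom/pos length mismatch")
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(integer(length(pos)))
  }
  snp_gr <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(pos + 1, pos + 1))
  ov <- GenomicRanges::countOverlaps(snp_gr, intervals_to_granges(intervals))
  as.integer(ov > 0)
}

#' Build an annotation matrix with a base column
#'
#' @param m Number of SNPs.
#' @param ... Named binary membership vectors of length `m`.
#' @return Integer matrix, SNPs x annotations, first column `base` all-ones.
#' @export
make_annotations <- function(m, ...) {
  extra <- list(...)
  out <- cbind(base = rep(1L, m))
  for (nm in names(extra)) {
    v <- as.integer(extra[[nm]] != 0)
    if (length(v) != m) stop_input(sprintf("annotation %s length mismatch", nm))
    out <- cbind(out, v)
    colnames(out)[ncol(out)] <- nm
  }
  out
}

#' Partitioned LD scores from a reference panel
#'
#' For SNP j and annotation c,
#' `l(j, c) = sum over SNPs k within `window` bp of adjusted r^2(j, k) *
#' a(k, c)` with the small-sample adjustment
#' `r2_adj = r2 - (1 - r2) / (n_panel - 2)`.
#'
#' @param genotypes Panel matrix, individuals x SNPs (standardized
#'   internally; monomorphic SNPs are an error).
#' @param positions Base-pair positions (ascending).
#' @param annotations SNPs x annotations matrix from [make_annotations()];
#'   the first column must be the all-ones base annotation.
#' @param window Window in bp.
#' @return A `dlam_ldscores` object: `scores` (SNPs x annotations),
#'   `annotations`, `window`, `n_panel`, `positions`.
#' @export
ld_scores <- function(genotypes, positions, annotations, window) {
  m <- ncol(genotypes)
  if (length(positions) != m) stop_input("positions/panel size mismatch")
  if (is.unsorted(positions)) stop_input("positions must be ascending")
  if (nrow(annotations) != m) stop_input("annotation rows must match SNPs")
  if (!all(annotations[, 1] == 1)) {
    stop_input("first annotation column must be the all-ones base")
  }
  if (nrow(genotypes) < 25) stop_input("panel size must be at least 25")
  X <- scale_cols(genotypes)
  sc <- ld_scores_cpp(X, as.numeric(positions),
                      matrix(as.integer(annotations), m), as.numeric(window))
  colnames(sc) <- colnames(annotations)
  structure(list(scores = sc, annotations = annotations, window = window,
                 n_panel = nrow(genotypes), positions = positions),
            class = "dlam_ldscores")
}

#' Stratified LD-score regression
#'
#' Weighted least-squares fit of per-SNP chi-square statistics on
#' `N * l(j, c)` plus an intercept. Per-annotation heritability is
#' `h2_c = sum over SNPs in c of the SNP's modeled per-SNP heritability
#' sum_c' tau_c' a(j, c')`; enrichment is the proportion of heritability
#' over the proportion of SNPs. Standard errors come from a
#' leave-one-block-out jackknife over contiguous SNP blocks, and the
#' enrichment p-value from the jackknife t-statistic of
#' `prop_h2 - prop_snps`.
#'
#' @param sumstats Tibble with CHI2 and N (SNP order must match the LD
#'   scores).
#' @param ld A `dlam_ldscores` object.
#' @param n_blocks Number of jackknife blocks (>= 2).
#' @param weighted Use the two-step LD-score weights: a first pass with
#'   `1 / max(l_base, 1)` (damping LD overcounting), then the same weight
#'   divided by the squared predicted chi-square mean (damping the
#'   heteroskedastic noise of high-signal SNPs). `FALSE` gives ordinary
#'   least squares (useful for exact-reduction checks).
#' @return A `dlam_h2` object; see [tidy.dlam_h2()] and
#'   [glance.dlam_h2()].
#' @export
sldsc <- function(sumstats, ld, n_blocks = 20, weighted = TRUE) {
  if (!inherits(ld, "dlam_ldscores")) stop_input("`ld` must be dlam_ldscores")
  check_count(n_blocks, "n_blocks", 2)
  m <- nrow(ld$scores)
  if (nrow(sumstats) != m) stop_input("sumstats/LD score SNP mismatch")
  chi2 <- sumstats$CHI2
  N <- sumstats$N
  A <- ld$annotations
  C <- ncol(A)
  M_c <- colSums(A)
  design <- cbind(intercept = 1, sweep(ld$scores, 1, N, "*"))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[seq(qrd$rank + 1, ncol(design))]]
    stop_input(paste("collinear annotation columns:",
                     paste(bad, collapse = ", ")))
  }
  w <- rep(1, m)
  if (weighted) {
    w1 <- 1 / pmax(ld$scores[, 1], 1)
    b1 <- solve(crossprod(design * w1, design),
                crossprod(design * w1, chi2))
    pred <- pmax(as.vector(design %*% b1), 0.5)
    w <- w1 / pred^2
  }

  fit_fun <- function(idx) {
    X <- design[idx, , drop = FALSE]
    wi <- w[idx]
    b <- solve(crossprod(X * wi, X), crossprod(X * wi, chi2[idx]))
    tau <- b[-1]
    per_snp <- as.vector(A %*% tau)
    h2c <- as.vector(crossprod(A, per_snp))
    h2_tot <- h2c[1]
    prop <- h2c / h2_tot
    list(intercept = b[1], tau = tau, h2c = h2c, prop = prop)
  }

  full <- fit_fun(seq_len(m))
  blocks <- split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE))
  jk <- lapply(blocks, function(bl) fit_fun(setdiff(seq_len(m), bl)))

  jk_stat <- function(f) {
    matrix(vapply(jk, f, numeric(C)), nrow = C)
  }
  B <- length(jk)
  jack_se <- function(v) {
    # v: C x B (or vector of length B)
    if (is.null(dim(v))) {
      sqrt((B - 1) / B * sum((v - mean(v))^2))
    } else {
      apply(v, 1, function(r) sqrt((B - 1) / B * sum((r - mean(r))^2)))
    }
  }
  prop_snps <- M_c / m
  prop_jk <- jk_stat(function(x) x$prop)
  enr_jk <- sweep(prop_jk, 1, prop_snps, "/")
  diff_jk <- sweep(prop_jk, 1, prop_snps, "-")
  enrichment <- full$prop / prop_snps
  enr_se <- jack_se(enr_jk)
  diff_se <- jack_se(diff_jk)
  diff_hat <- full$prop - prop_snps
  tstat <- ifelse(diff_se > 0, diff_hat / diff_se, 0)
  enr_p <- 2 * pt(-abs(tstat), df = B - 1)
  enr_p[1] <- NA_real_  # base annotation: enrichment is 1 by construction

  int_jk <- vapply(jk, function(x) x$intercept, numeric(1))
  tau_jk <- jk_stat(function(x) x$tau[seq_len(C)])

  table <- tibble(
    annotation = colnames(A), M_c = as.integer(unname(M_c)),
    prop_snps = unname(prop_snps), tau = unname(full$tau),
    h2 = unname(full$h2c), prop_h2 = unname(full$prop),
    enrichment = unname(enrichment), enrichment_se = unname(enr_se),
    enrichment_p = unname(enr_p))
  structure(
    list(table = table, h2_total = full$h2c[1], intercept = full$intercept,
         intercept_se = jack_se(int_jk), n_blocks = B, n_snps = m,
         weighted = weighted,
         tau_se = if (C > 1) jack_se(tau_jk) else jack_se(t(tau_jk))),
    class = "dlam_h2")
}

#' @export
print.dlam_h2 <- function(x, ...) {
  cat("<dlam_h2>\n")
  cat(sprintf("  h2 total: %.4f   intercept: %.3f (SE %.3f)   %d SNPs, %d blocks\n",
              x$h2_total, x$intercept, x$intercept_se, x$n_snps, x$n_blocks))
  print(x$table)
  invisible(x)
}

#' Tidy a stratified heritability fit
#' @param x A `dlam_h2` object.
#' @param ... Unused.
#' @return Per-annotation tibble (tau, h2, proportions, enrichment with
#'   jackknife SE and p).
#' @export
tidy.dlam_h2 <- function(x, ...) x$table

#' One-row summary of a stratified heritability fit
#' @param x A `dlam_h2` object.
#' @param ... Unused.
#' @return Tibble with h2_total, intercept, intercept_se, n_snps, n_blocks.
#' @export
glance.dlam_h2 <- function(x, ...) {
  tibble(h2_total = x$h2_total, intercept = x$intercept,
         intercept_se = x$intercept_se, n_snps = x$n_snps,
         n_blocks = x$n_blocks)
}

#' Drop SNPs falling inside exclusion regions
#'
#' @param sumstats Summary-statistics tibble (SNP, CHR, BP, CHI2, N).
#' @param exclusions Interval tibble (chrom, start, end).
#' @return The filtered sumstats tibble.
#' @export
filter_sumstats_regions <- function(sumstats, exclusions) {
  inside <- snps_in_intervals(sumstats$CHR, sumstats$BP, exclusions)
  sumstats[inside == 0, , drop = FALSE]
}
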