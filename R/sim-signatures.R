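#' Simulate a pair of differential-expression signatures
#'
#' A fraction `concordance` of genes receives a shared latent effect (equal
#' in both signatures); the remaining genes get independent effects. The
#' observed log2 fold change is the latent effect plus Gaussian estimation
#' noise with standard error `se`, and the p-value is the two-sided normal
#' tail of log2FC / se.
#'
#' @param n_genes Number of genes (>= 10).
#' @param concordance Fraction of genes with shared effects, in \[0, 1\].
#' @param effect_sd Standard deviation of latent log2 fold changes.
#' @param se Per-gene standard error of the log2FC estimate.
#' @param seed Integer seed.
#' @return List with `sig_a`, `sig_b` (tibbles: gene, log2FC, pvalue) and
#'   `truth` (a `dlam_signature_truth`: shared_up, shared_down, concordance).
#' @export
sim_signature_pair <- function(n_genes = 2000, concordance = 0.5,
                               effect_sd = 1.5, se = 0.25, seed = 1) {
  check_count(n_genes, "n_genes", 10)
  if (concordance < 0 || concordance > 1) {
    stop_input("`concordance` must lie in [0, 1]")
  }
  if (effect_sd <= 0 || se <= 0) {
    stop_input("`effect_sd` and `se` must be positive")
  }
  set.seed(substream_seed(seed, 6L))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  n_shared <- round(concordance * n_genes)
  shared <- logical(n_genes)
  if (n_shared > 0) shared[sample(n_genes, n_shared)] <- TRUE

  u <- rnorm(n_genes, sd = effect_sd)
  b_a <- ifelse(shared, u, rnorm(n_genes, sd = effect_sd))
  b_b <- ifelse(shared, u, rnorm(n_genes, sd = effect_sd))

  make_sig <- function(b) {
    est <- b + rnorm(n_genes, sd = se)
    z <- est / se
    tibble(gene = genes, log2FC = est,
           pvalue = pmax(2 * pnorm(-abs(z)), 1e-300))
  }
  truth <- structure(
    list(shared_up = genes[shared & u > 0],
         shared_down = genes[shared & u < 0],
         concordance = concordance),
    class = "dlam_signature_truth")
  list(sig_a = make_sig(b_a), sig_b = make_sig(b_b), truth = truth)
}
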