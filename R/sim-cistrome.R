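#' Simulate a promoter/peak/motif fixture with recorded motif placements
#'
#' Lays genes out along one chromosome, places an open-chromatin peak inside
#' the +/- `flank` bp window around each TSS, fills peaks with i.i.d. uniform
#' background sequence, and embeds the motif consensus into the peaks of
#' DLAM genes with probability `embed_prob` at a recorded offset and strand.
#'
#' @param genes Character vector of gene IDs (one peak per gene).
#' @param dlam_genes Subset of `genes` whose peaks may receive a motif.
#' @param motif_width Motif width in bp (>= 4).
#' @param embed_prob Per-DLAM-gene probability of embedding one consensus
#'   instance, in \[0, 1\].
#' @param peak_width Peak width in bp.
#' @param flank Promoter half-width around the TSS (bp).
#' @param gene_spacing Distance between consecutive TSSs (bp).
#' @param seed Integer seed.
#'
#' @return List with `sequences` (named character vector, one per peak),
#'   `tss` (tibble: gene, chrom, tss, strand), `peaks` (tibble: chrom,
#'   start, end, name), `motif` (a `dlam_motif`) and `truth` (tibble: gene,
#'   peak_index, offset, strand of every embedded instance).
#' @export
sim_cistrome <- function(genes, dlam_genes, motif_width = 8, embed_prob = 1,
                         peak_width = 300, flank = 2000, gene_spacing = 1e4,
                         seed = 1) {
  if (motif_width < 4) stop_input("`motif_width` must be at least 4")
  if (embed_prob < 0 || embed_prob > 1) {
    stop_input("`embed_prob` must lie in [0, 1]")
  }
  if (!all(dlam_genes %in% genes)) {
    stop_input("`dlam_genes` must be a subset of `genes`")
  }
  if (peak_width <= motif_width) stop_input("peak narrower than motif")
  set.seed(substream_seed(seed, 4L))
  bases <- c("A", "C", "G", "T")
  n <- length(genes)

  tss <- tibble(gene = genes, chrom = "chr1",
                tss = flank + 1000 + (seq_len(n) - 1) * gene_spacing,
                strand = "+")

  # consensus with an informative PWM around it
  consensus <- sample(bases, motif_width, replace = TRUE)
  mat <- matrix(0.05, motif_width, 4, dimnames = list(NULL, bases))
  mat[cbind(seq_len(motif_width), match(consensus, bases))] <- 0.85
  motif <- new_motif("planted_motif", mat)

  # peaks placed fully inside the TSS +/- flank window
  off <- sample.int(2 * flank - peak_width + 1, n, replace = TRUE) - 1L
  start <- tss$tss - flank + off
  peaks <- tibble(chrom = "chr1", start = start, end = start + peak_width,
                  name = genes)

  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(bases, peak_width, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- genes

  truth <- tibble(gene = character(), peak_index = integer(),
                  offset = integer(), strand = character())
  cons_fwd <- paste(consensus, collapse = "")
  cons_rev <- revcomp(cons_fwd)
  for (g in dlam_genes) {
    if (runif(1) < embed_prob) {
      i <- match(g, genes)
      pos <- sample.int(peak_width - motif_width + 1, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") cons_fwd else cons_rev
      s <- seqs[[i]]
      substr(s, pos + 1, pos + motif_width) <- ins
      seqs[[i]] <- s
      truth <- dplyr::bind_rows(truth, tibble(
        gene = g, peak_index = i, offset = pos, strand = strand))
    }
  }
  list(sequences = seqs, tss = tss, peaks = peaks, motif = motif,
       truth = truth)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
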