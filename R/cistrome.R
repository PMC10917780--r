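#' Promoter windows around transcription start sites
#'
#' Builds the strand-independent window `[max(0, tss - flank), tss + flank)`
#' for every gene.
#'
#' @param tss Tibble with gene, chrom, tss (0-based), and optionally strand.
#' @param flank Half-width in bp (> 0; 2000 gives the usual +/- 2 kb
#'   promoter annotation).
#' @return Tibble: gene, chrom, start, end.
#' @export
#' @examples
#' make_promoters(tibble::tibble(gene = "g1", chrom = "chr1", tss = 5000))
make_promoters <- function(tss, flank = 2000) {
  if (!all(c("gene", "chrom", "tss") %in% names(tss))) {
    stop_input("`tss` needs gene, chrom, tss columns")
  }
  if (!is.numeric(flank) || flank <= 0) {
    stop_input("`flank` must be a positive width")
  }
  if (anyDuplicated(tss$gene)) {
    stop_input(sprintf("duplicate gene in TSS table: %s",
                       tss$gene[duplicated(tss$gene)][1]))
  }
  if (any(tss$tss < 0)) stop_input("negative TSS coordinate")
  tibble(gene = tss$gene, chrom = tss$chrom,
         start = pmax(0, tss$tss - flank), end = tss$tss + flank)
}

#' Create a motif object
#'
#' @param name Motif name.
#' @param mat Width x 4 probability matrix (columns A, C, G, T), rows
#'   summing to 1 within 1e-3; width must be at least 4.
#' @param background Background base probabilities (default uniform).
#' @param threshold Log-odds hit threshold; when `NULL`, 80\% of the
#'   maximum attainable score is used at scan time.
#' @return A `dlam_motif` object (with a log2 odds `score_matrix`).
#' @export
new_motif <- function(name, mat, background = rep(0.25, 4),
                      threshold = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop_input("motif matrix must have 4 columns")
  if (nrow(mat) < 4) stop_input("motif width must be at least 4")
  if (any(abs(rowSums(mat) - 1) > 1e-3)) {
    stop_input("motif rows must sum to 1 within 1e-3")
  }
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6) {
    stop_input("background must be positive probabilities summing to 1")
  }
  colnames(mat) <- c("A", "C", "G", "T")
  score <- log2(sweep(mat, 2, background, "/"))
  max_score <- sum(apply(score, 1, max))
  if (!is.null(threshold) && threshold > max_score + 1e-9) {
    stop_input("threshold exceeds the maximum attainable score")
  }
  structure(list(name = name, mat = mat, background = background,
                 score_matrix = score, max_score = max_score,
                 threshold = threshold),
            class = "dlam_motif")
}

#' @export
print.dlam_motif <- function(x, ...) {
  cat(sprintf("<dlam_motif> %s: width %d, max score %.2f bits%s\n", x$name,
              nrow(x$mat), x$max_score,
              if (is.null(x$threshold)) "" else
                sprintf(", threshold %.2f", x$threshold)))
  invisible(x)
}

motif_threshold <- function(motif, threshold = NULL) {
  threshold %||% motif$threshold %||% (0.8 * motif$max_score)
}

#' Scan sequences for motif hits on both strands
#'
#' Scores every offset with the motif's log2 odds against its background;
#' the reverse strand is scored on the reverse complement. Windows
#' containing non-ACGT characters are skipped; sequences shorter than the
#' motif yield no hits.
#'
#' @param sequences Character vector of sequences (names preserved).
#' @param motif A `dlam_motif`.
#' @param threshold Log-odds threshold; defaults to the motif's own, or
#'   80\% of its maximum attainable score.
#' @return Tibble: seq_index, seq_name, offset (0-based), strand, score,
#'   width.
#' @export
scan_motif <- function(sequences, motif, threshold = NULL) {
  if (!inherits(motif, "dlam_motif")) stop_input("`motif` must be a dlam_motif")
  thr <- motif_threshold(motif, threshold)
  hits <- as_tibble(scan_sequences_cpp(as.character(sequences),
                                       motif$score_matrix, thr))
  hits$seq_name <- if (is.null(names(sequences))) NA_character_ else
    names(sequences)[hits$seq_index]
  hits$width <- nrow(motif$mat)
  hits[, c("seq_index", "seq_name", "offset", "strand", "score", "width")]
}

#' Proxy-binding sites: peaks containing at least one motif hit
#'
#' @param peaks Interval tibble (chrom, start, end, ...), one row per
#'   sequence.
#' @param sequences Character vector, one sequence per peak.
#' @param motif A `dlam_motif`.
#' @param threshold Optional log-odds threshold override.
#' @return A `dlam_pbs` object: `tf_name`, `peaks` (the subset with >= 1
#'   hit, with their original `peak_index`), and `hits`.
#' @export
proxy_binding_sites <- function(peaks, sequences, motif, threshold = NULL) {
  if (nrow(peaks) != length(sequences)) {
    stop_input("one sequence per peak required")
  }
  hits <- scan_motif(sequences, motif, threshold)
  keep <- sort(unique(hits$seq_index))
  out <- peaks[keep, , drop = FALSE]
  out$peak_index <- keep
  structure(list(tf_name = motif$name, peaks = as_tibble(out), hits = hits),
            class = "dlam_pbs")
}

#' @export
print.dlam_pbs <- function(x, ...) {
  cat(sprintf("<dlam_pbs> %s: %d proxy-binding peaks, %d motif hits\n",
              x$tf_name, nrow(x$peaks), nrow(x$hits)))
  invisible(x)
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Fraction of genes with a proxy-bound promoter
#'
#' A gene is flagged when its promoter overlaps a proxy-binding interval by
#' at least 1 bp (half-open coordinates; a peak that only touches the
#' promoter's exclusive end does not count).
#'
#' @param genes Gene IDs to score; all must have a promoter entry.
#' @param promoters Promoter tibble from [make_promoters()].
#' @param pbs A `dlam_pbs` or an interval tibble of proxy-binding sites.
#' @return List with `fraction` and `genes` (tibble: gene, bound).
#' @export
proxy_bound_fraction <- function(genes, promoters, pbs) {
  miss <- setdiff(genes, promoters$gene)
  if (length(miss)) {
    stop_input(sprintf("gene without promoter entry: %s", miss[1]))
  }
  ivs <- if (inherits(pbs, "dlam_pbs")) pbs$peaks else pbs
  prom <- promoters[match(genes, promoters$gene), ]
  bound <- rep(FALSE, length(genes))
  if (nrow(ivs)) {
    ov <- GenomicRanges::countOverlaps(intervals_to_granges(prom),
                                       intervals_to_granges(ivs))
    bound <- ov > 0
  }
  list(fraction = mean(bound), genes = tibble(gene = genes, bound = bound))
}

#' Motif position histogram around region centers
#'
#' Maps motif-hit centers to offsets relative to their region's center,
#' restricts them to +/- `window / 2`, and counts them in `window / bin`
#' bins. Also reports the per-bp frequency `count / (n_regions * bin)`.
#'
#' @param regions Interval tibble; row i corresponds to `seq_index == i` in
#'   `hits`.
#' @param hits Hit tibble from [scan_motif()] (needs seq_index, offset,
#'   width).
#' @param window Total window width in bp (must be divisible by `bin`).
#' @param bin Bin width in bp.
#' @return Tibble: bin_start, bin_mid, count, freq.
#' @export
motif_position_histogram <- function(regions, hits, window = 2000,
                                     bin = 20) {
  if (window %% bin != 0) stop_input("`window` must be divisible by `bin`")
  n_bins <- window / bin
  breaks <- seq(-window / 2, window / 2, by = bin)
  centers <- floor((regions$start + regions$end) / 2)
  hit_abs <- regions$start[hits$seq_index] + hits$offset +
    floor(hits$width / 2)
  rel <- hit_abs - centers[hits$seq_index]
  rel <- rel[rel >= -window / 2 & rel <= window / 2]
  # left-closed bins; the exact right edge joins the last bin
  idx <- pmin(floor((rel + window / 2) / bin) + 1, n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  tibble(bin_start = breaks[-length(breaks)],
         bin_mid = breaks[-length(breaks)] + bin / 2,
         count = cnt,
         freq = cnt / (nrow(regions) * bin))
}

#' Drop intervals overlapping an exclusion list
#'
#' Removes every interval that overlaps any exclusion interval by at least
#' 1 bp (e.g., the APOE chr19:45000000-45800000 and MHC/HLA
#' chr6:28477797-33448354 regions routinely excluded from heritability
#' analyses). An empty exclusion list is the identity.
#'
#' @param intervals Interval tibble (chrom, start, end, ...).
#' @param exclusions Interval tibble of regions to exclude.
#' @return The filtered interval tibble.
#' @export
exclude_regions <- function(intervals, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(intervals)
  ov <- GenomicRanges::countOverlaps(intervals_to_granges(intervals),
                                     intervals_to_granges(exclusions))
  intervals[ov == 0, , drop = FALSE]
}
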