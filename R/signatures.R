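#' Signed ranking metric for a differential-expression signature
#'
#' Adds `metric = -log10(pvalue) * sign(log2FC)` to a signature table.
#' P-values are floored at 1e-300 so the metric stays finite; a zero
#' log2FC yields a zero metric.
#'
#' @param signature Tibble with gene, log2FC, pvalue (one row per gene).
#' @return The signature tibble with a `metric` column.
#' @export
#' @examples
#' ranking_metric(tibble::tibble(gene = "g", log2FC = 2, pvalue = 0.01))
ranking_metric <- function(signature) {
  need <- c("gene", "log2FC", "pvalue")
  if (!all(need %in% names(signature))) {
    stop_input("signature needs gene, log2FC, pvalue columns")
  }
  if (anyNA(signature$pvalue) || anyNA(signature$log2FC)) {
    stop_input("missing p-value or log2FC")
  }
  if (any(signature$pvalue < 0 | signature$pvalue > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  if (anyDuplicated(signature$gene)) stop_input("duplicate gene in signature")
  p <- pmax(signature$pvalue, 1e-300)
  signature$metric <- -log10(p) * sign(signature$log2FC)
  signature
}

# order genes by metric descending, ties by |log2FC| descending then gene ID
metric_order <- function(sig) {
  sig[order(-sig$metric, -abs(sig$log2FC), sig$gene), , drop = FALSE]
}

#' Stratified rank-rank hypergeometric overlap map
#'
#' Restricts both signatures to their common genes, splits each ranked list
#' at the metric's sign change into an up-sublist (most positive first) and
#' a down-sublist (most negative first), and computes, on a grid with step
#' `step`, the upper-tail hypergeometric p-value of the overlap between
#' the top prefixes of the paired sublists, with the common-gene count as
#' the universe. Up-up and down-down pixels form the concordant quadrants,
#' up-down and down-up the discordant ones. P-values are
#' Benjamini-Hochberg adjusted across all pixels of the map; each pixel
#' carries `-log10(adjusted p)` signed by over-/under-representation. Per
#' concordant quadrant the warmest pixel (smallest adjusted p) is reported
#' with its overlap gene list.
#'
#' @param sig_a,sig_b Signature tibbles (gene, log2FC, pvalue).
#' @param step Grid step; default
#'   `max(1, ceiling(sqrt(min(sublist lengths))))`.
#' @return A `dlam_rrho` object: `pixels` (tibble: quadrant, i, j, size_a,
#'   size_b, overlap, expected, pvalue, padj, signed_nlp), `warmest` (per
#'   concordant quadrant: i, j, overlap genes, pvalue, padj), `step`,
#'   `n_common`, sublist lengths.
#' @export
rrho_map <- function(sig_a, sig_b, step = NULL) {
  sig_a <- ranking_metric(sig_a)
  sig_b <- ranking_metric(sig_b)
  common <- intersect(sig_a$gene, sig_b$gene)
  if (length(common) < 100) {
    stop_input("need at least 100 genes common to both signatures")
  }
  a <- metric_order(sig_a[sig_a$gene %in% common, ])
  b <- metric_order(sig_b[sig_b$gene %in% common, ])
  N <- length(common)

  split_sig <- function(s) {
    zero <- sum(s$metric == 0)
    if (zero > 0) {
      warn(sprintf("%d gene(s) with zero metric dropped from the sublists",
                   zero))
    }
    list(up = s$gene[s$metric > 0],
         down = rev(s$gene[s$metric < 0]))  # most negative first
  }
  la <- split_sig(a)
  lb <- split_sig(b)
  lens <- c(lengths(la), lengths(lb))
  if (any(lens == 0)) {
    warn("a sublist is empty (all genes share one sign); affected quadrants are empty")
  }
  if (is.null(step)) step <- max(1, ceiling(sqrt(min(lens[lens > 0]))))
  step <- as.integer(step)

  quadrant_pixels <- function(ga, gb, qname) {
    na <- length(ga); nb <- length(gb)
    if (na == 0 || nb == 0) {
      return(tibble(quadrant = character(), i = integer(), j = integer(),
                    size_a = integer(), size_b = integer(),
                    overlap = integer(), expected = numeric(),
                    pvalue = numeric()))
    }
    ni <- ceiling(na / step); nj <- ceiling(nb / step)
    pos_b <- match(ga, gb)  # position of A-sublist genes inside B's sublist
    ia <- pmin(seq_len(ni) * step, na)
    jb <- pmin(seq_len(nj) * step, nb)
    # 2D cumulative overlap counts via a binned dominance table
    bin_a <- ceiling(seq_len(na) / step)
    present <- !is.na(pos_b)
    M <- matrix(0L, ni, nj)
    if (any(present)) {
      bi <- bin_a[present]
      bj <- ceiling(pos_b[present] / step)
      for (t in seq_along(bi)) M[bi[t], bj[t]] <- M[bi[t], bj[t]] + 1L
    }
    Kc <- matrix(apply(M, 2, cumsum), ni, nj)
    K <- matrix(apply(Kc, 1, cumsum), nj, ni)  # K[j, i]
    grid <- expand.grid(i = seq_len(ni), j = seq_len(nj))
    k <- K[cbind(grid$j, grid$i)]
    sa <- ia[grid$i]; sb <- jb[grid$j]
    tibble(quadrant = qname, i = grid$i, j = grid$j,
           size_a = sa, size_b = sb, overlap = as.integer(k),
           expected = as.numeric(sa) * sb / N,
           pvalue = phyper(k - 1, sa, N - sa, sb, lower.tail = FALSE))
  }

  pixels <- dplyr::bind_rows(
    quadrant_pixels(la$up, lb$up, "up_up"),
    quadrant_pixels(la$down, lb$down, "down_down"),
    quadrant_pixels(la$up, lb$down, "up_down"),
    quadrant_pixels(la$down, lb$up, "down_up"))
  pixels$padj <- p.adjust(pixels$pvalue, method = "BH")
  pixels$signed_nlp <- ifelse(pixels$overlap >= pixels$expected, 1, -1) *
    -log10(pmax(pixels$padj, 1e-300))

  warmest_of <- function(qname, ga, gb) {
    px <- pixels[pixels$quadrant == qname, ]
    if (!nrow(px)) return(NULL)
    best <- px[order(px$padj, -px$overlap), ][1, ]
    genes <- intersect(ga[seq_len(best$size_a)], gb[seq_len(best$size_b)])
    list(i = best$i, j = best$j, size_a = best$size_a, size_b = best$size_b,
         genes = genes, pvalue = best$pvalue, padj = best$padj)
  }
  warmest <- list(up_up = warmest_of("up_up", la$up, lb$up),
                  down_down = warmest_of("down_down", la$down, lb$down))

  structure(
    list(pixels = pixels, warmest = warmest, step = step, n_common = N,
         lengths = list(a_up = length(la$up), a_down = length(la$down),
                        b_up = length(lb$up), b_down = length(lb$down))),
    class = "dlam_rrho")
}

#' @export
print.dlam_rrho <- function(x, ...) {
  cat("<dlam_rrho>\n")
  cat(sprintf("  %d common genes, step %d, %d pixels\n", x$n_common, x$step,
              nrow(x$pixels)))
  for (q in names(x$warmest)) {
    w <- x$warmest[[q]]
    if (!is.null(w)) {
      cat(sprintf("  warmest %s: adj p = %.3g, %d overlap genes\n", q,
                  w$padj, length(w$genes)))
    }
  }
  invisible(x)
}

#' @export
tidy.dlam_rrho <- function(x, ...) x$pixels

#' @export
glance.dlam_rrho <- function(x, ...) {
  w <- x$warmest
  tibble(n_common = x$n_common, step = x$step, n_pixels = nrow(x$pixels),
         warmest_up_padj = w$up_up$padj %||% NA_real_,
         warmest_up_n = length(w$up_up$genes %||% character(0)),
         warmest_down_padj = w$down_down$padj %||% NA_real_,
         warmest_down_n = length(w$down_down$genes %||% character(0)))
}

#' Universe-restricted overlap test
#'
#' Upper-tail hypergeometric probability of the observed overlap between
#' two gene sets drawn from a universe of `universe_size` genes.
#'
#' @param set_a,set_b Character vectors.
#' @param universe_size Universe size (>= both set sizes).
#' @return One-row tibble: n_a, n_b, overlap, pvalue.
#' @export
restricted_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop_input("set larger than the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), universe_size - length(set_a),
              length(set_b), lower.tail = FALSE)
  tibble(n_a = length(set_a), n_b = length(set_b), overlap = k, pvalue = p)
}

#' Spearman comparison of two signatures
#'
#' Spearman rank correlation of log2 fold changes over the genes common to
#' both signatures (optionally restricted to `gene_subset`), with a 95\%
#' confidence interval from the Fisher z-transform and a two-sided normal
#' p-value.
#'
#' @param sig_a,sig_b Signature tibbles (gene, log2FC, ...).
#' @param gene_subset Optional gene filter.
#' @return One-row tibble: rho, conf.low, conf.high, pvalue, n.
#' @export
spearman_compare <- function(sig_a, sig_b, gene_subset = NULL) {
  common <- intersect(sig_a$gene, sig_b$gene)
  if (!is.null(gene_subset)) common <- intersect(common, gene_subset)
  if (length(common) < 10) stop_input("need at least 10 common genes")
  xa <- sig_a$log2FC[match(common, sig_a$gene)]
  xb <- sig_b$log2FC[match(common, sig_b$gene)]
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop_input("constant log2FC vector")
  }
  rho <- cor(xa, xb, method = "spearman")
  n <- length(common)
  z <- atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  p <- 2 * pnorm(-abs(z) / se)
  tibble(rho = rho, conf.low = ci[1], conf.high = ci[2], pvalue = p, n = n)
}
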