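#' Preranked geneset enrichment analysis
#'
#' Walks the ranked list accumulating `|metric|^weight` (normalized to sum
#' to one over the geneset) at geneset hits and a uniform decrement at
#' misses; the enrichment score (ES) is the extreme deviation of the
#' running sum. The null distribution draws `n_perm` random genesets of
#' the same size from the ranked genes; the normalized enrichment score
#' (NES) divides the ES by the mean magnitude of same-sign null ES values,
#' the nominal p-value is the fraction of same-sign null ES at least as
#' extreme, and the FDR q-value follows the standard same-sign pooled-null
#' procedure over the observed NES distribution.
#'
#' @param metric Named numeric vector of ranking metrics, or a signature
#'   tibble (gene, log2FC, pvalue) run through [ranking_metric()].
#' @param genesets Named list of genesets; sets smaller than `min_size`
#'   after intersection with the ranked genes are skipped with a warning.
#' @param n_perm Number of null genesets per observed set.
#' @param weight Hit-weight exponent (1 = classic weighted statistic; 0
#'   makes the ES depend on ranks only).
#' @param min_size Minimum geneset size after intersection.
#' @param seed Integer seed.
#' @return Tibble: geneset, size, es, nes, pvalue, qvalue, leading_edge
#'   (list column).
#' @export
gsea_preranked <- function(metric, genesets, n_perm = 1000, weight = 1,
                           min_size = 5, seed = 1) {
  if (is.data.frame(metric)) {
    sig <- metric_order(ranking_metric(metric))
    metric <- setNames(sig$metric, sig$gene)
  } else {
    if (is.null(names(metric))) stop_input("`metric` must be named by gene")
    metric <- sort(metric, decreasing = TRUE)
  }
  if (anyNA(metric)) stop_input("metric contains missing values")
  if (is.null(names(genesets)) || anyDuplicated(names(genesets))) {
    stop_input("`genesets` must be a uniquely named list")
  }
  genes <- names(metric)
  N <- length(genes)
  absw <- abs(metric)^weight

  es_stat <- function(pos) {
    # pos: sorted hit positions within the ranked list
    nh <- length(pos)
    w <- absw[pos]
    sw <- sum(w)
    hit_cum <- if (sw > 0) cumsum(w) / sw else seq_len(nh) / nh
    miss_unit <- 1 / (N - nh)
    after <- hit_cum - (pos - seq_len(nh)) * miss_unit
    before <- c(0, hit_cum[-nh]) - (pos - seq_len(nh)) * miss_unit
    hi <- max(after)
    lo <- min(before)
    if (hi >= -lo) {
      list(es = hi, peak = pos[which.max(after)], positive = TRUE)
    } else {
      list(es = lo, peak = pos[which.min(before)], positive = FALSE)
    }
  }

  set.seed(substream_seed(seed, 13L))
  res <- list()
  null_nes <- list()
  for (nm in names(genesets)) {
    pos <- sort(match(intersect(genesets[[nm]], genes), genes))
    n_hit <- length(pos)
    if (n_hit < min_size) {
      warn(sprintf("geneset %s has fewer than %d genes after intersection; skipped",
                   nm, min_size))
      next
    }
    obs <- es_stat(pos)
    null_es <- vapply(seq_len(n_perm), function(i) {
      es_stat(sort(sample.int(N, n_hit)))$es
    }, numeric(1))
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    mean_mag <- if (length(same)) mean(abs(same)) else NA_real_
    nes <- if (!is.na(mean_mag) && mean_mag > 0) obs$es / mean_mag else NA_real_
    pval <- if (length(same)) {
      sum(abs(same) >= abs(obs$es)) / length(same)
    } else 1 / (n_perm + 1)
    # null NES normalized by the same-sign mean magnitude (pooled later)
    pos_mean <- mean(null_es[null_es >= 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    nes_null <- ifelse(null_es >= 0,
                       null_es / ifelse(pos_mean > 0, pos_mean, NA_real_),
                       null_es / ifelse(neg_mean > 0, neg_mean, NA_real_))
    null_nes[[nm]] <- nes_null[is.finite(nes_null)]
    leading <- if (obs$positive) {
      genes[pos[pos <= obs$peak]]
    } else {
      genes[pos[pos >= obs$peak]]
    }
    res[[nm]] <- tibble(geneset = nm, size = n_hit, es = obs$es, nes = nes,
                        pvalue = pval, leading_edge = list(leading))
  }
  if (!length(res)) {
    return(tibble(geneset = character(), size = integer(), es = numeric(),
                  nes = numeric(), pvalue = numeric(), qvalue = numeric(),
                  leading_edge = list()))
  }
  out <- dplyr::bind_rows(res)
  pool <- unlist(null_nes, use.names = FALSE)
  out$qvalue <- vapply(out$nes, function(s) {
    if (is.na(s)) return(NA_real_)
    if (s >= 0) {
      num_pool <- pool[pool >= 0]
      obs_nes <- out$nes[!is.na(out$nes) & out$nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= s) else 0
      den <- mean(obs_nes >= s)
    } else {
      num_pool <- pool[pool < 0]
      obs_nes <- out$nes[!is.na(out$nes) & out$nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= s) else 0
      den <- mean(obs_nes <= s)
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))
  out[, c("geneset", "size", "es", "nes", "pvalue", "qvalue",
          "leading_edge")]
}
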