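# Independent oracles used across tests. Deliberately naive implementations:
# direct summation, exhaustive enumeration, O(n^2) double loops.

# upper-tail hypergeometric by direct term-by-term summation
hyper_tail_oracle <- function(k, N, K, n) {
  if (k > min(K, n)) return(0)
  i <- seq(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# DPI by exhaustive scan over all node triplets
dpi_oracle <- function(edges, regulators, tolerance = 0) {
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  mi_map <- tapply(edges$mi, ukey(edges$regulator, edges$target), max)
  nodes <- unique(c(edges$regulator, edges$target))
  drop <- character(0)
  for (a in nodes) for (b in nodes) for (t in nodes) {
    if (a >= b || a == t || b == t) next
    if (!(a %in% regulators && b %in% regulators)) next
    k1 <- ukey(a, t); k2 <- ukey(b, t); k12 <- ukey(a, b)
    if (anyNA(c(mi_map[k1], mi_map[k2], mi_map[k12]))) next
    tol <- 1 + tolerance
    if (mi_map[k1] * tol < mi_map[k12] && mi_map[k1] * tol < mi_map[k2]) {
      drop <- c(drop, k1)
    }
    if (mi_map[k2] * tol < mi_map[k12] && mi_map[k2] * tol < mi_map[k1]) {
      drop <- c(drop, k2)
    }
    if (t %in% regulators &&
        mi_map[k12] * tol < mi_map[k1] && mi_map[k12] * tol < mi_map[k2]) {
      drop <- c(drop, k12)
    }
  }
  edges[!(ukey(edges$regulator, edges$target) %in% drop), ]
}

# random candidate edge set over a small node universe, for DPI testing
random_edge_graph <- function(n_nodes = 20, n_regs = 6, p_edge = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  regs <- nodes[seq_len(n_regs)]
  cand <- expand.grid(regulator = regs, target = nodes,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$regulator != cand$target, ]
  # undirected sampling: keep one record per unordered pair
  key <- paste(pmin(cand$regulator, cand$target),
               pmax(cand$regulator, cand$target))
  cand <- cand[!duplicated(key), ]
  keep <- runif(nrow(cand)) < p_edge
  out <- cand[keep, ]
  out$mi <- runif(nrow(out), 0.05, 1)
  tibble::as_tibble(out)
}

# GSEA enrichment score by literal running-sum unrolling
gsea_es_oracle <- function(metric_sorted, hits, weight = 1) {
  N <- length(metric_sorted)
  is_hit <- names(metric_sorted) %in% hits
  nh <- sum(is_hit)
  w <- abs(metric_sorted)^weight
  sw <- sum(w[is_hit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (is_hit[i]) w[i] / sw else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# O(m^2) partitioned LD scores with per-pair correlation
ld_scores_oracle <- function(X, pos, annot, window) {
  n <- nrow(X); m <- ncol(X)
  Xs <- scale(X) * sqrt(n / (n - 1))  # rescale to a 1/n-denominator sd
  out <- matrix(0, m, ncol(annot))
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (abs(pos[k] - pos[j]) > window) next
    r <- sum(Xs[, j] * Xs[, k]) / n
    adj <- r^2 - (1 - r^2) / (n - 2)
    out[j, ] <- out[j, ] + adj * annot[k, ]
  }
  out
}

# brute-force motif scan: re-score every window on both strands
scan_oracle <- function(seqs, motif, threshold) {
  lo <- motif$score_matrix
  w <- nrow(lo)
  rc_seq <- function(s) dlamreg:::revcomp(s)
  out <- list()
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    L <- nchar(s)
    if (L < w) next
    for (off in 0:(L - w)) {
      win <- substr(s, off + 1, off + w)
      if (grepl("[^ACGT]", win)) next
      score_of <- function(x) {
        b <- match(strsplit(x, "")[[1]], c("A", "C", "G", "T"))
        sum(lo[cbind(seq_len(w), b)])
      }
      fw <- score_of(win)
      rv <- score_of(rc_seq(win))
      if (fw >= threshold) {
        out[[length(out) + 1]] <- data.frame(seq_index = si, offset = off,
                                             strand = "+", score = fw)
      }
      if (rv >= threshold) {
        out[[length(out) + 1]] <- data.frame(seq_index = si, offset = off,
                                             strand = "-", score = rv)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_index = integer(), offset = integer(),
                      strand = character(), score = numeric()))
  }
  do.call(rbind, out)
}
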