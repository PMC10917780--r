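#' Mutual information by adaptive partitioning
#'
#' Rank-transforms both vectors to (0, 1] (ties broken by first occurrence)
#' and recursively partitions the unit square into four equal-area
#' quadrants while the 4-cell occupancy chi-square statistic exceeds
#' `chi_crit` (7.815 = upper 5\% of chi-square with 3 df) and the cell holds
#' at least `4 * min_leaf` points. The estimate, in nats, is
#' `sum over leaves of (n_l/n) * log((n_l/n) / area_l)`, floored at zero.
#' Being rank-based, it is invariant under strictly monotone transforms of
#' either argument and symmetric in its arguments.
#'
#' @param x,y Numeric vectors of equal length `n >= 16`.
#' @param min_leaf Minimum expected points per child cell.
#' @param chi_crit Chi-square recursion threshold.
#' @return Nonnegative scalar MI in nats.
#' @export
#' @examples
#' x <- rnorm(500)
#' estimate_mi(x, x + rnorm(500, sd = 0.3))
estimate_mi <- function(x, y, min_leaf = 8, chi_crit = 7.815) {
  if (length(x) != length(y)) stop_input("`x` and `y` differ in length")
  if (length(x) < 16) stop_input("need at least 16 observations")
  mi_ap_cpp(as.numeric(x), as.numeric(y), as.integer(min_leaf), chi_crit)
}

# rank rows to (0,1] after adding tie-breaking jitter from the current
# RNG stream (uniform in (0, 1e-9))
ranked_rows <- function(mat, jitter = TRUE) {
  if (jitter) {
    mat <- mat + matrix(runif(length(mat), 0, 1e-9), nrow(mat))
  }
  r <- rank_rows_cpp(mat)
  rownames(r) <- rownames(mat)
  r
}

#' Permutation-calibrated MI threshold
#'
#' Draws `n_null` null MI values from randomly chosen gene pairs with one
#' member independently permuted, fits `log(empirical tail probability)` as
#' a linear function of MI over the top `tail_frac` of the null values, and
#' returns the MI at which the fitted line reaches `log(target_p)`.
#'
#' @param mat Expression matrix, genes x samples (metacell CPM values).
#' @param target_p Target tail probability (1e-8 mirrors the usual network
#'   reconstruction setting).
#' @param n_null Number of null draws (>= 1e4).
#' @param tail_frac Fraction of the largest null values used for the fit.
#' @param seed Integer seed.
#' @param min_leaf,chi_crit Passed to the MI estimator.
#' @return Scalar MI threshold (nats).
#' @export
mi_threshold <- function(mat, target_p = 1e-8, n_null = 1e5,
                         tail_frac = 0.01, seed = 1, min_leaf = 8,
                         chi_crit = 7.815) {
  if (n_null < 1e4) stop_input("`n_null` must be at least 1e4")
  if (target_p <= 0 || target_p >= 1) stop_input("`target_p` must be in (0,1)")
  set.seed(substream_seed(seed, 11L))
  ranks <- ranked_rows(mat)
  null <- mi_null_cpp(ranks, as.integer(n_null), as.integer(min_leaf),
                      chi_crit)
  null <- sort(null, decreasing = TRUE)
  # the null has a point mass at zero (no significant split); fit the
  # exponential tail over the top tail_frac, restricted to positive values
  m <- min(ceiling(tail_frac * n_null), sum(null > 0))
  if (m < 20) {
    stop_input("degenerate null tail: too few positive null MI values")
  }
  top <- null[seq_len(m)]
  tailp <- seq_len(m) / n_null
  fit <- lm(log(tailp) ~ top)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0) {
    stop_input("degenerate fit: null tail slope is not negative")
  }
  (log(target_p) - coef(fit)[[1]]) / slope
}

#' Infer a single MI network
#'
#' Scores every (regulator, gene) pair by mutual information, keeps pairs
#' with MI at or above `threshold`, and (by default) prunes likely indirect
#' edges with the data processing inequality.
#'
#' @param mat Expression matrix, genes x samples.
#' @param regulators Character vector of regulator gene IDs (intersected
#'   with the matrix rows; an empty intersection is an error).
#' @param threshold MI threshold (nats), usually from [mi_threshold()].
#' @param dpi Apply DPI pruning.
#' @param dpi_tolerance DPI tolerance (see [apply_dpi()]).
#' @param min_leaf,chi_crit MI estimator settings.
#' @param ranks Optional pre-ranked matrix (internal use).
#' @return Tibble of edges: regulator, target, mi.
#' @export
infer_network <- function(mat, regulators, threshold, dpi = TRUE,
                          dpi_tolerance = 0, min_leaf = 8, chi_crit = 7.815,
                          ranks = NULL) {
  if (is.null(ranks)) ranks <- ranked_rows(mat)
  regulators <- intersect(regulators, rownames(ranks))
  if (!length(regulators)) {
    stop_input("no regulator is present in the expression matrix")
  }
  reg_rows <- match(regulators, rownames(ranks))
  mi <- mi_pairs_cpp(ranks, reg_rows, as.integer(min_leaf), chi_crit)
  dimnames(mi) <- list(regulators, rownames(ranks))
  hit <- which(!is.na(mi) & mi >= threshold, arr.ind = TRUE)
  edges <- tibble(regulator = regulators[hit[, 1]],
                  target = rownames(ranks)[hit[, 2]],
                  mi = mi[hit])
  # TF-TF pairs appear once per direction; DPI treats them as one edge
  if (dpi) edges <- apply_dpi(edges, dpi_tolerance, regulators)
  edges
}

#' Data processing inequality pruning
#'
#' For every triplet (r1, r2, t) in which the three edges r1-t, r2-t and
#' r1-r2 are all present, the edge r1-t is marked for removal when its MI is
#' strictly below both `mi(r1, r2)` and `mi(r2, t)` after inflating it by
#' `1 + tolerance`. All decisions are taken against the original MI values;
#' marked edges are removed together at the end. A regulator-regulator edge
#' is itself removable when the third vertex of its triangle is a
#' regulator. The output is always a subset of the input.
#'
#' @param edges Edge tibble with regulator, target, mi.
#' @param tolerance Relative tolerance (0 = strict weakest-edge removal).
#' @param regulators Regulator IDs; defaults to the regulators occurring in
#'   `edges`.
#' @return The pruned edge tibble.
#' @export
apply_dpi <- function(edges, tolerance = 0, regulators = NULL) {
  if (nrow(edges) == 0) return(edges)
  if (!all(c("regulator", "target", "mi") %in% names(edges))) {
    stop_input("`edges` needs regulator, target, mi columns")
  }
  if (is.null(regulators)) regulators <- unique(edges$regulator)

  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  key <- ukey(edges$regulator, edges$target)
  mi_map <- tapply(edges$mi, key, max)  # duplicates of a pair share one MI
  targets_of <- split(edges$target, edges$regulator)
  is_reg <- function(x) x %in% regulators

  drop <- character(0)
  regs <- intersect(regulators, names(targets_of))
  if (length(regs) >= 2) {
    for (a in seq_len(length(regs) - 1)) {
      for (b in seq(a + 1, length(regs))) {
        r1 <- regs[a]; r2 <- regs[b]
        k12 <- ukey(r1, r2)
        mi12 <- mi_map[k12]
        if (is.na(mi12)) next
        common <- setdiff(intersect(targets_of[[r1]], targets_of[[r2]]),
                          c(r1, r2))
        for (t in common) {
          k1 <- ukey(r1, t); k2 <- ukey(r2, t)
          mi1 <- mi_map[k1]; mi2 <- mi_map[k2]
          tol <- 1 + tolerance
          if (mi1 * tol < mi12 && mi1 * tol < mi2) drop <- c(drop, k1)
          if (mi2 * tol < mi12 && mi2 * tol < mi1) drop <- c(drop, k2)
          if (is_reg(t) && mi12 * tol < mi1 && mi12 * tol < mi2) {
            drop <- c(drop, k12)
          }
        }
      }
    }
  }
  edges[!(key %in% drop), , drop = FALSE]
}

#' Bootstrap network reconstruction with Poisson consolidation
#'
#' Resamples metacell columns with replacement `n_bootstraps` times, infers
#' a DPI-pruned network per bootstrap at a fixed MI threshold, counts per
#' edge the number of supporting bootstraps, and tests each unique edge
#' against a Poisson null whose rate is the mean support over unique edges.
#' Benjamini-Hochberg significant edges (FDR below `fdr`) are retained with
#' their mean MI over supporting bootstraps.
#'
#' @param mat Expression matrix, genes x samples.
#' @param regulators Regulator gene IDs.
#' @param threshold MI threshold computed once on the full matrix.
#' @param n_bootstraps Number of bootstraps (>= 2; 200 mirrors the usual
#'   reconstruction setting).
#' @param fdr Consolidation FDR cutoff.
#' @param seed Integer seed; each bootstrap uses a derived substream.
#' @param dpi,dpi_tolerance,min_leaf,chi_crit Passed to [infer_network()].
#' @return A `dlam_grn` object with consolidated `edges` (regulator,
#'   target, mi, support, pvalue, fdr), the full bootstrap `pool`, the
#'   threshold and bootstrap count.
#' @export
bootstrap_network <- function(mat, regulators, threshold,
                              n_bootstraps = 200, fdr = 0.05, seed = 1,
                              dpi = TRUE, dpi_tolerance = 0, min_leaf = 8,
                              chi_crit = 7.815) {
  check_count(n_bootstraps, "n_bootstraps", 2)
  n <- ncol(mat)
  pool_env <- new.env(parent = emptyenv())
  for (b in seq_len(n_bootstraps)) {
    set.seed(substream_seed(seed, 20L + b))
    cols <- sample.int(n, n, replace = TRUE)
    ranks <- ranked_rows(mat[, cols, drop = FALSE])
    eb <- infer_network(NULL, regulators, threshold, dpi = dpi,
                        dpi_tolerance = dpi_tolerance, min_leaf = min_leaf,
                        chi_crit = chi_crit, ranks = ranks)
    if (nrow(eb)) {
      keys <- paste(eb$regulator, eb$target, sep = "\r")
      for (i in seq_along(keys)) {
        cur <- pool_env[[keys[i]]]
        if (is.null(cur)) cur <- c(0, 0)
        pool_env[[keys[i]]] <- cur + c(1, eb$mi[i])
      }
    }
  }
  keys <- ls(pool_env)
  if (!length(keys)) stop_input("no edge observed in any bootstrap")
  dlam_log(sprintf("%d unique edges across %d bootstraps", length(keys),
                   n_bootstraps), level = 2)
  supp <- vapply(keys, function(k) pool_env[[k]][1], numeric(1))
  misum <- vapply(keys, function(k) pool_env[[k]][2], numeric(1))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  pool <- tibble(regulator = vapply(parts, `[`, character(1), 1),
                 target = vapply(parts, `[`, character(1), 2),
                 support = as.integer(unname(supp)),
                 mi = unname(misum / supp))
  consolidate_pool(pool, n_bootstraps, fdr, threshold)
}

# Poisson consolidation over a pooled edge-support table.
consolidate_pool <- function(pool, n_bootstraps, fdr, threshold = NA_real_) {
  lambda <- sum(pool$support) / nrow(pool)
  pvalue <- ppois(pool$support - 1, lambda, lower.tail = FALSE)
  adj <- p.adjust(pvalue, method = "BH")
  edges <- pool
  edges$pvalue <- pvalue
  edges$fdr <- adj
  edges <- edges[edges$fdr < fdr, , drop = FALSE]
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  pool <- pool[order(pool$regulator, pool$target), , drop = FALSE]
  structure(
    list(edges = as_tibble(edges), pool = as_tibble(pool),
         mi_threshold = threshold, n_bootstraps = n_bootstraps,
         fdr = fdr, lambda = lambda),
    class = "dlam_grn")
}

#' Meta-network across datasets
#'
#' Pools the bootstrap edge supports of several networks (e.g., all
#' datasets of one species) and consolidates the pooled pool with the same
#' Poisson/Benjamini-Hochberg procedure, with the rate recomputed on the
#' pooled counts. With a single input this reduces exactly to that
#' network's own consolidation.
#'
#' @param networks List of `dlam_grn` objects.
#' @param fdr Consolidation FDR cutoff.
#' @return A `dlam_grn` with pooled support.
#' @export
meta_network <- function(networks, fdr = 0.05) {
  if (!length(networks)) stop_input("empty network list")
  if (!all(vapply(networks, inherits, logical(1), "dlam_grn"))) {
    stop_input("`networks` must be dlam_grn objects")
  }
  pools <- lapply(networks, function(x) x$pool)
  pooled <- dplyr::bind_rows(pools)
  pooled <- dplyr::summarise(
    dplyr::group_by(pooled, .data$regulator, .data$target),
    mi = sum(.data$mi * .data$support) / sum(.data$support),
    support = as.integer(sum(.data$support)), .groups = "drop")
  pooled <- pooled[, c("regulator", "target", "support", "mi")]
  n_boot <- sum(vapply(networks, function(x) x$n_bootstraps, numeric(1)))
  consolidate_pool(pooled, n_boot, fdr)
}

#' @export
print.dlam_grn <- function(x, ...) {
  cat("<dlam_grn>\n")
  cat(sprintf("  %d consolidated edges over %d regulators (%d bootstraps, FDR < %g)\n",
              nrow(x$edges), length(unique(x$edges$regulator)),
              x$n_bootstraps, x$fdr))
  if (is.finite(x$mi_threshold %||% NA_real_)) {
    cat(sprintf("  MI threshold: %.4f nats\n", x$mi_threshold))
  }
  invisible(x)
}

#' @export
tidy.dlam_grn <- function(x, ...) x$edges

#' @export
glance.dlam_grn <- function(x, ...) {
  tibble(n_edges = nrow(x$edges),
         n_regulators = length(unique(x$edges$regulator)),
         n_bootstraps = x$n_bootstraps,
         mi_threshold = x$mi_threshold %||% NA_real_,
         fdr = x$fdr, lambda = x$lambda)
}
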