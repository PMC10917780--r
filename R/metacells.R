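#' Counts-per-million normalization
#'
#' Scales every column (cell or metacell) to a total of one million.
#'
#' @param mat Numeric matrix, genes x cells, all column sums positive.
#' @return Matrix of the same shape on the CPM scale.
#' @export
#' @examples
#' cpm_normalize(matrix(c(1, 1, 2), 3, 1, dimnames = list(letters[1:3], "c1")))
cpm_normalize <- function(mat) {
  cs <- colSums(mat)
  if (any(cs <= 0)) {
    stop_input(sprintf("zero-sum column: %s",
                       paste(head(colnames(mat)[cs <= 0], 3), collapse = ", ")))
  }
  sweep(mat, 2, 1e6 / cs, "*")
}

#' Correlation distance between cell expression profiles
#'
#' Distance `1 - r` where `r` is the Pearson correlation between cell
#' profiles, computed on `log2(CPM + 1)` by default (raw CPM with
#' `log = FALSE`).
#'
#' @param mat CPM-scale matrix, genes x cells, with at least 2 cells and 2
#'   variable genes.
#' @param log Correlate log2(CPM + 1) profiles (default) or raw CPM.
#' @return Symmetric cells x cells distance matrix with a zero diagonal.
#' @export
correlation_distance <- function(mat, log = TRUE) {
  if (ncol(mat) < 2 || nrow(mat) < 2) {
    stop_input("need at least 2 cells and 2 genes")
  }
  x <- if (log) log2(mat + 1) else mat
  xc <- sweep(x, 2, colMeans(x))
  s <- sqrt(colSums(xc^2))
  if (any(s == 0)) {
    stop_input(sprintf("constant cell profile: %s",
                       paste(head(colnames(mat)[s == 0], 3), collapse = ", ")))
  }
  xs <- sweep(xc, 2, s, "/")
  d <- 1 - crossprod(xs)
  d[d < 0] <- 0  # clip rounding noise
  diag(d) <- 0
  d
}

#' Aggregate single cells into metacells
#'
#' Samples `sub_size` seed cells without replacement; each metacell is the
#' elementwise sum of raw counts over a seed cell and its
#' `num_neighbors - 1` nearest cells under `dist` (seed included; overlapping
#' membership across metacells is allowed). The aggregate is CPM-normalized
#' and genes are filtered to those non-zero in at least `min_nonzero_frac`
#' of metacells. Neighbor ties are broken by cell ID for reproducibility.
#'
#' @param counts Count matrix, genes x cells.
#' @param dist Cells x cells distance matrix; computed with
#'   [correlation_distance()] on CPM values when `NULL`.
#' @param num_neighbors Cells aggregated per metacell (>= 1).
#' @param sub_size Number of metacells (>= 2, <= number of cells).
#' @param min_nonzero_frac Gene filter threshold (see [filter_genes()]).
#' @param seed Integer seed for the seed-cell sample.
#' @return A `dlam_metacells` object: `values` (filtered CPM matrix, genes x
#'   metacells), `raw` (pre-normalization sums, all genes), `members`
#'   (list of member cell IDs) and `params`.
#' @export
make_metacells <- function(counts, dist = NULL, num_neighbors = 10,
                           sub_size = 200, min_nonzero_frac = 0.75,
                           seed = 1) {
  counts <- validate_count_matrix(counts)
  n_cells <- ncol(counts)
  check_count(num_neighbors, "num_neighbors")
  check_count(sub_size, "sub_size", 2)
  if (num_neighbors > n_cells) stop_input("`num_neighbors` exceeds cell count")
  if (sub_size > n_cells) stop_input("`sub_size` exceeds cell count")
  if (is.null(dist)) {
    dist <- correlation_distance(cpm_normalize(counts))
  }
  if (!all(dim(dist) == n_cells)) stop_input("distance matrix shape mismatch")

  set.seed(substream_seed(seed, 7L))
  seeds <- sort(sample(n_cells, sub_size))
  ids <- colnames(counts)

  members <- vector("list", sub_size)
  raw <- matrix(0L, nrow(counts), sub_size,
                dimnames = list(rownames(counts),
                                sprintf("mc%04d", seq_len(sub_size))))
  for (m in seq_len(sub_size)) {
    s <- seeds[m]
    if (num_neighbors == 1) {
      sel <- s
    } else {
      others <- setdiff(seq_len(n_cells), s)
      ord <- others[order(dist[others, s], ids[others])]
      sel <- c(s, ord[seq_len(num_neighbors - 1)])
    }
    members[[m]] <- ids[sel]
    raw[, m] <- as.integer(rowSums(counts[, sel, drop = FALSE]))
  }

  values <- filter_genes(cpm_normalize(raw), min_nonzero_frac)
  structure(
    list(values = values, raw = raw, members = members,
         params = list(num_neighbors = num_neighbors, sub_size = sub_size,
                       min_nonzero_frac = min_nonzero_frac, seed = seed)),
    class = "dlam_metacells")
}

#' Filter genes by metacell detection rate
#'
#' Retains exactly the genes with a nonzero value in at least
#' `ceiling(min_nonzero_frac * n_metacells)` columns.
#'
#' @param mat Expression matrix, genes x metacells.
#' @param min_nonzero_frac Required detection fraction, in (0, 1].
#' @return The filtered matrix; raises an error if no gene survives.
#' @export
filter_genes <- function(mat, min_nonzero_frac = 0.75) {
  if (!is.numeric(min_nonzero_frac) || min_nonzero_frac <= 0 ||
      min_nonzero_frac > 1) {
    stop_input("`min_nonzero_frac` must lie in (0, 1]")
  }
  need <- ceiling(min_nonzero_frac * ncol(mat))
  keep <- rowSums(mat != 0) >= need
  if (!any(keep)) stop_input("no gene passes the detection filter")
  mat[keep, , drop = FALSE]
}

#' @export
print.dlam_metacells <- function(x, ...) {
  cat("<dlam_metacells>\n")
  cat(sprintf("  %d genes x %d metacells (num_neighbors = %d)\n",
              nrow(x$values), ncol(x$values), x$params$num_neighbors))
  invisible(x)
}

#' @export
glance.dlam_metacells <- function(x, ...) {
  tibble(n_genes = nrow(x$values), n_metacells = ncol(x$values),
         num_neighbors = x$params$num_neighbors,
         sub_size = x$params$sub_size,
         min_nonzero_frac = x$params$min_nonzero_frac)
}
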