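#' Read a count matrix (MTX triplet or dense TSV)
#'
#' Accepts either the path of a MatrixMarket file together with gene and
#' cell ID files (one ID per line), or a single dense TSV whose header row
#' holds the cell IDs and whose first column holds gene IDs. Entries must be
#' nonnegative integers and IDs unique; anything else raises a
#' `dlamreg_format_error`.
#'
#' @param path MTX file path or dense TSV path.
#' @param genes,cells Paths of the gene/cell ID files (MTX mode only).
#' @return Integer matrix, genes x cells, with ID dimnames.
#' @export
read_count_matrix <- function(path, genes = NULL, cells = NULL) {
  if (!is.null(genes) || !is.null(cells)) {
    if (is.null(genes) || is.null(cells)) {
      stop_format("MTX mode needs both `genes` and `cells` ID files")
    }
    check_mtx_entry_count(path)
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop_format(paste0("malformed MTX file: ", conditionMessage(e)))
    })
    gid <- readLines(genes)
    cid <- readLines(cells)
    if (nrow(m) != length(gid) || ncol(m) != length(cid)) {
      stop_format(sprintf(
        "MTX dimensions %d x %d do not match %d gene / %d cell IDs",
        nrow(m), ncol(m), length(gid), length(cid)))
    }
    mat <- as.matrix(m)
    dimnames(mat) <- list(gid, cid)
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    gid <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- gid
  }
  validate_count_matrix(mat)
}

# The MatrixMarket header declares the entry count; readMM() tolerates a
# short file, so the declared and actual counts are compared explicitly.
check_mtx_entry_count <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (!length(body)) stop_format("empty MTX file")
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]]))
  if (length(hdr) != 3 || anyNA(hdr)) stop_format("malformed MTX header")
  declared <- hdr[3]
  actual <- length(body) - 1
  if (actual != declared) {
    stop_format(sprintf("MTX declares %d entries but contains %d",
                        declared, actual))
  }
  invisible(path)
}

validate_count_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_format("count matrix must carry gene and cell IDs")
  }
  if (anyDuplicated(rownames(mat))) stop_format("duplicate gene IDs")
  if (anyDuplicated(colnames(mat))) stop_format("duplicate cell IDs")
  if (!is.numeric(mat)) stop_format("non-numeric entries in count matrix")
  if (anyNA(mat)) stop_format("missing values in count matrix")
  if (any(mat < 0)) stop_format("negative entries in count matrix")
  if (any(mat != floor(mat))) stop_format("non-integer entries in count matrix")
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count matrix as an MTX triplet or dense TSV
#'
#' @param mat Integer matrix with gene/cell dimnames.
#' @param path Output MTX path (with `genes`/`cells`) or dense TSV path.
#' @param genes,cells Output ID file paths (MTX mode).
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(mat, path, genes = NULL, cells = NULL) {
  mat <- validate_count_matrix(mat)
  if (!is.null(genes) || !is.null(cells)) {
    if (is.null(genes) || is.null(cells)) {
      stop_format("MTX mode needs both `genes` and `cells` ID files")
    }
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), genes)
    writeLines(colnames(mat), cells)
  } else {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT geneset collection
#'
#' Tab-separated lines: set name, description, then gene IDs. Lines with
#' fewer than three fields, duplicate set names or empty gene lists raise a
#' `dlamreg_format_error`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad)) {
    stop_format(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  nm <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop_format(sprintf("duplicate geneset name: %s", nm[duplicated(nm)][1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0)) stop_format("empty geneset")
  sets
}

#' Write a GMT geneset collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_format("genesets must have unique names")
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' Coordinates are 0-based half-open. Intervals with `start >= end`,
#' negative starts or non-numeric coordinates raise a
#' `dlamreg_format_error`. Input order is preserved.
#'
#' @param path BED file path.
#' @return Tibble with chrom, start, end and (when present) name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop_format("BED needs at least 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nm[seq_len(min(ncol(df), 6))]
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(start) || anyNA(end)) stop_format("non-numeric BED coordinates")
  if (any(start != floor(start) | end != floor(end))) {
    stop_format("non-integer BED coordinates")
  }
  if (any(start < 0)) stop_format("negative BED start")
  if (any(start >= end)) stop_format("BED interval with start >= end")
  df$start <- as.integer(start)
  df$end <- as.integer(end)
  as_tibble(df)
}

#' Write intervals as BED
#' @param intervals Tibble with chrom, start, end and optional name, score,
#'   strand columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  if (!all(c("chrom", "start", "end") %in% cols)) {
    stop_format("intervals need chrom, start, end")
  }
  if (any(intervals$start >= intervals$end)) {
    stop_format("BED interval with start >= end")
  }
  write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motifs from a PWM text file
#'
#' Dialect: a line starting with `>` gives the motif name and an optional
#' log-odds threshold; the following rows give per-position probabilities
#' for A, C, G, T. Rows must sum to 1 within 1e-3 and are renormalized with
#' a 1e-4 pseudocount on read.
#'
#' @param path Motif file path.
#' @return Named list of `dlam_motif` objects.
#' @export
read_motif <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_format("no motif header ('>') found")
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1]]
    nm <- hd[1]
    thr <- if (length(hd) > 1) as.numeric(hd[2]) else NULL
    body <- lines[seq(heads[i] + 1, bounds[i + 1] - 1)]
    rows <- lapply(strsplit(body, "\\s+"), as.numeric)
    if (any(vapply(rows, length, integer(1)) != 4) || anyNA(unlist(rows))) {
      stop_format(sprintf("motif %s: rows must hold 4 numeric values", nm))
    }
    mat <- do.call(rbind, rows)
    if (any(abs(rowSums(mat) - 1) > 1e-3)) {
      stop_format(sprintf("motif %s: probabilities do not sum to 1", nm))
    }
    mat <- mat + 1e-4
    mat <- mat / rowSums(mat)
    colnames(mat) <- c("A", "C", "G", "T")
    out[[nm]] <- new_motif(nm, mat, threshold = thr)
  }
  out
}

#' Write motifs to a PWM text file
#' @param motifs A `dlam_motif` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motif <- function(motifs, path) {
  if (inherits(motifs, "dlam_motif")) motifs <- list(motifs)
  lines <- character(0)
  for (m in motifs) {
    hd <- paste0(">", m$name)
    if (!is.null(m$threshold)) hd <- paste(hd, format(m$threshold, digits = 10))
    lines <- c(lines, hd,
               apply(m$mat, 1, function(r) paste(format(r, digits = 8),
                                                 collapse = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a network edge table
#'
#' TSV with columns Regulator, Target, MI, Support, Pvalue, FDR.
#'
#' @param path TSV path.
#' @return Tibble with regulator, target, mi, support, pvalue, fdr.
#' @export
read_network <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("Regulator", "Target", "MI", "Support", "Pvalue", "FDR")
  if (!all(need %in% names(df))) {
    stop_format(paste("network TSV needs columns:", paste(need, collapse = ", ")))
  }
  tibble(regulator = as.character(df$Regulator),
         target = as.character(df$Target), mi = as.numeric(df$MI),
         support = as.integer(df$Support), pvalue = as.numeric(df$Pvalue),
         fdr = as.numeric(df$FDR))
}

#' @rdname read_network
#' @param edges Edge tibble (regulator, target, mi, support, pvalue, fdr).
#' @export
write_network <- function(edges, path) {
  df <- data.frame(Regulator = edges$regulator, Target = edges$target,
                   MI = edges$mi,
                   Support = edges$support %||% NA_integer_,
                   Pvalue = edges$pvalue %||% NA_real_,
                   FDR = edges$fdr %||% NA_real_)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write GWAS summary statistics
#'
#' TSV with columns SNP, CHR, BP, CHI2, N (chi-square statistics are
#' consumed directly).
#'
#' @param path TSV path.
#' @return Tibble with SNP, CHR, BP, CHI2, N.
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "CHI2", "N")
  if (!all(need %in% names(df))) {
    stop_format(paste("sumstats TSV needs columns:", paste(need, collapse = ", ")))
  }
  if (any(df$CHI2 < 0)) stop_format("negative chi-square")
  as_tibble(df[, need])
}

#' @rdname read_sumstats
#' @param sumstats Tibble with SNP, CHR, BP, CHI2, N.
#' @export
write_sumstats <- function(sumstats, path) {
  write.table(sumstats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a TSS table
#'
#' 4-column TSV: gene, chrom, tss, strand, with 0-based TSS coordinates.
#'
#' @param path TSV path.
#' @return Tibble with gene, chrom, tss, strand.
#' @export
read_tss <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop_format("TSS table needs columns gene, chrom, tss, strand")
  }
  if (any(df$tss < 0)) stop_format("negative TSS coordinate")
  as_tibble(df[, need])
}

#' @rdname read_tss
#' @param tss Tibble with gene, chrom, tss, strand.
#' @export
write_tss <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
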