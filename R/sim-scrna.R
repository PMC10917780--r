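#' Simulate single-cell counts with a planted DLAM subpopulation
#'
#' Generates a genes x cells matrix of negative-binomial UMI-like counts in
#' which a subset of cells occupies a DLAM-like activation state driven by a
#' small set of planted transcription factors (TFs). Each planted TF carries a
#' per-cell activity that is shifted by `effect_size` in DLAM cells; each of
#' its target genes responds to the weighted sum of its regulators'
#' activities on the log scale. The remaining "decoy" TFs drive independent
#' modules tied to their own random cell subsets, so that network inference
#' has realistic true negatives as well as non-DLAM true edges.
#'
#' The per-cell expected proportions are a softmax over
#' `log(base_rate) + sum(w * activity)`, scaled by a log-normal library size,
#' so column totals track the drawn library sizes up to negative-binomial
#' sampling noise.
#'
#' @param n_cells,n_genes,n_tfs Dimensions of the simulation. TFs occupy the
#'   first `n_tfs` gene slots and form the regulator list.
#' @param n_dlam_tfs Number of planted DLAM regulators (first TFs).
#' @param dlam_fraction Fraction of cells in the DLAM state, in (0, 1).
#' @param effect_size Activity shift of a planted TF in DLAM cells (and of a
#'   decoy TF in its own "on" cells); 0 gives a null dataset.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param n_dlam_genes Number of DLAM target genes.
#' @param module_size Targets per decoy TF module.
#' @param decoy_fraction Fraction of cells in which a decoy TF is active.
#' @param activity_sd Within-state standard deviation of TF activities.
#' @param lib_median,lib_sigma Log-normal library-size parameters.
#' @param species_tag Label stored in the truth object.
#' @param seed Integer seed; fixed seeds give bit-identical output.
#'
#' @return A list with `counts` (integer matrix, genes x cells) and `truth`,
#'   a `dlam_scrna_truth` object holding `planted_tfs`, `decoy_tfs`,
#'   `dlam_geneset`, `true_edges` (tibble: tf, target, weight),
#'   `cell_state` (named vector, `baseline`/`DLAM`), `regulators`,
#'   `lib_size` and `species_tag`.
#' @export
#' @examples
#' sim <- sim_scrna(n_cells = 200, n_genes = 80, n_tfs = 8, seed = 1)
#' dim(sim$counts)
#' sim$truth$planted_tfs
sim_scrna <- function(n_cells = 2000, n_genes = 500, n_tfs = 30,
                      n_dlam_tfs = 3, dlam_fraction = 0.3, effect_size = 2.5,
                      dispersion = 0.1, n_dlam_genes = 60, module_size = 8,
                      decoy_fraction = 0.25, activity_sd = 1,
                      lib_median = 5000, lib_sigma = 0.3,
                      species_tag = "human", seed = 1, .topology = NULL) {
  check_count(n_cells, "n_cells", 2)
  check_count(n_genes, "n_genes", 4)
  check_count(n_tfs, "n_tfs")
  check_count(n_dlam_tfs, "n_dlam_tfs")
  if (!is.numeric(dlam_fraction) || dlam_fraction <= 0 || dlam_fraction >= 1) {
    stop_input("`dlam_fraction` must lie strictly inside (0, 1)")
  }
  if (n_tfs >= n_genes) stop_input("`n_tfs` must be smaller than `n_genes`")
  if (n_dlam_tfs > n_tfs) stop_input("`n_dlam_tfs` cannot exceed `n_tfs`")
  if (dispersion <= 0) stop_input("`dispersion` must be positive")
  if (effect_size < 0) stop_input("`effect_size` must be nonnegative")

  topo <- .topology %||% scrna_topology(n_genes, n_tfs, n_dlam_tfs,
                                        n_dlam_genes, module_size, seed)
  draw <- scrna_draw(topo, n_cells, dlam_fraction, effect_size, dispersion,
                     decoy_fraction, activity_sd, lib_median, lib_sigma, seed)

  truth <- structure(
    list(planted_tfs = topo$planted_tfs,
         decoy_tfs = topo$decoy_tfs,
         regulators = topo$regulators,
         genes = topo$genes,
         dlam_geneset = topo$dlam_geneset,
         true_edges = topo$true_edges,
         cell_state = draw$cell_state,
         lib_size = draw$lib_size,
         species_tag = species_tag),
    class = "dlam_scrna_truth")
  list(counts = draw$counts, truth = truth)
}

# Regulatory topology shared across datasets generated from the same seed.
scrna_topology <- function(n_genes, n_tfs, n_dlam_tfs, n_dlam_genes,
                           module_size, seed) {
  n_decoy <- n_tfs - n_dlam_tfs
  need <- n_tfs + n_dlam_genes + n_decoy * module_size
  if (need > n_genes) {
    stop_input(sprintf(
      "topology needs %d genes (TFs + DLAM targets + decoy modules) but n_genes = %d",
      need, n_genes))
  }
  set.seed(substream_seed(seed, 1L))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  regulators <- genes[seq_len(n_tfs)]
  planted <- regulators[seq_len(n_dlam_tfs)]
  decoys <- setdiff(regulators, planted)

  pool <- sample(genes[(n_tfs + 1):n_genes])
  dlam_targets <- sort(pool[seq_len(n_dlam_genes)])
  pool <- pool[-seq_len(n_dlam_genes)]

  # response sign alternates across targets so an activation state moves
  # genes both up and down (composition-balanced, like real DLAM signatures)
  edges <- list()
  sgn <- list()
  for (gi in seq_along(dlam_targets)) {
    g <- dlam_targets[gi]
    k <- sample(seq_len(min(2L, n_dlam_tfs)), 1)
    for (tf in sample(planted, k)) {
      edges[[length(edges) + 1]] <- c(tf, g)
      sgn[[length(sgn) + 1]] <- if (gi %% 2 == 0) 1 else -1
    }
  }
  for (i in seq_along(decoys)) {
    tgts <- pool[seq_len(module_size) + (i - 1) * module_size]
    for (gi in seq_along(tgts)) {
      edges[[length(edges) + 1]] <- c(decoys[i], tgts[gi])
      sgn[[length(sgn) + 1]] <- if (gi %% 2 == 0) 1 else -1
    }
  }
  true_edges <- tibble(
    tf = vapply(edges, `[`, character(1), 1),
    target = vapply(edges, `[`, character(1), 2),
    weight = unlist(sgn) * runif(length(edges), 0.5, 1.5))

  # regulators are drawn well-expressed (TF lists in this setting are
  # restricted to detectably expressed genes); other genes vary more
  base_rate <- setNames(rlnorm(n_genes, 0, 0.5), genes)
  base_rate[regulators] <- rlnorm(n_tfs, log(3), 0.25)
  list(genes = genes, regulators = regulators, planted_tfs = planted,
       decoy_tfs = decoys, dlam_geneset = dlam_targets,
       true_edges = true_edges, base_rate = base_rate)
}

scrna_draw <- function(topo, n_cells, dlam_fraction, effect_size, dispersion,
                       decoy_fraction, activity_sd, lib_median, lib_sigma,
                       seed) {
  set.seed(substream_seed(seed, 2L))
  genes <- topo$genes
  n_genes <- length(genes)
  n_tfs <- length(topo$regulators)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  n_dlam <- round(n_cells * dlam_fraction)
  state <- rep("baseline", n_cells)
  state[sample(n_cells, n_dlam)] <- "DLAM"
  is_dlam <- state == "DLAM"

  lib_size <- rlnorm(n_cells, log(lib_median), lib_sigma)

  act <- matrix(rnorm(n_tfs * n_cells, sd = activity_sd), n_tfs, n_cells,
                dimnames = list(topo$regulators, cells))
  for (tf in topo$planted_tfs) {
    act[tf, is_dlam] <- act[tf, is_dlam] + effect_size
  }
  for (tf in topo$decoy_tfs) {
    on <- runif(n_cells) < decoy_fraction
    act[tf, on] <- act[tf, on] + effect_size
  }

  # loading matrix: TFs load on their own activity, targets on their edges
  W <- matrix(0, n_genes, n_tfs, dimnames = list(genes, topo$regulators))
  W[cbind(topo$regulators, topo$regulators)] <- 1
  W[cbind(topo$true_edges$target, topo$true_edges$tf)] <- topo$true_edges$weight

  # hierarchical composition: each module (planted TFs + DLAM targets, one
  # per decoy TF with its targets, background) holds a fixed share of the
  # library; activities redistribute mass only within their module, so
  # modules are exactly independent in composition
  module <- rep(0L, n_genes)
  names(module) <- genes
  module[c(topo$planted_tfs, topo$dlam_geneset)] <- 1L
  for (i in seq_along(topo$decoy_tfs)) {
    tf <- topo$decoy_tfs[i]
    tgts <- topo$true_edges$target[topo$true_edges$tf == tf]
    module[c(tf, tgts)] <- i + 1L
  }
  r <- topo$base_rate[genes]
  share <- tapply(r, module, sum) / sum(r)

  E <- r * exp(W %*% act)
  Z <- rowsum(E, module)               # module totals per cell
  p <- E / Z[match(module, rownames(Z)), , drop = FALSE]
  p <- p * as.numeric(share[match(module, names(share))])
  mu <- sweep(p, 2, lib_size, "*")

  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
                   n_genes, n_cells, dimnames = list(genes, cells))
  list(counts = counts, cell_state = setNames(state, cells),
       lib_size = setNames(lib_size, cells))
}

#' Simulate a cross-species panel of single-cell datasets
#'
#' Draws one shared regulatory topology and then generates `n_per_species`
#' independent count matrices for each species from it. Gene IDs carry a
#' species suffix and an identity ortholog map links them, so cross-species
#' consensus nomination can be exercised with known truth.
#'
#' @param n_per_species Datasets per species.
#' @param species Character vector of species labels (two expected).
#' @param ... Passed on to [sim_scrna()] (dimensions, effect sizes, ...).
#' @param seed Integer seed.
#' @return List with `datasets` (named list of `list(counts, truth)`),
#'   `ortholog_map` (tibble with one ID column per species) and `species`.
#' @export
sim_scrna_panel <- function(n_per_species = 3,
                            species = c("human", "mouse"), ..., seed = 1) {
  check_count(n_per_species, "n_per_species")
  if (length(species) < 1) stop_input("at least one species required")
  suffix <- paste0("_", substr(species, 1, 2))
  # one shared topology: datasets differ only in their cell draws
  args <- list(...)
  topo_arg <- function(nm) args[[nm]] %||% formals(sim_scrna)[[nm]]
  topo <- scrna_topology(topo_arg("n_genes"), topo_arg("n_tfs"),
                         topo_arg("n_dlam_tfs"), topo_arg("n_dlam_genes"),
                         topo_arg("module_size"), seed)
  datasets <- list()
  map <- NULL
  for (si in seq_along(species)) {
    for (k in seq_len(n_per_species)) {
      sim <- sim_scrna(..., species_tag = species[si], .topology = topo,
                       seed = substream_seed(seed, 100L * si + k))
      rownames(sim$counts) <- paste0(rownames(sim$counts), suffix[si])
      tr <- sim$truth
      tr$planted_tfs <- paste0(tr$planted_tfs, suffix[si])
      tr$decoy_tfs <- paste0(tr$decoy_tfs, suffix[si])
      tr$regulators <- paste0(tr$regulators, suffix[si])
      tr$genes <- paste0(tr$genes, suffix[si])
      tr$dlam_geneset <- paste0(tr$dlam_geneset, suffix[si])
      tr$true_edges$tf <- paste0(tr$true_edges$tf, suffix[si])
      tr$true_edges$target <- paste0(tr$true_edges$target, suffix[si])
      sim$truth <- tr
      datasets[[paste0(species[si], "_", k)]] <- sim
      if (is.null(map)) {
        base <- sub(paste0(suffix[si], "$"), "", rownames(sim$counts))
        map <- tibble(.base = base)
      }
    }
  }
  for (si in seq_along(species)) {
    map[[species[si]]] <- paste0(map$.base, suffix[si])
  }
  map$.base <- NULL
  list(datasets = datasets, ortholog_map = map, species = species)
}

#' Derive DLAM enrichment genesets from a simulation truth
#'
#' Emulates the three independently derived DLAM genesets used as enrichment
#' targets: each set is a random subset of the true DLAM genes plus a few
#' unrelated genes, so the sets overlap without being identical.
#'
#' @param truth A `dlam_scrna_truth` object.
#' @param n_sets Number of genesets.
#' @param include_frac Fraction of the true DLAM genes kept in each set.
#' @param n_noise Unrelated genes added to each set.
#' @param seed Integer seed.
#' @return Named list of character vectors (a geneset collection).
#' @export
dlam_genesets <- function(truth, n_sets = 3, include_frac = 0.75,
                          n_noise = 10, seed = 1) {
  if (!inherits(truth, "dlam_scrna_truth")) {
    stop_input("`truth` must come from sim_scrna()")
  }
  set.seed(substream_seed(seed, 3L))
  dlam <- truth$dlam_geneset
  other <- setdiff(truth$genes, c(dlam, truth$planted_tfs))
  sets <- lapply(seq_len(n_sets), function(i) {
    core <- sample(dlam, max(1, round(include_frac * length(dlam))))
    sort(unique(c(core, sample(other, min(n_noise, length(other))))))
  })
  names(sets) <- paste0("DLAM_set", seq_len(n_sets))
  sets
}

#' @export
print.dlam_scrna_truth <- function(x, ...) {
  cat("<dlam_scrna_truth>\n")
  cat("  planted TFs:", paste(x$planted_tfs, collapse = ", "), "\n")
  cat("  decoy TFs:", length(x$decoy_tfs), "\n")
  cat("  DLAM genes:", length(x$dlam_geneset),
      " true edges:", nrow(x$true_edges), "\n")
  cat("  cells:", length(x$cell_state),
      sprintf(" (%d DLAM)", sum(x$cell_state == "DLAM")), "\n")
  invisible(x)
}
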