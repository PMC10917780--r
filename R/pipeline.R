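#' End-to-end regulator nomination over a panel of datasets
#'
#' Runs the full nomination pipeline on a list of count datasets: metacell
#' aggregation, MI threshold calibration, bootstrap network reconstruction
#' with Poisson consolidation, per-network regulon geneset enrichment, and
#' two-tier cross-species consensus nomination.
#'
#' @param panel Output of [sim_scrna_panel()], or a compatible list with
#'   `datasets` (named `list(counts, truth)` entries, names
#'   `<species>_<k>`), `ortholog_map` and `species`.
#' @param genesets_per_species Named list (by species) of geneset
#'   collections used for regulon enrichment. When `NULL`, three DLAM
#'   genesets are derived from each species' truth via [dlam_genesets()].
#' @param num_neighbors,sub_size Metacell parameters.
#' @param target_p,n_null MI threshold calibration parameters.
#' @param n_bootstraps,consolidate_fdr Network consolidation parameters.
#' @param fdr_cut Regulon enrichment nomination FDR cutoff.
#' @param expressed_genes Optional expressed-gene filter for the
#'   high-confidence tier; defaults to the union of genes retained in the
#'   first species' metacell matrices (mapped to first-species IDs).
#' @param seed Integer seed.
#' @return List with `consensus` (tibble from [consensus_nomination()]),
#'   `networks` (per-dataset `dlam_grn`), `records` (enrichment records),
#'   `nominations` (per-network nominated TFs) and `thresholds`.
#' @export
run_nomination_pipeline <- function(panel, genesets_per_species = NULL,
                                    num_neighbors = 10, sub_size = 200,
                                    target_p = 1e-8, n_null = 1e5,
                                    n_bootstraps = 200,
                                    consolidate_fdr = 0.05, fdr_cut = 0.2,
                                    expressed_genes = NULL, seed = 1) {
  datasets <- panel$datasets
  species_of <- vapply(datasets, function(d) d$truth$species_tag,
                       character(1))
  if (is.null(genesets_per_species)) {
    genesets_per_species <- list()
    for (sp in panel$species) {
      first <- datasets[[which(species_of == sp)[1]]]
      genesets_per_species[[sp]] <- dlam_genesets(first$truth, seed = seed)
    }
  }

  networks <- list()
  thresholds <- numeric(0)
  records <- list()
  expressed_first <- character(0)
  for (i in seq_along(datasets)) {
    nm <- names(datasets)[i]
    sp <- species_of[i]
    ds <- datasets[[i]]
    mc <- make_metacells(ds$counts, num_neighbors = num_neighbors,
                         sub_size = sub_size,
                         seed = substream_seed(seed, 1000L + i))
    thr <- mi_threshold(mc$values, target_p = target_p, n_null = n_null,
                        seed = substream_seed(seed, 2000L + i))
    dlam_log(sprintf("[%s] %d genes x %d metacells, MI threshold %.4f",
                     nm, nrow(mc$values), ncol(mc$values), thr))
    net <- bootstrap_network(mc$values, ds$truth$regulators, thr,
                             n_bootstraps = n_bootstraps,
                             fdr = consolidate_fdr,
                             seed = substream_seed(seed, 3000L + i))
    dlam_log(sprintf("[%s] %d consolidated edges", nm, nrow(net$edges)))
    universe <- rownames(mc$values)
    rec <- regulon_enrichment(net, genesets_per_species[[sp]], universe,
                              network_id = nm, species = sp)
    networks[[nm]] <- net
    thresholds[nm] <- thr
    records[[nm]] <- rec
    if (sp == panel$species[1]) {
      expressed_first <- union(expressed_first, universe)
    }
  }
  records <- dplyr::bind_rows(records)
  nom <- nominate_tfs(records, fdr_cut = fdr_cut)
  registry <- tibble(network_id = names(datasets), species = species_of)
  consensus <- consensus_nomination(
    nom$nominations, registry, ortholog_map = panel$ortholog_map,
    expressed_genes = expressed_genes %||% expressed_first)
  list(consensus = consensus, networks = networks, records = nom$records,
       nominations = nom$nominations, thresholds = thresholds)
}
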