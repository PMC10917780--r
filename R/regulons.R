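#' Extract regulons from a consolidated network
#'
#' One entry per regulator with at least one retained edge; targets never
#' include the regulator itself.
#'
#' @param network A `dlam_grn` or an edge tibble with regulator/target.
#' @return Named list mapping regulator to its target set.
#' @export
extract_regulons <- function(network) {
  edges <- if (inherits(network, "dlam_grn")) network$edges else network
  if (!nrow(edges)) return(setNames(list(), character(0)))
  sp <- split(edges$target, edges$regulator)
  mapply(function(tf, tg) sort(unique(setdiff(tg, tf))), names(sp), sp,
         SIMPLIFY = FALSE)
}

#' Hypergeometric geneset over-representation of one regulon
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a regulon and a geneset inside an expressed-gene
#' universe. Regulon and geneset are intersected with the universe first.
#'
#' @param regulon Character vector of target genes.
#' @param geneset Character vector of geneset genes.
#' @param universe Character vector, the expressed-gene background.
#' @param tf,geneset_name,network_id,species Optional labels carried into
#'   the record.
#' @return One-row tibble: network_id, species, tf, geneset_name, universe
#'   size `N`, geneset size `K`, regulon size `n`, overlap `k`, pvalue.
#' @export
hypergeom_enrichment <- function(regulon, geneset, universe, tf = NA_character_,
                                 geneset_name = NA_character_,
                                 network_id = NA_character_,
                                 species = NA_character_) {
  universe <- unique(universe)
  if (!length(universe)) stop_input("empty universe")
  reg <- intersect(unique(regulon), universe)
  set <- intersect(unique(geneset), universe)
  N <- length(universe)
  K <- length(set)
  n <- length(reg)
  k <- length(intersect(reg, set))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(network_id = network_id, species = species, tf = tf,
         geneset_name = geneset_name, N = N, K = K, n = n, k = k,
         pvalue = p)
}

#' Enrichment records for every regulon x geneset pair of one network
#'
#' @param network A `dlam_grn` (or edge tibble).
#' @param genesets Named list of genesets.
#' @param universe Expressed-gene universe (typically the genes retained in
#'   the network's filtered metacell matrix).
#' @param network_id,species Labels stamped on every record.
#' @return Tibble of enrichment records (one row per TF x geneset).
#' @export
regulon_enrichment <- function(network, genesets, universe,
                               network_id = "network1",
                               species = NA_character_) {
  if (is.null(names(genesets)) || anyDuplicated(names(genesets))) {
    stop_input("`genesets` must be a uniquely named list")
  }
  regs <- extract_regulons(network)
  purrr::list_rbind(purrr::imap(regs, function(targets, tf) {
    purrr::list_rbind(purrr::imap(genesets, function(set, nm) {
      hypergeom_enrichment(targets, set, universe, tf = tf,
                           geneset_name = nm, network_id = network_id,
                           species = species)
    }))
  }))
}

#' Nominate TFs within one or more networks
#'
#' Benjamini-Hochberg FDR is computed across TFs within each
#' (network, geneset) stratum; a TF is nominated in a network when its
#' regulon is enriched (FDR below `fdr_cut`) for every geneset tested in
#' that network. A TF missing a geneset record counts as non-enriched.
#'
#' @param records Enrichment records from [regulon_enrichment()]
#'   (possibly several networks bound together).
#' @param fdr_cut Nomination FDR cutoff.
#' @return List with `records` (input plus an `fdr` column) and
#'   `nominations` (tibble: network_id, species, tf).
#' @export
nominate_tfs <- function(records, fdr_cut = 0.2) {
  if (!nrow(records)) {
    return(list(records = records,
                nominations = tibble(network_id = character(),
                                     species = character(),
                                     tf = character())))
  }
  records <- dplyr::mutate(
    dplyr::group_by(records, .data$network_id, .data$geneset_name),
    fdr = p.adjust(.data$pvalue, method = "BH"))
  records <- dplyr::ungroup(records)

  noms <- dplyr::summarise(
    dplyr::group_by(records, .data$network_id, .data$species, .data$tf),
    n_sets = dplyr::n_distinct(.data$geneset_name),
    n_hit = sum(.data$fdr < fdr_cut), .groups = "drop")
  per_net <- dplyr::summarise(
    dplyr::group_by(records, .data$network_id),
    total_sets = dplyr::n_distinct(.data$geneset_name), .groups = "drop")
  noms <- dplyr::left_join(noms, per_net, by = "network_id")
  noms <- noms[noms$n_hit == noms$total_sets & noms$n_sets == noms$total_sets, ]
  list(records = records,
       nominations = noms[, c("network_id", "species", "tf")])
}

#' Two-tier cross-species consensus nomination
#'
#' TFs are keyed by the first species' ID through a 1:1 ortholog map. A TF
#' reaches the `replicated` tier when nominated in at least
#' `replicate_min` networks of every species, and the `high_confidence`
#' tier when nominated in at least half (ceiling) of every species'
#' networks and, when `expressed_genes` is given, present in it. TFs
#' absent from the ortholog map are excluded with a warning.
#'
#' @param nominations Tibble: network_id, species, tf (per-network
#'   nominations, e.g. from [nominate_tfs()]).
#' @param networks Tibble: network_id, species — the full registry of
#'   networks, including those that nominated nothing.
#' @param ortholog_map Tibble with one ID column per species (1:1 rows).
#'   `NULL` treats IDs as shared across species.
#' @param expressed_genes Optional expressed-gene filter for the
#'   high-confidence tier (keyed like the first species' IDs).
#' @param replicate_min Networks per species required for the replicated
#'   tier.
#' @return Tibble: tf (first-species ID), one `n_<species>` count column
#'   per species, tier (`none`, `replicated` or `high_confidence`).
#' @export
consensus_nomination <- function(nominations, networks, ortholog_map = NULL,
                                 expressed_genes = NULL, replicate_min = 2) {
  # species order: ortholog-map column order when given (its first column
  # keys the output), otherwise alphabetical — invariant to row order
  species <- if (!is.null(ortholog_map)) {
    intersect(names(ortholog_map), unique(networks$species))
  } else {
    sort(unique(networks$species))
  }
  if (!length(species)) stop_input("no species shared with the ortholog map")
  n_per_species <- table(unique(networks[, c("network_id", "species")])$species)

  key_of <- function(tf, sp) {
    if (is.null(ortholog_map)) return(tf)
    col <- ortholog_map[[sp]]
    if (is.null(col)) stop_input(sprintf("no ortholog column for %s", sp))
    idx <- match(tf, col)
    ortholog_map[[species[1]]][idx]
  }

  noms <- nominations
  noms$key <- noms$tf
  if (!is.null(ortholog_map)) {
    noms$key <- NA_character_
    for (sp in species) {
      sel <- noms$species == sp
      noms$key[sel] <- key_of(noms$tf[sel], sp)
    }
    if (anyNA(noms$key)) {
      miss <- unique(noms$tf[is.na(noms$key)])
      warn(sprintf("%d TF(s) missing from the ortholog map were excluded: %s",
                   length(miss), paste(head(miss, 5), collapse = ", ")))
      noms <- noms[!is.na(noms$key), ]
    }
  }

  counts <- dplyr::summarise(
    dplyr::group_by(noms, .data$key, .data$species),
    n = dplyr::n_distinct(.data$network_id), .groups = "drop")
  wide <- tidyr::pivot_wider(counts, names_from = "species",
                             values_from = "n", values_fill = 0L)
  for (sp in species) {
    if (!sp %in% names(wide)) wide[[sp]] <- 0L
  }

  half <- setNames(ceiling(as.numeric(n_per_species[species]) / 2), species)
  cnt <- as.matrix(wide[, species, drop = FALSE])
  replicated <- apply(cnt >= replicate_min, 1, all)
  highc <- apply(sweep(cnt, 2, half[colnames(cnt)], ">="), 1, all)
  if (!is.null(expressed_genes)) {
    highc <- highc & wide$key %in% expressed_genes
  }
  tier <- ifelse(highc & replicated, "high_confidence",
                 ifelse(replicated, "replicated", "none"))
  out <- tibble(tf = wide$key)
  for (sp in species) out[[paste0("n_", sp)]] <- as.integer(wide[[sp]])
  out$tier <- tier
  dplyr::arrange(out, dplyr::desc(.data$tier == "high_confidence"),
                 dplyr::desc(.data$tier == "replicated"), .data$tf)
}

#' Per-TF max-scaled MI matrix for heatmap export
#'
#' Rows are regulators, columns the requested genes; each row is scaled by
#' its maximum MI so regulons are comparable across TFs. A plain matrix
#' export (one normalization convention among several possible ones).
#'
#' @param network A `dlam_grn`.
#' @param tfs Regulators to include (default: all).
#' @param genes Target genes to include (default: all targets).
#' @return Numeric matrix, TFs x genes, values in \[0, 1\].
#' @export
normalized_mi_matrix <- function(network, tfs = NULL, genes = NULL) {
  edges <- if (inherits(network, "dlam_grn")) network$edges else network
  tfs <- tfs %||% sort(unique(edges$regulator))
  genes <- genes %||% sort(unique(edges$target))
  m <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  sel <- edges$regulator %in% tfs & edges$target %in% genes
  m[cbind(edges$regulator[sel], edges$target[sel])] <- edges$mi[sel]
  mx <- apply(m, 1, max)
  mx[mx == 0] <- 1
  sweep(m, 1, mx, "/")
}
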