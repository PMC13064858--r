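#' Pipeline configuration
#'
#' Returns the configuration object holding every numeric threshold of the
#' core-defensome pipeline. Defaults are the published analysis values:
#' RBH admissibility (identity >= 95%, coverage >= 80% on both sequences,
#' e-value <= 1e-4), core/quasi-core presence cut-offs (100% and >= 90%),
#' defense-island geometry (gap <= 10 intervening genes, >= 5 defense genes,
#' >= 3 distinct families), genome QC (completeness >= 90%, contamination
#' <= 5%), the 10-genome species floor, and the vOTU clustering thresholds
#' (ANI >= 95, target coverage >= 0.85).
#'
#' @param min_identity_pct minimum percent identity for an admissible hit.
#' @param min_coverage_frac minimum alignment coverage; applied to the
#'   smaller of query and subject coverage (`coverage_mode = "both"`) or to
#'   the query only.
#' @param max_evalue maximum e-value for an admissible hit.
#' @param core_frac presence fraction defining a core block (exactly 1).
#' @param quasi_core_min_frac minimum presence fraction of a quasi-core
#'   block (inclusive).
#' @param island_max_gap_genes maximum number of intervening non-defense
#'   genes between consecutive defense genes of one island.
#' @param island_min_genes minimum number of defense genes in an island.
#' @param island_min_families minimum number of distinct system families in
#'   an island.
#' @param min_genomes_per_species minimum genomes for a species (or contigs
#'   for a vOTU) to enter the conservation analysis.
#' @param qc_min_completeness,qc_max_contamination genome QC bounds
#'   (percent, inclusive).
#' @param votu_min_ani,votu_min_tcov,votu_min_qcov vOTU admission rule:
#'   ANI percent, target-coverage fraction, query-coverage fraction.
#' @param coverage_mode `"both"` (default, the strict reading) or
#'   `"query"`.
#' @param gap_mode `"intervening"` (default: gap counts non-defense genes
#'   between consecutive defense genes) or `"rank"` (gap is the rank
#'   difference).
#' @param linkage `"single"` (default) or `"complete"` for block building.
#' @param min_component_match_frac fraction of components of each system
#'   that must have an RBH partner in the other system for a system-level
#'   link; 1 (default) requires all components.
#' @param mge_overlap_mode `"both"` (default: remove both members of every
#'   overlapping MGE pair) or `"nested"` (remove only intervals fully
#'   contained in another).
#' @param mww_exact_max_n sample-size bound `n1 + n2` below which the
#'   Mann-Whitney test uses the exact permutation null.
#' @param rng_seed integer seed recorded in run reports.
#' @return An object of class `defensome_config` (a validated list).
#' @examples
#' cfg <- defensome_config()
#' cfg$min_identity_pct
#' @export
defensome_config <- function(min_identity_pct = 95,
                             min_coverage_frac = 0.80,
                             max_evalue = 1e-4,
                             core_frac = 1.0,
                             quasi_core_min_frac = 0.90,
                             island_max_gap_genes = 10,
                             island_min_genes = 5,
                             island_min_families = 3,
                             min_genomes_per_species = 10,
                             qc_min_completeness = 90,
                             qc_max_contamination = 5,
                             votu_min_ani = 95,
                             votu_min_tcov = 0.85,
                             votu_min_qcov = 0.0,
                             coverage_mode = c("both", "query"),
                             gap_mode = c("intervening", "rank"),
                             linkage = c("single", "complete"),
                             min_component_match_frac = 1.0,
                             mge_overlap_mode = c("both", "nested"),
                             mww_exact_max_n = 16,
                             rng_seed = 1L) {
  cfg <- list(
    min_identity_pct = min_identity_pct,
    min_coverage_frac = min_coverage_frac,
    max_evalue = max_evalue,
    core_frac = core_frac,
    quasi_core_min_frac = quasi_core_min_frac,
    island_max_gap_genes = as.integer(island_max_gap_genes),
    island_min_genes = as.integer(island_min_genes),
    island_min_families = as.integer(island_min_families),
    min_genomes_per_species = as.integer(min_genomes_per_species),
    qc_min_completeness = qc_min_completeness,
    qc_max_contamination = qc_max_contamination,
    votu_min_ani = votu_min_ani,
    votu_min_tcov = votu_min_tcov,
    votu_min_qcov = votu_min_qcov,
    coverage_mode = match.arg(coverage_mode),
    gap_mode = match.arg(gap_mode),
    linkage = match.arg(linkage),
    min_component_match_frac = min_component_match_frac,
    mge_overlap_mode = match.arg(mge_overlap_mode),
    mww_exact_max_n = as.integer(mww_exact_max_n),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "defensome_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_identity_pct >= 0, cfg$min_identity_pct <= 100,
    cfg$min_coverage_frac >= 0, cfg$min_coverage_frac <= 1,
    cfg$max_evalue >= 0,
    cfg$core_frac > 0, cfg$core_frac <= 1,
    cfg$quasi_core_min_frac > 0, cfg$quasi_core_min_frac <= cfg$core_frac,
    cfg$island_max_gap_genes >= 0,
    cfg$island_min_genes >= 1,
    cfg$island_min_families >= 1,
    cfg$min_genomes_per_species >= 1,
    cfg$qc_min_completeness >= 0, cfg$qc_min_completeness <= 100,
    cfg$qc_max_contamination >= 0, cfg$qc_max_contamination <= 100,
    cfg$votu_min_ani >= 0, cfg$votu_min_ani <= 100,
    cfg$votu_min_tcov >= 0, cfg$votu_min_tcov <= 1,
    cfg$votu_min_qcov >= 0, cfg$votu_min_qcov <= 1,
    cfg$min_component_match_frac > 0, cfg$min_component_match_frac <= 1
  )
  invisible(cfg)
}

#' @export
print.defensome_config <- function(x, ...) {
  cat("<defensome_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

MGE_CLASSES <- c("plasmid", "prophage", "ICE", "IME",
                 "integron_sedentary", "integron_mobile")

POLARITIES <- c("defense", "counter_defense")
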