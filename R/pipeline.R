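# End-to-end orchestration: io -> orthology -> persistence -> islands ->
# colocalization -> stats (-> vOTU/HCCDS when phage inputs are given).

#' Run the core-defensome analysis on an in-memory dataset
#'
#' Applies genome QC and the species floor, then per species builds the
#' all-vs-all hit table, RBH pairs, system-level links and conservation
#' blocks, calls HCADS, detects defense islands, resolves MGE overlaps,
#' assigns genomic contexts, computes densities and runs the standard
#' statistics (Spearman correlation of HCADS density with genome size;
#' per-family Fisher enrichment inside versus outside islands).
#' Conservation identities (block partition of instances, island
#' disjointness, context partition) are asserted, not merely reported.
#'
#' @param dataset `defensome_dataset`.
#' @param cfg [defensome_config()].
#' @param backend hit-table backend passed to [build_hit_table()].
#' @param external_hits named list (species id -> TSV path) for
#'   `external_tsv` mode.
#' @return list of class `defensome_results`: `species`, `blocks`,
#'   `hcads`, `islands`, `island_membership`, `contexts`, `densities`,
#'   `stats`, `mges_removed`, `report`.
#' @export
analyze_dataset <- function(dataset, cfg = defensome_config(),
                            backend = "builtin", external_hits = NULL) {
  t0 <- proc.time()[["elapsed"]]
  manifest <- filter_genomes_qc(dataset$manifest, cfg)
  species <- select_species(manifest, dataset$systems, cfg)
  kept <- species$species_id[species$kept & !species$excluded_from_hcads]

  genomes_kept <- manifest$genome_id[manifest$species_id %in% kept]
  sysd <- dataset$systems
  sysd <- sysd[sysd$complete & sysd$polarity == "defense" &
                 sysd$genome_id %in% genomes_kept, , drop = FALSE]

  all_blocks <- list()
  n_rbh <- 0L
  for (sp in kept) {
    hits <- build_hit_table(dataset, sp, backend = backend,
                            external_path = external_hits[[sp]])
    rbh <- compute_rbh(hits, cfg)
    n_rbh <- n_rbh + nrow(rbh)
    sp_genomes <- manifest$genome_id[manifest$species_id == sp]
    sp_sys <- sysd[sysd$genome_id %in% sp_genomes, , drop = FALSE]
    links <- link_systems(rbh, sp_sys, cfg)
    all_blocks[[sp]] <- build_blocks(links, sp_sys, sp_genomes,
                                     scope_id = sp, cfg = cfg)
  }
  blocks <- if (length(all_blocks)) do.call(rbind, all_blocks)
            else empty_blocks()
  rownames(blocks) <- NULL
  hcads <- call_hcads(blocks)

  # partition identity: every complete instance in exactly one block
  member_uids <- unlist(blocks$member_system_uids)
  stopifnot(!anyDuplicated(member_uids),
            length(member_uids) == nrow(sysd))

  genes_kept <- dataset$genes[dataset$genes$genome_id %in% genomes_kept, ,
                              drop = FALSE]
  islands <- detect_defense_islands(genes_kept, sysd, cfg)
  assert_island_disjointness(islands)
  memb <- island_membership(hcads$hcads, islands, sysd)

  mge_res <- resolve_mge_overlaps(
    dataset$mges[dataset$mges$genome_id %in% genomes_kept, , drop = FALSE],
    cfg)
  contexts <- assign_context(sysd, genes_kept, mge_res$kept)
  # context partition: one context per instance, nothing lost
  stopifnot(nrow(contexts) == nrow(sysd),
            sum(contexts$context == "chromosome") +
              sum(contexts$context %in% MGE_CLASSES) == nrow(sysd))

  hcads_uids <- unlist(hcads$hcads$member_system_uids)
  hcads_ctx <- contexts[contexts$system_uid %in% hcads_uids, , drop = FALSE]
  densities <- compute_densities(hcads_ctx, sysd, islands,
                                 manifest[manifest$species_id %in% kept, ,
                                          drop = FALSE],
                                 mge_res$kept)

  stats_rows <- run_output_stats(densities, manifest, sysd, memb, islands)

  report <- list(
    n_genomes_in = nrow(dataset$manifest),
    n_genomes_qc = nrow(manifest),
    n_species_kept = length(kept),
    n_species_flagged_no_systems = sum(species$excluded_from_hcads),
    n_systems = nrow(sysd),
    n_rbh_pairs = n_rbh,
    n_blocks = nrow(blocks),
    n_hcads = nrow(hcads$hcads),
    n_islands = nrow(islands),
    n_mges_removed_overlap = nrow(mge_res$removed),
    mge_removed_fraction = mge_res$removed_fraction,
    n_contexts = nrow(contexts),
    frac_hcads_instances_in_islands = memb$fraction_instances,
    frac_instances_hcads = hcads$summary$frac_instances_hcads,
    pct_core_of_hcads = hcads$summary$pct_core_of_hcads,
    seed = cfg$rng_seed,
    elapsed_sec = proc.time()[["elapsed"]] - t0
  )
  structure(list(species = species, blocks = blocks, hcads = hcads,
                 islands = islands, island_membership = memb,
                 contexts = contexts, densities = densities,
                 stats = stats_rows, mges_removed = mge_res$removed,
                 report = report),
            class = "defensome_results")
}

assert_island_disjointness <- function(islands) {
  key <- paste(islands$genome_id, islands$replicon_id)
  for (k in unique(key)) {
    sub <- islands[key == k, , drop = FALSE]
    genes <- unlist(sub$member_gene_ids)
    stopifnot(!anyDuplicated(genes))
  }
  invisible(TRUE)
}

run_output_stats <- function(densities, manifest, systems, memb, islands) {
  rows <- list()
  wg <- densities[densities$scope == "whole_genome", , drop = FALSE]
  sizes <- manifest$genome_size_bp[match(wg$genome_id,
                                         manifest$genome_id)] / 1e6
  ok <- length(wg$density_per_mb) >= 3 &&
    length(unique(wg$density_per_mb)) > 1 && length(unique(sizes)) > 1
  if (ok) {
    ct <- correlate_density_size(wg$density_per_mb, sizes)
    rows[[1]] <- data.frame(comparison = "hcads_density_vs_genome_size",
                            method = ct$method, statistic = ct$statistic,
                            p_value = ct$p_value, adjusted_p = NA_real_,
                            stringsAsFactors = FALSE)
  }
  # family enrichment inside vs outside islands over all defense genes
  if (nrow(islands) > 0 && nrow(systems) > 0) {
    flags <- memb$instance_flags
    fam <- systems$family[match(names(flags), systems$system_uid)]
    tab_in <- table(fam[flags])
    tab_out <- table(fam[!flags])
    enr <- enrichment_test(tab_in, tab_out)
    if (nrow(enr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0("island_enrichment_", enr$family),
        method = enr$method, statistic = enr$odds_ratio,
        p_value = enr$p_value, adjusted_p = enr$adjusted_p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(comparison = character(0), method = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.defensome_results <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<defensome_results> %d/%d genomes past QC, ",
                     "%d species analyzed\n  %d systems -> %d blocks ",
                     "(%d HCADS), %d islands, %d MGEs removed as ",
                     "overlapping\n"),
              r$n_genomes_qc, r$n_genomes_in, r$n_species_kept,
              r$n_systems, r$n_blocks, r$n_hcads, r$n_islands,
              r$n_mges_removed_overlap))
  invisible(x)
}

#' Run the full pipeline on an input directory
#'
#' Expects the package's documented dialects under `input_dir`:
#' `manifest.tsv`, `genes/<genome_id>.gff3`, `systems.tsv`, `mges.tsv`
#' (optional), `proteins.faa`. Writes `hcads_blocks.tsv`, `islands.tsv`,
#' `context.tsv`, `densities.tsv`, `stats.tsv`, `mges_removed.tsv` and
#' `run_report.json` under `output_dir`. Reruns with identical inputs,
#' config and seed reproduce identical tables.
#'
#' @param input_dir input directory.
#' @param output_dir output directory (created).
#' @param cfg [defensome_config()].
#' @param backend hit backend (`"builtin"`, `"identity"`,
#'   `"external_tsv"`).
#' @param external_hits named list species -> hit TSV for external mode.
#' @return `defensome_results`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         cfg = defensome_config(), backend = "builtin",
                         external_hits = NULL) {
  manifest_path <- file.path(input_dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop("missing manifest: ", manifest_path, call. = FALSE)
  }
  mge_path <- file.path(input_dir, "mges.tsv")
  ds <- read_dataset(manifest_path, file.path(input_dir, "genes"),
                     file.path(input_dir, "systems.tsv"),
                     if (file.exists(mge_path)) mge_path else NULL,
                     file.path(input_dir, "proteins.faa"))
  res <- analyze_dataset(ds, cfg, backend, external_hits)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_blocks(res$blocks, file.path(output_dir, "hcads_blocks.tsv"))
  write_islands(res$islands, file.path(output_dir, "islands.tsv"))
  write_contexts(res$contexts, file.path(output_dir, "context.tsv"))
  write_densities(res$densities, file.path(output_dir, "densities.tsv"))
  write_tsv(res$stats, file.path(output_dir, "stats.tsv"))
  write_mges(res$mges_removed, file.path(output_dir, "mges_removed.tsv"))
  jsonlite::write_json(res$report,
                       file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Cluster phage contigs and call HCCDS
#'
#' The vOTU arm: clusters contigs by the greedy centroid rule, then for
#' every vOTU with at least 10 members runs the same orthology and
#' conservation logic as the HCADS arm on the vOTU's counter-defense
#' systems.
#'
#' @param dataset `defensome_dataset` whose genomes are phage contigs and
#'   whose systems have counter-defense polarity.
#' @param contig_lengths named vector of contig lengths (bp).
#' @param ani sparse ANI table (see [cluster_votus()]).
#' @param cfg [defensome_config()].
#' @param backend hit backend for the orthology step.
#' @return list with `votus`, `blocks`, `hccds`, `skipped`.
#' @export
analyze_phage <- function(dataset, contig_lengths, ani,
                          cfg = defensome_config(), backend = "builtin") {
  votus <- cluster_votus(contig_lengths, ani, cfg)
  links_by_votu <- list()
  ds2 <- dataset
  for (i in seq_len(nrow(votus))) {
    members <- votus$member_contigs[[i]]
    if (length(members) < cfg$min_genomes_per_species) next
    # treat the vOTU as the species scope for the orthology step
    ds2$manifest <- dataset$manifest
    ds2$manifest$species_id <- ifelse(
      dataset$manifest$genome_id %in% members, votus$votu_id[i],
      paste0("not_", votus$votu_id[i]))
    hits <- build_hit_table(ds2, votus$votu_id[i], backend = backend,
                            polarity = "counter_defense")
    rbh <- compute_rbh(hits, cfg)
    vsys <- dataset$systems[dataset$systems$genome_id %in% members &
                              dataset$systems$polarity ==
                                "counter_defense", , drop = FALSE]
    links_by_votu[[votus$votu_id[i]]] <- link_systems(rbh, vsys, cfg)
  }
  res <- call_hccds(votus, dataset$systems, links_by_votu, cfg)
  c(list(votus = votus), res)
}
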