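# Conserved system blocks: connected components of the ortholog-link graph,
# classified core / quasi-core / accessory by presence across the genomes of
# a species (or the member contigs of a vOTU).

#' Build conservation blocks from system-level ortholog links
#'
#' Blocks are connected components (single linkage by default) of the
#' ortholog-link graph over the complete system instances of one species;
#' every instance belongs to exactly one block, singletons included.
#' Presence is counted over ALL genomes supplied in `genomes` — including
#' genomes without any defense system — so the presence fraction denominator
#' is the species' full QC-passing genome count. Classification: core iff
#' presence fraction == 1, quasi-core iff 0.90 <= fraction < 1, accessory
#' otherwise. With `linkage = "complete"` a component is kept as one block
#' only if its instances form a clique; otherwise it is split into
#' single-instance blocks (sensitivity mode).
#'
#' @param links ortholog links from [link_systems()].
#' @param systems complete system instances of the species.
#' @param genomes character vector of ALL genome ids of the species.
#' @param scope_id species (or vOTU) identifier stamped on the blocks.
#' @param cfg [defensome_config()].
#' @return data.frame of blocks: `block_id`, `species_id`, `family`,
#'   `classification`, `presence_count`, `genome_count`, `presence_frac`,
#'   plus a list column `member_system_uids`.
#' @export
build_blocks <- function(links, systems, genomes, scope_id = "species",
                         cfg = defensome_config()) {
  systems <- systems[systems$complete, , drop = FALSE]
  n <- nrow(systems)
  if (n == 0) return(empty_blocks())
  uid <- systems$system_uid
  from <- match(links$system_uid_a, uid)
  to <- match(links$system_uid_b, uid)
  keep <- !is.na(from) & !is.na(to)
  membership <- connected_components(n, from[keep], to[keep])

  if (cfg$linkage == "complete") {
    membership <- enforce_complete_linkage(membership, uid, links)
  }

  comp_ids <- sort(unique(membership))
  rows <- lapply(comp_ids, function(cid) {
    idx <- which(membership == cid)
    fam <- unique(systems$family[idx])
    # links require equal family, so chimeric blocks are impossible
    stopifnot(length(fam) == 1)
    members <- sort(uid[idx])
    pres <- length(unique(systems$genome_id[idx]))
    data.frame(species_id = scope_id, family = fam,
               presence_count = pres, genome_count = length(genomes),
               representative = members[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$member_system_uids <- lapply(comp_ids, function(cid) {
    sort(uid[membership == cid])
  })
  # deterministic block ids: order by family then representative member
  ord <- order(out$family, out$representative, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$block_id <- sprintf("%s_block_%04d", scope_id, seq_len(nrow(out)))
  out$presence_frac <- out$presence_count / out$genome_count
  out$classification <- classify_presence(out$presence_frac, cfg)
  out$representative <- NULL
  rownames(out) <- NULL
  out[, c("block_id", "species_id", "family", "classification",
          "presence_count", "genome_count", "presence_frac",
          "member_system_uids")]
}

classify_presence <- function(frac, cfg = defensome_config()) {
  ifelse(frac >= cfg$core_frac, "core",
         ifelse(frac >= cfg$quasi_core_min_frac, "quasi_core", "accessory"))
}

enforce_complete_linkage <- function(membership, uid, links) {
  key <- paste(pmin(links$system_uid_a, links$system_uid_b),
               pmax(links$system_uid_a, links$system_uid_b))
  out <- membership
  next_id <- max(membership) + 1L
  for (cid in unique(membership)) {
    idx <- which(membership == cid)
    if (length(idx) < 3) next
    members <- uid[idx]
    pairs <- utils::combn(sort(members), 2)
    have <- paste(pairs[1, ], pairs[2, ]) %in% key
    if (!all(have)) {
      # not a clique: fall back to singletons for this component
      out[idx] <- seq(next_id, length.out = length(idx))
      next_id <- next_id + length(idx)
    }
  }
  match(out, unique(out))
}

empty_blocks <- function() {
  out <- data.frame(block_id = character(0), species_id = character(0),
                    family = character(0), classification = character(0),
                    presence_count = integer(0), genome_count = integer(0),
                    presence_frac = numeric(0), stringsAsFactors = FALSE)
  out$member_system_uids <- list()
  out
}

#' Block-by-genome presence matrix
#' @param blocks blocks from [build_blocks()].
#' @param systems systems table.
#' @param genomes genome ids (columns).
#' @return logical matrix, rows = blocks, columns = genomes.
#' @export
presence_matrix <- function(blocks, systems, genomes) {
  m <- matrix(FALSE, nrow = nrow(blocks), ncol = length(genomes),
              dimnames = list(blocks$block_id, genomes))
  for (i in seq_len(nrow(blocks))) {
    g <- systems$genome_id[match(blocks$member_system_uids[[i]],
                                 systems$system_uid)]
    m[i, unique(g)] <- TRUE
  }
  m
}

#' Call highly conserved systems (HCADS) from classified blocks
#'
#' HCADS are the core plus quasi-core blocks. The summary reports block
#' counts by classification, per-family counts, the fraction of all
#' complete system instances that belong to an HCADS block, and the
#' core / quasi-core split among HCADS.
#'
#' @param blocks blocks from [build_blocks()].
#' @return list with `hcads` (subset of blocks) and `summary`.
#' @export
call_hcads <- function(blocks) {
  hc <- blocks[blocks$classification != "accessory", , drop = FALSE]
  n_instances <- sum(lengths(blocks$member_system_uids))
  n_hc_instances <- sum(lengths(hc$member_system_uids))
  fam_counts <- if (nrow(hc)) table(hc$family) else table(character(0))
  summary <- list(
    n_blocks = nrow(blocks),
    n_hcads = nrow(hc),
    n_core = sum(blocks$classification == "core"),
    n_quasi = sum(blocks$classification == "quasi_core"),
    n_accessory = sum(blocks$classification == "accessory"),
    n_instances = n_instances,
    n_hcads_instances = n_hc_instances,
    frac_instances_hcads = if (n_instances) n_hc_instances / n_instances
                           else 0,
    pct_core_of_hcads = if (nrow(hc))
      100 * sum(hc$classification == "core") / nrow(hc) else 0,
    pct_quasi_of_hcads = if (nrow(hc))
      100 * sum(hc$classification == "quasi_core") / nrow(hc) else 0,
    family_counts = as.list(fam_counts)
  )
  list(hcads = hc, summary = summary)
}

#' Call highly conserved counter-defense systems (HCCDS) per vOTU
#'
#' Runs the same block-building and conservation logic as the HCADS arm
#' with genomes replaced by the member contigs of each vOTU and systems
#' restricted to counter-defense polarity. vOTUs below the 10-member floor
#' are skipped (recorded in the returned `skipped` vector).
#'
#' @param votus vOTU table from [cluster_votus()] (list column
#'   `member_contigs`).
#' @param systems systems table whose `genome_id` is the contig id.
#' @param links_by_votu named list of ortholog-link tables per vOTU id (as
#'   produced by running [build_hit_table()]/[compute_rbh()]/
#'   [link_systems()] on each vOTU's contigs), or `NULL` when every member
#'   carries at most one system per family and links are computed here from
#'   `rbh_by_votu`.
#' @param cfg [defensome_config()].
#' @return list with `blocks` (all classifications, one table), `hccds`
#'   (core + quasi-core subset) and `skipped` (vOTU ids below the floor).
#' @export
call_hccds <- function(votus, systems, links_by_votu = NULL,
                       cfg = defensome_config()) {
  cd <- systems[systems$complete &
                  systems$polarity == "counter_defense", , drop = FALSE]
  all_blocks <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(votus))) {
    vid <- votus$votu_id[i]
    members <- votus$member_contigs[[i]]
    if (length(members) < cfg$min_genomes_per_species) {
      skipped <- c(skipped, vid)
      next
    }
    vsys <- cd[cd$genome_id %in% members, , drop = FALSE]
    if (nrow(vsys) == 0) next
    links <- if (!is.null(links_by_votu)) {
      links_by_votu[[vid]] %||% empty_links()
    } else {
      empty_links()
    }
    all_blocks[[vid]] <- build_blocks(links, vsys, members, scope_id = vid,
                                      cfg = cfg)
  }
  blocks <- if (length(all_blocks)) do.call(rbind, all_blocks)
            else empty_blocks()
  rownames(blocks) <- NULL
  list(blocks = blocks,
       hccds = blocks[blocks$classification != "accessory", , drop = FALSE],
       skipped = skipped)
}

empty_links <- function() {
  data.frame(system_uid_a = character(0), system_uid_b = character(0),
             family = character(0), matched_component_count = integer(0),
             total_component_count_a = integer(0),
             total_component_count_b = integer(0), stringsAsFactors = FALSE)
}

#' Write the blocks table
#' @param blocks blocks data.frame.
#' @param path output path.
#' @export
write_blocks <- function(blocks, path) {
  write_tsv(data.frame(
    block_id = blocks$block_id,
    species_id = blocks$species_id,
    family = blocks$family,
    classification = blocks$classification,
    presence_count = blocks$presence_count,
    genome_count = blocks$genome_count,
    presence_frac = blocks$presence_frac,
    member_system_uids = vapply(blocks$member_system_uids, paste,
                                character(1), collapse = ","),
    stringsAsFactors = FALSE
  ), path)
}
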