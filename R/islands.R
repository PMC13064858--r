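# Defense islands: gene-rank clusters of defense-system genes separated by
# no more than 10 intervening genes, containing at least 5 defense genes
# from at least 3 distinct families.

#' Detect defense islands on every replicon
#'
#' Defense genes are the component genes of complete systems of defense
#' polarity. Clusters are grown greedily left-to-right along gene rank:
#' the current cluster is extended while the number of intervening
#' non-defense genes between consecutive defense genes (rank difference
#' minus one) is at most `island_max_gap_genes`; with
#' `gap_mode = "rank"` the rank difference itself is bounded instead. A
#' closed maximal cluster is an island iff it holds at least
#' `island_min_genes` defense genes from at least `island_min_families`
#' distinct families. On circular replicons the wrap-around gap between the
#' last and first defense gene is evaluated and the two terminal clusters
#' are merged when it is within the bound.
#'
#' @param genes gene records (ranks valid per replicon).
#' @param systems systems table.
#' @param cfg [defensome_config()].
#' @return data.frame of islands: `island_id`, `genome_id`, `replicon_id`,
#'   `start_rank`, `end_rank`, `start_bp`, `end_bp`, `n_defense_genes`,
#'   `n_families`, plus list columns `member_gene_ids` and
#'   `member_system_uids`. For a wrapped island `start_rank > end_rank`;
#'   bp bounds are those of its member genes.
#' @export
detect_defense_islands <- function(genes, systems,
                                   cfg = defensome_config()) {
  systems <- systems[systems$complete &
                       systems$polarity == "defense", , drop = FALSE]
  out <- list()
  if (nrow(systems) == 0) return(empty_islands())

  comp_gene <- unlist(systems$component_gene_ids)
  comp_fam <- rep(systems$family, lengths(systems$component_gene_ids))
  comp_sys <- rep(systems$system_uid, lengths(systems$component_gene_ids))
  comp_genome <- rep(systems$genome_id, lengths(systems$component_gene_ids))
  comp_key <- paste(comp_genome, comp_gene)

  gene_key <- paste(genes$genome_id, genes$gene_id)
  is_def <- gene_key %in% comp_key

  def <- genes[is_def, , drop = FALSE]
  rep_key <- paste(def$genome_id, def$replicon_id, sep = "\r")
  for (rk in unique(rep_key)) {
    sub <- def[rep_key == rk, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    n_rep <- sum(genes$genome_id == sub$genome_id[1] &
                   genes$replicon_id == sub$replicon_id[1])
    clusters <- chain_ranks(sub$rank, n_rep,
                            circular = sub$is_circular_replicon[1],
                            max_gap = cfg$island_max_gap_genes,
                            gap_mode = cfg$gap_mode)
    for (cl in clusters) {
      idx <- match(cl, sub$rank)
      g <- sub[idx, , drop = FALSE]
      gk <- paste(g$genome_id, g$gene_id)
      fams <- unique(comp_fam[comp_key %in% gk])
      if (nrow(g) >= cfg$island_min_genes &&
          length(fams) >= cfg$island_min_families) {
        out[[length(out) + 1L]] <- data.frame(
          genome_id = g$genome_id[1], replicon_id = g$replicon_id[1],
          start_rank = cl[1], end_rank = cl[length(cl)],
          start_bp = min(g$start), end_bp = max(g$end),
          n_defense_genes = nrow(g), n_families = length(fams),
          stringsAsFactors = FALSE
        )
        out[[length(out)]]$member_gene_ids <- list(g$gene_id)
        out[[length(out)]]$member_system_uids <-
          list(sort(unique(comp_sys[comp_key %in% gk])))
      }
    }
  }
  if (!length(out)) return(empty_islands())
  res <- do.call(rbind, out)
  ord <- order(res$genome_id, res$replicon_id, res$start_rank,
               method = "radix")
  res <- res[ord, , drop = FALSE]
  res$island_id <- sprintf("island_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("island_id", "genome_id", "replicon_id", "start_rank",
          "end_rank", "start_bp", "end_bp", "n_defense_genes",
          "n_families", "member_gene_ids", "member_system_uids")]
}

# Greedy maximal chaining of sorted defense-gene ranks under the gap bound.
# Returns a list of integer vectors of ranks (in island order; a wrapped
# circular cluster keeps its rotated order).
chain_ranks <- function(ranks, n_genes, circular, max_gap,
                        gap_mode = "intervening") {
  if (!length(ranks)) return(list())
  gap_of <- function(delta) {
    if (gap_mode == "intervening") delta - 1L else delta
  }
  clusters <- list(ranks[1])
  for (r in ranks[-1]) {
    last <- clusters[[length(clusters)]]
    if (gap_of(r - last[length(last)]) <= max_gap) {
      clusters[[length(clusters)]] <- c(last, r)
    } else {
      clusters[[length(clusters) + 1L]] <- r
    }
  }
  if (circular && length(ranks) >= 2) {
    first <- clusters[[1]]
    last <- clusters[[length(clusters)]]
    wrap_delta <- (ranks[1] + n_genes) - ranks[length(ranks)]
    if (length(clusters) > 1 && gap_of(wrap_delta) <= max_gap) {
      clusters[[1]] <- c(last, first)
      clusters[[length(clusters)]] <- NULL
    }
  }
  clusters
}

empty_islands <- function() {
  out <- data.frame(island_id = character(0), genome_id = character(0),
                    replicon_id = character(0), start_rank = integer(0),
                    end_rank = integer(0), start_bp = integer(0),
                    end_bp = integer(0), n_defense_genes = integer(0),
                    n_families = integer(0), stringsAsFactors = FALSE)
  out$member_gene_ids <- list()
  out$member_system_uids <- list()
  out
}

#' Flag island colocalization of conserved blocks
#'
#' A block is island-colocalized iff at least one of its member system
#' instances has at least one component gene inside an island. The reported
#' fraction is over system INSTANCES of the supplied blocks (an instance is
#' colocalized iff >= 1 of its component genes lies in an island), matching
#' how island residence of highly conserved systems is quantified.
#'
#' @param hcads blocks (typically the HCADS subset).
#' @param islands islands from [detect_defense_islands()].
#' @param systems systems table.
#' @return list with `blocks` (the input plus `in_island` flag),
#'   `instance_flags` (per member instance) and `fraction_instances`.
#' @export
island_membership <- function(hcads, islands, systems) {
  island_genes <- unique(unlist(mapply(
    function(g, ids) paste(g, ids),
    islands$genome_id, islands$member_gene_ids, SIMPLIFY = FALSE)))
  inst_in_island <- function(uid) {
    i <- match(uid, systems$system_uid)
    any(paste(systems$genome_id[i], systems$component_gene_ids[[i]]) %in%
          island_genes)
  }
  all_members <- unlist(hcads$member_system_uids)
  flags <- vapply(all_members, inst_in_island, logical(1))
  block_flag <- vapply(hcads$member_system_uids,
                       function(m) any(vapply(m, inst_in_island,
                                              logical(1))),
                       logical(1))
  blocks <- hcads
  blocks$in_island <- block_flag
  list(blocks = blocks,
       instance_flags = stats::setNames(flags, all_members),
       fraction_instances = if (length(flags)) mean(flags) else 0)
}

#' Write the islands table
#' @param islands islands data.frame.
#' @param path output path.
#' @export
write_islands <- function(islands, path) {
  write_tsv(data.frame(
    island_id = islands$island_id,
    genome_id = islands$genome_id,
    replicon_id = islands$replicon_id,
    start_rank = islands$start_rank,
    end_rank = islands$end_rank,
    start_bp = islands$start_bp,
    end_bp = islands$end_bp,
    n_defense_genes = islands$n_defense_genes,
    n_families = islands$n_families,
    member_system_uids = vapply(islands$member_system_uids, paste,
                                character(1), collapse = ","),
    stringsAsFactors = FALSE
  ), path)
}
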