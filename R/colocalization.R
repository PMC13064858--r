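# Genomic context of defense systems: MGE overlap exclusion, chromosome /
# MGE-class assignment, per-megabase densities.

#' Exclude overlapping MGE annotations
#'
#' Any two MGEs on the same replicon whose base-pair intervals intersect
#' are BOTH removed (e.g. an integron carried by a plasmid removes the pair);
#' with `mge_overlap_mode = "nested"` only intervals fully contained in
#' another are removed. Order-independent and idempotent.
#'
#' @param mges MGE annotation data.frame.
#' @param cfg [defensome_config()].
#' @return list with `kept`, `removed` (data.frames) and `removed_fraction`.
#' @export
resolve_mge_overlaps <- function(mges, cfg = defensome_config()) {
  if (nrow(mges) == 0) {
    return(list(kept = mges, removed = mges, removed_fraction = 0))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = paste(mges$genome_id, mges$replicon_id, sep = "\r"),
    ranges = IRanges::IRanges(start = mges$start, end = mges$end))
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  drop <- rep(FALSE, nrow(mges))
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    if (cfg$mge_overlap_mode == "both") {
      drop[unique(c(q, s))] <- TRUE
    } else {
      contained <- function(i, j) {
        mges$start[i] >= mges$start[j] & mges$end[i] <= mges$end[j]
      }
      drop[q[contained(q, s)]] <- TRUE
      drop[s[contained(s, q)]] <- TRUE
    }
  }
  kept <- mges[!drop, , drop = FALSE]
  removed <- mges[drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed,
       removed_fraction = mean(drop))
}

#' Assign a genomic context to each system instance
#'
#' A system is assigned to an MGE class iff ALL its component genes fall
#' entirely within one MGE's interval (after overlap exclusion); otherwise
#' its context is `chromosome`. Systems with a partial MGE overlap (some
#' but not all components inside an MGE) default to chromosome and are
#' flagged in the `partial_overlap` column.
#'
#' @param systems systems table (complete instances).
#' @param genes gene records (for component coordinates).
#' @param mges_filtered overlap-resolved MGEs ([resolve_mge_overlaps()]
#'   `$kept`).
#' @return data.frame: `system_uid`, `context`, `mge_uid` (NA for
#'   chromosome), `partial_overlap`.
#' @export
assign_context <- function(systems, genes, mges_filtered) {
  systems <- systems[systems$complete, , drop = FALSE]
  n <- nrow(systems)
  out <- data.frame(system_uid = systems$system_uid,
                    context = rep("chromosome", n),
                    mge_uid = NA_character_,
                    partial_overlap = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0 || nrow(mges_filtered) == 0) return(out)
  gene_key <- paste(genes$genome_id, genes$gene_id)
  for (i in seq_len(n)) {
    comp <- systems$component_gene_ids[[i]]
    gi <- match(paste(systems$genome_id[i], comp), gene_key)
    g <- genes[gi, , drop = FALSE]
    m <- mges_filtered[mges_filtered$genome_id == systems$genome_id[i], ,
                       drop = FALSE]
    if (nrow(m) == 0) next
    inside <- vapply(seq_len(nrow(m)), function(j) {
      sum(g$replicon_id == m$replicon_id[j] &
            g$start >= m$start[j] & g$end <= m$end[j])
    }, integer(1))
    full <- which(inside == nrow(g))
    if (length(full)) {
      j <- full[1]  # post-exclusion MGEs are disjoint, so at most one
      out$context[i] <- m$mge_class[j]
      out$mge_uid[i] <- m$mge_uid[j]
    } else if (any(inside > 0)) {
      out$partial_overlap[i] <- TRUE
    }
  }
  out
}

#' Per-genome densities of conserved systems and islands
#'
#' Whole-genome density is HCADS instances per Mb of genome; island density
#' is islands per Mb of genome; per-integron-class density is HCADS
#' instances assigned to that class per Mb of summed class span in the
#' genome. Zero counts are emitted as density 0 (null values included);
#' scopes with zero span are emitted with `NA` density.
#'
#' @param hcads_contexts context assignments restricted to the instances of
#'   HCADS blocks (data.frame from [assign_context()] subset).
#' @param systems systems table (for genome of each instance).
#' @param islands islands table.
#' @param manifest manifest (genome sizes).
#' @param mges_filtered overlap-resolved MGEs, used for integron spans.
#' @return data.frame: `genome_id`, `scope`, `count`, `span_mb`,
#'   `density_per_mb`.
#' @export
compute_densities <- function(hcads_contexts, systems, islands, manifest,
                              mges_filtered = empty_mges()) {
  genome_of <- function(uids) {
    systems$genome_id[match(uids, systems$system_uid)]
  }
  rows <- list()
  for (gi in seq_len(nrow(manifest))) {
    g <- manifest$genome_id[gi]
    size_mb <- manifest$genome_size_bp[gi] / 1e6
    n_hc <- sum(genome_of(hcads_contexts$system_uid) == g)
    n_isl <- sum(islands$genome_id == g)
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g, scope = c("whole_genome", "islands"),
      count = c(n_hc, n_isl), span_mb = size_mb,
      density_per_mb = c(n_hc, n_isl) / size_mb,
      stringsAsFactors = FALSE)
    for (cls in c("integron_sedentary", "integron_mobile")) {
      m <- mges_filtered[mges_filtered$genome_id == g &
                           mges_filtered$mge_class == cls, , drop = FALSE]
      span <- sum(m$end - m$start + 1) / 1e6
      cnt <- sum(hcads_contexts$context == cls &
                   genome_of(hcads_contexts$system_uid) == g)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, scope = cls, count = cnt, span_mb = span,
        density_per_mb = if (span > 0) cnt / span else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write context assignments
#' @param contexts data.frame from [assign_context()].
#' @param path output path.
#' @export
write_contexts <- function(contexts, path) write_tsv(contexts, path)

#' Write the densities table
#' @param densities data.frame from [compute_densities()].
#' @param path output path.
#' @export
write_densities <- function(densities, path) write_tsv(densities, path)
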