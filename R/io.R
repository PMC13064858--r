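#' Read a genome manifest
#'
#' The manifest is a TSV with columns `species_id`, `genome_id`,
#' `genome_size_bp`, `completeness`, `contamination`. QC fields are CheckM-style
#' percentages.
#'
#' @param path path to the manifest TSV.
#' @return data.frame with columns `species_id`, `genome_id`,
#'   `genome_size_bp`, `completeness_pct`, `contamination_pct`.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_strict(path, c("species_id", "genome_id", "genome_size_bp",
                                "completeness", "contamination"), "manifest")
  out <- data.frame(
    species_id = df$species_id,
    genome_id = df$genome_id,
    genome_size_bp = as.integer(df$genome_size_bp),
    completeness_pct = as.numeric(df$completeness),
    contamination_pct = as.numeric(df$contamination),
    stringsAsFactors = FALSE
  )
  validate_manifest(out)
  out
}

validate_manifest <- function(m) {
  if (anyNA(m$genome_size_bp) || any(m$genome_size_bp <= 0)) {
    stop("manifest: genome_size_bp must be a positive integer", call. = FALSE)
  }
  if (any(m$completeness_pct < 0 | m$completeness_pct > 100)) {
    stop("manifest: completeness out of [0,100]", call. = FALSE)
  }
  dup <- duplicated(m$genome_id)
  if (any(dup)) {
    stop(sprintf("manifest: duplicate genome_id: %s",
                 paste(unique(m$genome_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(m)
}

#' Write a genome manifest TSV
#' @param manifest data.frame as returned by [read_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(data.frame(
    species_id = manifest$species_id,
    genome_id = manifest$genome_id,
    genome_size_bp = manifest$genome_size_bp,
    completeness = manifest$completeness_pct,
    contamination = manifest$contamination_pct
  ), path)
}

#' Read one genome's gene table from GFF3
#'
#' CDS features carry the gene identity in their `ID` attribute. Replicon
#' circularity follows the NCBI convention: a `region` feature with attribute
#' `Is_circular=true`. Gene ranks (0-based annotation order per replicon) are
#' recomputed from coordinates: sort by start, ties broken by end then
#' gene_id.
#'
#' @param path GFF3 file for one genome.
#' @param genome_id genome identifier to stamp on the records.
#' @return data.frame of gene records (`genome_id`, `replicon_id`, `gene_id`,
#'   `rank`, `start`, `end`, `strand`, `is_circular_replicon`).
#' @export
read_gene_gff3 <- function(path, genome_id) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  circular <- character(0)
  if ("Is_circular" %in% names(md)) {
    is_region <- as.character(md$type) == "region"
    circ_flag <- as_bool(md$Is_circular)
    circular <- unique(as.character(GenomicRanges::seqnames(gr))[is_region & circ_flag])
  }
  keep <- as.character(md$type) == "CDS"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  if (anyNA(ids) || any(ids == "")) {
    stop("GFF3 CDS feature without ID attribute in ", path, call. = FALSE)
  }
  genes <- data.frame(
    genome_id = genome_id,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = ids,
    rank = NA_integer_,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genes$is_circular_replicon <- genes$replicon_id %in% circular
  genes <- compute_gene_ranks(genes)
  validate_genes(genes)
  genes
}

#' Recompute 0-based gene ranks per replicon
#'
#' Rank is annotation order: genes sorted by start, ties broken by end then
#' gene_id, numbered 0..n-1 within each replicon.
#'
#' @param genes gene record data.frame.
#' @return the same data.frame with `rank` filled and rows sorted by
#'   replicon then rank.
#' @export
compute_gene_ranks <- function(genes) {
  ord <- order(genes$genome_id, genes$replicon_id, genes$start, genes$end,
               genes$gene_id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  genes$rank <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

validate_genes <- function(genes) {
  if (any(genes$start > genes$end)) {
    stop("gene records with start > end", call. = FALSE)
  }
  key <- paste(genes$genome_id, genes$gene_id)
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("duplicate gene_id within genome: %s",
                 paste(unique(genes$gene_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(genes)
}

#' Write one genome's gene table as GFF3
#' @param genes gene records of a single genome.
#' @param path output path.
#' @export
write_gene_gff3 <- function(genes, path) {
  stopifnot(length(unique(genes$genome_id)) == 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  reps <- unique(genes$replicon_id)
  for (rep in reps) {
    sub <- genes[genes$replicon_id == rep, , drop = FALSE]
    circ <- if (sub$is_circular_replicon[1]) "true" else "false"
    writeLines(sprintf("%s\tcoredefensome\tregion\t1\t%d\t.\t+\t.\tID=%s;Is_circular=%s",
                       rep, max(sub$end) + 1L, rep, circ), con)
    writeLines(sprintf("%s\tcoredefensome\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       rep, sub$start, sub$end, sub$strand, sub$gene_id), con)
  }
  invisible(path)
}

#' Read a defense/counter-defense systems table
#'
#' A documented dialect of DefenseFinder's systems output: TSV with columns
#' `system_uid`, `genome_id`, `replicon_id`, `family`, `polarity`,
#' `complete`, `component_gene_ids` (comma-joined).
#'
#' @param path systems TSV.
#' @return data.frame with a list column `component_gene_ids`.
#' @export
read_systems <- function(path) {
  df <- read_tsv_strict(path, c("system_uid", "genome_id", "replicon_id",
                                "family", "polarity", "complete",
                                "component_gene_ids"), "systems")
  out <- data.frame(
    system_uid = df$system_uid,
    genome_id = df$genome_id,
    replicon_id = df$replicon_id,
    family = df$family,
    polarity = df$polarity,
    complete = as_bool(df$complete),
    stringsAsFactors = FALSE
  )
  out$component_gene_ids <- lapply(strsplit(df$component_gene_ids, ","),
                                   trimws)
  validate_systems(out)
  out
}

validate_systems <- function(systems) {
  if (nrow(systems) == 0) return(invisible(systems))
  if (any(systems$family == "")) stop("system with empty family", call. = FALSE)
  bad <- !systems$polarity %in% POLARITIES
  if (any(bad)) {
    stop(sprintf("unknown polarity: %s",
                 paste(unique(systems$polarity[bad]), collapse = ", ")),
         call. = FALSE)
  }
  n_comp <- lengths(systems$component_gene_ids)
  if (any(n_comp == 0)) {
    stop("system with no component genes: ",
         paste(systems$system_uid[n_comp == 0], collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(systems$system_uid)
  if (any(dup)) {
    stop("duplicate system_uid: ",
         paste(unique(systems$system_uid[dup]), collapse = ", "),
         call. = FALSE)
  }
  invisible(systems)
}

#' Write a systems table TSV
#' @param systems systems data.frame (list column `component_gene_ids`).
#' @param path output path.
#' @export
write_systems <- function(systems, path) {
  write_tsv(data.frame(
    system_uid = systems$system_uid,
    genome_id = systems$genome_id,
    replicon_id = systems$replicon_id,
    family = systems$family,
    polarity = systems$polarity,
    complete = ifelse(systems$complete, "true", "false"),
    component_gene_ids = vapply(systems$component_gene_ids,
                                paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  ), path)
}

#' Read MGE interval annotations
#'
#' BED-like TSV with 1-based inclusive coordinates: columns `mge_uid`,
#' `genome_id`, `replicon_id`, `start`, `end`, `mge_class`. Classes outside
#' the closed set (plasmid, prophage, ICE, IME, integron_sedentary,
#' integron_mobile) are rejected rather than coerced.
#'
#' @param path MGE TSV.
#' @return data.frame of MGE annotations.
#' @export
read_mges <- function(path) {
  df <- read_tsv_strict(path, c("mge_uid", "genome_id", "replicon_id",
                                "start", "end", "mge_class"), "MGE")
  out <- data.frame(
    mge_uid = df$mge_uid,
    genome_id = df$genome_id,
    replicon_id = df$replicon_id,
    start = as.integer(df$start),
    end = as.integer(df$end),
    mge_class = df$mge_class,
    stringsAsFactors = FALSE
  )
  validate_mges(out)
  out
}

validate_mges <- function(mges) {
  if (nrow(mges) == 0) return(invisible(mges))
  if (any(mges$start > mges$end)) stop("MGE with start > end", call. = FALSE)
  bad <- !mges$mge_class %in% MGE_CLASSES
  if (any(bad)) {
    stop(sprintf("unknown mge_class: %s",
                 paste(unique(mges$mge_class[bad]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(mges)
}

#' Write an MGE table TSV
#' @param mges MGE data.frame.
#' @param path output path.
#' @export
write_mges <- function(mges, path) {
  write_tsv(mges[, c("mge_uid", "genome_id", "replicon_id",
                     "start", "end", "mge_class")], path)
}

#' Read the full input dataset and cross-validate references
#'
#' Loads the manifest, all per-genome GFF3 gene tables, the systems table,
#' the MGE table and the protein FASTA, then checks referential integrity:
#' every component gene of every system must resolve to a gene record and a
#' protein sequence, and every genome referenced by systems or MGEs must be
#' in the manifest.
#'
#' @param manifest_path manifest TSV.
#' @param gene_table_dir directory with one `<genome_id>.gff3` per genome.
#' @param systems_path systems TSV.
#' @param mge_path MGE TSV (optional; `NULL` for none).
#' @param proteins_path protein FASTA, headers = gene_id.
#' @return object of class `defensome_dataset`: list with `manifest`,
#'   `genes`, `systems`, `mges`, `proteins`.
#' @export
read_dataset <- function(manifest_path, gene_table_dir, systems_path,
                         mge_path = NULL, proteins_path = NULL) {
  manifest <- read_manifest(manifest_path)
  genes <- do.call(rbind, lapply(manifest$genome_id, function(g) {
    read_gene_gff3(file.path(gene_table_dir, paste0(g, ".gff3")), g)
  }))
  systems <- read_systems(systems_path)
  mges <- if (!is.null(mge_path)) read_mges(mge_path) else empty_mges()
  proteins <- if (!is.null(proteins_path)) {
    if (!file.exists(proteins_path)) {
      stop("protein FASTA not found: ", proteins_path, call. = FALSE)
    }
    Biostrings::readAAStringSet(proteins_path)
  } else Biostrings::AAStringSet()
  ds <- new_dataset(manifest, genes, systems, mges, proteins)
  ds
}

empty_mges <- function() {
  data.frame(mge_uid = character(0), genome_id = character(0),
             replicon_id = character(0), start = integer(0),
             end = integer(0), mge_class = character(0),
             stringsAsFactors = FALSE)
}

#' Assemble and cross-validate an in-memory dataset
#'
#' @param manifest,genes,systems,mges data.frames in the package's table
#'   layouts.
#' @param proteins named `AAStringSet` (names are gene ids) or named
#'   character vector.
#' @return `defensome_dataset` object.
#' @export
new_dataset <- function(manifest, genes, systems, mges = empty_mges(),
                        proteins = Biostrings::AAStringSet()) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  validate_manifest(manifest)
  validate_genes(genes)
  validate_systems(systems)
  validate_mges(mges)

  unknown_g <- setdiff(unique(genes$genome_id), manifest$genome_id)
  if (length(unknown_g)) {
    stop("gene records for genomes absent from manifest: ",
         paste(unknown_g, collapse = ", "), call. = FALSE)
  }
  unknown_s <- setdiff(unique(systems$genome_id), manifest$genome_id)
  if (length(unknown_s)) {
    stop("systems reference genomes absent from manifest: ",
         paste(unknown_s, collapse = ", "), call. = FALSE)
  }
  unknown_m <- setdiff(unique(mges$genome_id), manifest$genome_id)
  if (length(unknown_m)) {
    stop("MGEs reference genomes absent from manifest: ",
         paste(unknown_m, collapse = ", "), call. = FALSE)
  }

  # every component gene must resolve to a GeneRecord of the same genome
  gene_key <- paste(genes$genome_id, genes$gene_id)
  for (i in seq_len(nrow(systems))) {
    comp <- systems$component_gene_ids[[i]]
    miss <- comp[!paste(systems$genome_id[i], comp) %in% gene_key]
    if (length(miss)) {
      stop(sprintf("system %s references unknown gene id(s): %s",
                   systems$system_uid[i], paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    if (length(proteins) > 0) {
      missp <- comp[!comp %in% names(proteins)]
      if (length(missp)) {
        stop(sprintf("system %s component(s) missing from protein FASTA: %s",
                     systems$system_uid[i], paste(missp, collapse = ", ")),
             call. = FALSE)
      }
    }
  }

  structure(list(manifest = manifest, genes = genes, systems = systems,
                 mges = mges, proteins = proteins),
            class = "defensome_dataset")
}

#' @export
print.defensome_dataset <- function(x, ...) {
  cat(sprintf(paste0("<defensome_dataset> %d genomes / %d species, ",
                     "%d genes, %d systems (%d complete), %d MGEs, ",
                     "%d proteins\n"),
              nrow(x$manifest), length(unique(x$manifest$species_id)),
              nrow(x$genes), nrow(x$systems), sum(x$systems$complete),
              nrow(x$mges), length(x$proteins)))
  invisible(x)
}

#' Apply genome quality-control filters
#'
#' Retains genomes with completeness >= 90% and contamination <= 5%
#' (both bounds inclusive; thresholds configurable).
#'
#' @param manifest manifest data.frame.
#' @param cfg [defensome_config()].
#' @return filtered manifest.
#' @export
filter_genomes_qc <- function(manifest, cfg = defensome_config()) {
  keep <- manifest$completeness_pct >= cfg$qc_min_completeness &
    manifest$contamination_pct <= cfg$qc_max_contamination
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select species for the core-defensome analysis
#'
#' A species is kept when it has at least `min_genomes_per_species` (default
#' 10) QC-passing genomes. Species in which no genome carries any complete
#' defense system are kept but flagged `excluded_from_hcads` rather than
#' deleted.
#'
#' @param manifest QC-filtered manifest.
#' @param systems systems table (used for the zero-systems flag); may be
#'   `NULL`.
#' @param cfg [defensome_config()].
#' @return data.frame with `species_id`, `n_genomes`, `kept`,
#'   `excluded_from_hcads`, sorted by `species_id`.
#' @export
select_species <- function(manifest, systems = NULL,
                           cfg = defensome_config()) {
  counts <- table(manifest$species_id)
  species <- sort(names(counts))
  n <- as.integer(counts[species])
  kept <- n >= cfg$min_genomes_per_species
  has_sys <- rep(FALSE, length(species))
  if (!is.null(systems) && nrow(systems) > 0) {
    sys_complete <- systems[systems$complete &
                              systems$polarity == "defense", , drop = FALSE]
    sp_of_genome <- manifest$species_id[match(sys_complete$genome_id,
                                              manifest$genome_id)]
    has_sys <- species %in% sp_of_genome
  }
  data.frame(species_id = species, n_genomes = n, kept = kept,
             excluded_from_hcads = kept & !has_sys,
             stringsAsFactors = FALSE)
}
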