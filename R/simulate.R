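# Synthetic pangenome and phage-contig generators with planted ground
# truth. The mutation model is substitution-only (no indels) so planted
# identity levels are analytically bounded: with per-member substitution
# count s = round(d * L), any two members of a block differ at <= 2s
# positions, and decoy paralogs derived from an 85%-identity ancestor can
# never reach the 95% RBH threshold.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
DNA4 <- c("A", "C", "G", "T")

#' Synthetic pangenome configuration
#'
#' Defaults are the package's stated demo world: 5 species of 20 genomes,
#' 120 genes per genome, six planted conservation blocks per species at
#' presence fractions 1.0 / 0.95 / 0.9 / 0.5 arranged into two defense
#' islands, a same-family decoy paralog block at 85% identity carried by a
#' prophage, and an MGE layout exercising overlap exclusion (an ICE
#' overlapping a mobile integron), an empty plasmid and a sedentary
#' integron.
#'
#' @param n_species number of species.
#' @param genomes_per_species genomes per species.
#' @param genes_per_genome genes per genome (single circular replicon).
#' @param planted_blocks data.frame with columns `family`,
#'   `presence_frac`, `n_components`, `island` (integer island id or NA),
#'   `mge_class` (class or NA).
#' @param within_block_divergence_frac per-member substitution fraction
#'   from the block ancestor (default 0.02, keeping all within-block pairs
#'   >= 95% identity).
#' @param decoy_paralog_identity_pct identity of the decoy ancestor to the
#'   first block's ancestor (default 85, keeping all decoy/block pairs
#'   < 95%).
#' @param decoy_presence_frac fraction of genomes carrying the decoy block.
#' @param circular mark the replicon circular.
#' @param rng_seed integer seed; the whole output is a deterministic
#'   function of the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 5,
                       genomes_per_species = 20,
                       genes_per_genome = 120,
                       planted_blocks = default_planted_blocks(),
                       within_block_divergence_frac = 0.02,
                       decoy_paralog_identity_pct = 85,
                       decoy_presence_frac = 0.2,
                       circular = TRUE,
                       rng_seed = 42L) {
  stopifnot(all(planted_blocks$presence_frac > 0),
            all(planted_blocks$presence_frac <= 1),
            all(planted_blocks$n_components >= 1))
  # planted orthologs must stay above and decoys below the RBH threshold
  stopifnot(100 * (1 - 2 * within_block_divergence_frac) >= 95,
            decoy_paralog_identity_pct +
              200 * within_block_divergence_frac < 95)
  structure(list(n_species = as.integer(n_species),
                 genomes_per_species = as.integer(genomes_per_species),
                 genes_per_genome = as.integer(genes_per_genome),
                 planted_blocks = planted_blocks,
                 within_block_divergence_frac = within_block_divergence_frac,
                 decoy_paralog_identity_pct = decoy_paralog_identity_pct,
                 decoy_presence_frac = decoy_presence_frac,
                 circular = isTRUE(circular),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Default planted-block layout of the demo world
#' @return data.frame of six planted blocks.
#' @export
default_planted_blocks <- function() {
  data.frame(
    family = c("Gabija", "Septu", "RM_Type_I", "Thoeris", "CBASS",
               "Zorya_Type_II"),
    presence_frac = c(1.0, 1.0, 0.95, 0.90, 1.0, 0.50),
    n_components = c(3L, 2L, 2L, 2L, 2L, 2L),
    island = c(1L, 1L, 1L, 2L, 2L, 2L),
    mge_class = NA_character_,
    stringsAsFactors = FALSE
  )
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

mutate_protein <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_sub)
  repl <- sample(AA20, n_sub, TRUE)
  bad <- repl == v[pos]
  while (any(bad)) {  # resample until every substitution changes the residue
    repl[bad] <- sample(AA20, sum(bad), TRUE)
    bad <- repl == v[pos]
  }
  v[pos] <- repl
  paste(v, collapse = "")
}

mutate_dna <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(v), n_sub)
    for (p in pos) v[p] <- sample(setdiff(DNA4, v[p]), 1)
  }
  paste(v, collapse = "")
}

hamming_identity_pct <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  100 * sum(va == vb) / length(va)
}

# Allocate 0-based gene ranks for planted features. Island blocks get
# contiguous windows with a 1-gene background gap between systems; isolated
# blocks, the decoy and MGE regions are separated by >= 15 background genes
# so they can never chain into a planted island (gap bound is 10).
plan_layout <- function(blocks, genes_per_genome, decoy_components) {
  sep <- 15L
  pos <- 10L
  slots <- vector("list", nrow(blocks))
  island_ids <- sort(unique(blocks$island[!is.na(blocks$island)]))
  for (isl in island_ids) {
    idx <- which(!is.na(blocks$island) & blocks$island == isl)
    for (bi in idx) {
      slots[[bi]] <- seq.int(pos, length.out = blocks$n_components[bi])
      pos <- pos + blocks$n_components[bi] + 1L  # 1 background gene gap
    }
    pos <- pos + sep
  }
  for (bi in which(is.na(blocks$island))) {
    slots[[bi]] <- seq.int(pos, length.out = blocks$n_components[bi])
    pos <- pos + blocks$n_components[bi] + sep
  }
  decoy_slots <- seq.int(pos, length.out = decoy_components)
  pos <- pos + decoy_components + sep
  # background gene windows hosting the MGE fixtures
  mge_regions <- list(
    plasmid = seq.int(pos, length.out = 4L),
    ice_overlap = seq.int(pos + 6L, length.out = 5L),
    integron_mobile_overlap = seq.int(pos + 9L, length.out = 5L),
    integron_sedentary = seq.int(pos + 16L, length.out = 3L)
  )
  pos <- pos + 20L
  if (pos >= genes_per_genome) {
    stop(sprintf("infeasible layout: %d gene slots needed, %d available",
                 pos + 1L, genes_per_genome), call. = FALSE)
  }
  list(slots = slots, decoy_slots = decoy_slots, mge_regions = mge_regions)
}

#' Simulate a multi-species pangenome with planted conservation structure
#'
#' Emits (optionally to disk, in the package's table dialects) a manifest,
#' per-genome GFF3 gene tables, a systems TSV, an MGE TSV and a protein
#' FASTA, together with the ground truth needed to score every pipeline
#' stage. A planted block of presence fraction `p` is carried by the first
#' `round(p * genomes_per_species)` genomes (carrier sets are nested, so
#' the 0.90 boundary is exactly plantable, e.g. 18/20). Each carrier's
#' component proteins are the block ancestor with exactly
#' `round(d * L)` substitutions. The decoy block shares the first block's
#' family but descends from an 85%-identity ancestor, so it must be
#' recovered as a separate accessory block. Planted identity levels are
#' verified post hoc by assertion.
#'
#' @param cfg [sim_config()].
#' @param out_dir if non-NULL, write the dataset files under this
#'   directory (`manifest.tsv`, `genes/<genome>.gff3`, `systems.tsv`,
#'   `mges.tsv`, `proteins.faa`).
#' @return list with `dataset` (a `defensome_dataset`) and `truth` (see
#'   Details), plus `dir` when written.
#' @details `truth$blocks` holds one row per planted block and species with
#'   the planted classification and member uids; `truth$islands` the
#'   per-genome called island spans (computed definitionally from planted
#'   placements, not by the detector); `truth$contexts` the per-instance
#'   MGE context.
#' @export
simulate_pangenome <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$rng_seed)
  blocks <- cfg$planted_blocks
  n_blk <- nrow(blocks)
  decoy_comp <- 2L
  layout <- plan_layout(blocks, cfg$genes_per_genome, decoy_comp)

  manifest <- list(); genes <- list(); systems <- list(); mges <- list()
  proteins <- character(0)
  truth_blocks <- list(); truth_islands <- list(); truth_ctx <- list()

  for (sp in seq_len(cfg$n_species)) {
    species_id <- sprintf("sp%02d", sp)
    genome_ids <- sprintf("%s_G%02d", species_id, seq_len(cfg$genomes_per_species))
    n_g <- cfg$genomes_per_species

    # ancestors: per block component; decoy derived from block 1
    anc <- lapply(seq_len(n_blk), function(bi) {
      vapply(seq_len(blocks$n_components[bi]), function(j) {
        random_protein(sample(150:250, 1))
      }, character(1))
    })
    decoy_anc <- vapply(seq_len(decoy_comp), function(j) {
      base <- anc[[1]][j]
      n_sub <- round((1 - cfg$decoy_paralog_identity_pct / 100) *
                       nchar(base))
      mutate_protein(base, n_sub)
    }, character(1))
    decoy_family <- blocks$family[1]

    carriers <- lapply(blocks$presence_frac, function(p) {
      genome_ids[seq_len(round(p * n_g))]
    })
    decoy_carriers <- genome_ids[seq_len(round(cfg$decoy_presence_frac * n_g))]

    member_uids <- vector("list", n_blk)
    decoy_uids <- character(0)

    for (g in seq_len(n_g)) {
      gid <- genome_ids[g]
      aa_len <- integer(cfg$genes_per_genome)
      seqs <- character(cfg$genes_per_genome)
      # background genes everywhere first
      aa_len[] <- sample(80:200, cfg$genes_per_genome, TRUE)

      def_rows <- list()
      for (bi in seq_len(n_blk)) {
        if (!gid %in% carriers[[bi]]) next
        uid <- sprintf("%s_%s_sys", gid, blocks$family[bi])
        slot <- layout$slots[[bi]]
        comp_ids <- sprintf("%s_g%04d", gid, slot + 1L)
        for (j in seq_along(slot)) {
          s <- anc[[bi]][j]
          n_sub <- round(cfg$within_block_divergence_frac * nchar(s))
          seqs[slot[j] + 1L] <- mutate_protein(s, n_sub)
          aa_len[slot[j] + 1L] <- nchar(s)
        }
        member_uids[[bi]] <- c(member_uids[[bi]], uid)
        def_rows[[length(def_rows) + 1L]] <- list(
          uid = uid, family = blocks$family[bi], comp = comp_ids,
          slot = slot, mge = blocks$mge_class[bi])
        truth_ctx[[length(truth_ctx) + 1L]] <- data.frame(
          system_uid = uid,
          context = ifelse(is.na(blocks$mge_class[bi]), "chromosome",
                           blocks$mge_class[bi]),
          stringsAsFactors = FALSE)
      }
      if (gid %in% decoy_carriers) {
        uid <- sprintf("%s_%s_decoy", gid, decoy_family)
        slot <- layout$decoy_slots
        comp_ids <- sprintf("%s_g%04d", gid, slot + 1L)
        for (j in seq_along(slot)) {
          s <- decoy_anc[j]
          n_sub <- round(cfg$within_block_divergence_frac * nchar(s))
          seqs[slot[j] + 1L] <- mutate_protein(s, n_sub)
          aa_len[slot[j] + 1L] <- nchar(s)
        }
        decoy_uids <- c(decoy_uids, uid)
        def_rows[[length(def_rows) + 1L]] <- list(
          uid = uid, family = decoy_family, comp = comp_ids,
          slot = slot, mge = "prophage")
        truth_ctx[[length(truth_ctx) + 1L]] <- data.frame(
          system_uid = uid, context = "prophage", stringsAsFactors = FALSE)
      }
      # fill background sequences
      bg <- which(seqs == "")
      seqs[bg] <- vapply(aa_len[bg], random_protein, character(1))

      # coordinates: genes laid consecutively, 100 bp intergenic
      gene_bp <- aa_len * 3L + 3L
      starts <- cumsum(c(101L, utils::head(gene_bp + 100L, -1L)))
      ends <- starts + gene_bp - 1L
      gene_ids <- sprintf("%s_g%04d", gid, seq_len(cfg$genes_per_genome))
      genes[[gid]] <- data.frame(
        genome_id = gid, replicon_id = paste0(gid, "_chr"),
        gene_id = gene_ids, rank = seq_len(cfg$genes_per_genome) - 1L,
        start = starts, end = ends, strand = "+",
        is_circular_replicon = cfg$circular, stringsAsFactors = FALSE)
      names(seqs) <- gene_ids
      proteins <- c(proteins, seqs)

      for (dr in def_rows) {
        systems[[length(systems) + 1L]] <- data.frame(
          system_uid = dr$uid, genome_id = gid,
          replicon_id = paste0(gid, "_chr"), family = dr$family,
          polarity = "defense", complete = TRUE, stringsAsFactors = FALSE)
        systems[[length(systems)]]$component_gene_ids <- list(dr$comp)
      }

      # MGE fixtures (bp intervals over the fixed gene windows)
      span_of <- function(slots) {
        c(starts[slots[1] + 1L] - 50L, ends[slots[length(slots)] + 1L] + 50L)
      }
      add_mge <- function(uid, slots, cls) {
        sp_bp <- span_of(slots)
        mges[[length(mges) + 1L]] <<- data.frame(
          mge_uid = paste0(gid, "_", uid), genome_id = gid,
          replicon_id = paste0(gid, "_chr"), start = sp_bp[1],
          end = sp_bp[2], mge_class = cls, stringsAsFactors = FALSE)
      }
      # one MGE interval per planted system that lives on an MGE
      for (dr in def_rows) {
        if (!is.na(dr$mge)) {
          add_mge(paste0(dr$uid, "_mge"), dr$slot, dr$mge)
        }
      }
      add_mge("plasmid1", layout$mge_regions$plasmid, "plasmid")
      add_mge("ice1", layout$mge_regions$ice_overlap, "ICE")
      add_mge("im1", layout$mge_regions$integron_mobile_overlap,
              "integron_mobile")
      add_mge("is1", layout$mge_regions$integron_sedentary,
              "integron_sedentary")

      manifest[[gid]] <- data.frame(
        species_id = species_id, genome_id = gid,
        genome_size_bp = ends[length(ends)] + 200L,
        completeness_pct = round(stats::runif(1, 95, 100), 2),
        contamination_pct = round(stats::runif(1, 0, 2), 2),
        stringsAsFactors = FALSE)

      # truth islands for this genome: a planted island is called iff the
      # blocks present reach >= 5 defense genes from >= 3 families
      for (isl in sort(unique(blocks$island[!is.na(blocks$island)]))) {
        idx <- which(!is.na(blocks$island) & blocks$island == isl &
                       vapply(carriers, function(cc) gid %in% cc,
                              logical(1)))
        if (!length(idx)) next
        n_genes <- sum(blocks$n_components[idx])
        n_fam <- length(unique(blocks$family[idx]))
        if (n_genes >= 5 && n_fam >= 3) {
          ranks <- sort(unlist(layout$slots[idx]))
          truth_islands[[length(truth_islands) + 1L]] <- data.frame(
            genome_id = gid, island = isl,
            start_rank = ranks[1], end_rank = ranks[length(ranks)],
            member_system_uids = paste(
              sort(sprintf("%s_%s_sys", gid, blocks$family[idx])),
              collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }

    pres_count <- vapply(carriers, length, integer(1))
    tb <- data.frame(
      species_id = species_id, family = blocks$family,
      presence_count = pres_count, genome_count = n_g,
      presence_frac = pres_count / n_g,
      classification = classify_presence(pres_count / n_g),
      island = blocks$island, stringsAsFactors = FALSE)
    tb$member_system_uids <- lapply(member_uids, sort)
    dec <- data.frame(
      species_id = species_id, family = decoy_family,
      presence_count = length(decoy_carriers), genome_count = n_g,
      presence_frac = length(decoy_carriers) / n_g,
      classification = classify_presence(length(decoy_carriers) / n_g),
      island = NA_integer_, stringsAsFactors = FALSE)
    dec$member_system_uids <- list(sort(decoy_uids))
    truth_blocks[[species_id]] <- rbind(tb, dec)

    # planted-identity assertions: within-block pairs >= 95%, decoy vs
    # block-1 pairs < 95% (first component of each, all carrier pairs)
    assert_planted_identities(proteins, member_uids, decoy_uids, blocks,
                              layout, decoy_comp)
  }

  manifest <- do.call(rbind, manifest)
  genes <- do.call(rbind, genes)
  systems <- do.call(rbind, systems)
  mges <- do.call(rbind, mges)
  rownames(manifest) <- rownames(genes) <- rownames(systems) <-
    rownames(mges) <- NULL
  ds <- new_dataset(manifest, genes, systems, mges,
                    Biostrings::AAStringSet(proteins))
  truth <- list(
    blocks = {
      tb <- do.call(rbind, truth_blocks); rownames(tb) <- NULL; tb
    },
    islands = if (length(truth_islands)) {
      ti <- do.call(rbind, truth_islands); rownames(ti) <- NULL; ti
    } else NULL,
    contexts = {
      tc <- do.call(rbind, truth_ctx); rownames(tc) <- NULL; tc
    }
  )
  out <- list(dataset = ds, truth = truth)
  if (!is.null(out_dir)) {
    out$dir <- write_sim_dataset(ds, out_dir)
  }
  out
}

assert_planted_identities <- function(proteins, member_uids, decoy_uids,
                                      blocks, layout, decoy_comp) {
  first_comp_seq <- function(uid, slot) {
    # genome ids are always "spXX_GYY": the first two underscore tokens
    gid <- paste(strsplit(uid, "_")[[1]][1:2], collapse = "_")
    proteins[[sprintf("%s_g%04d", gid, slot + 1L)]]
  }
  for (bi in seq_len(nrow(blocks))) {
    uids <- member_uids[[bi]]
    if (length(uids) < 2) next
    seqs <- vapply(uids, first_comp_seq, character(1),
                   slot = layout$slots[[bi]][1])
    n <- length(seqs)
    for (i in seq_len(n - 1)) {
      stopifnot(hamming_identity_pct(seqs[i], seqs[i + 1]) >= 95)
    }
  }
  if (length(decoy_uids) && length(member_uids[[1]])) {
    d <- first_comp_seq(decoy_uids[1], layout$decoy_slots[1])
    b <- first_comp_seq(member_uids[[1]][1], layout$slots[[1]][1])
    stopifnot(hamming_identity_pct(d, b) < 95)
  }
  invisible(TRUE)
}

write_sim_dataset <- function(ds, out_dir) {
  dir.create(file.path(out_dir, "genes"), recursive = TRUE,
             showWarnings = FALSE)
  write_manifest(ds$manifest, file.path(out_dir, "manifest.tsv"))
  for (g in ds$manifest$genome_id) {
    write_gene_gff3(ds$genes[ds$genes$genome_id == g, , drop = FALSE],
                    file.path(out_dir, "genes", paste0(g, ".gff3")))
  }
  write_systems(ds$systems, file.path(out_dir, "systems.tsv"))
  write_mges(ds$mges, file.path(out_dir, "mges.tsv"))
  Biostrings::writeXStringSet(ds$proteins,
                              file.path(out_dir, "proteins.faa"))
  out_dir
}

#' Simulate phage contigs with planted vOTU structure and HCCDS
#'
#' Each vOTU descends from a random ancestor contig; members carry exactly
#' `round(d * L)` nucleotide substitutions, keeping intra-vOTU ANI at
#' `>= 100 * (1 - 2d)` while inter-vOTU pairs (independent random
#' sequences) stay far below the 95% threshold and are omitted from the
#' sparse ANI table. Planted counter-defense systems are generated like
#' pangenome blocks: a per-vOTU protein ancestor per component, members
#' mutated at 2%.
#'
#' @param n_votus number of vOTUs.
#' @param members_per_votu contigs per vOTU.
#' @param within_votu_divergence nucleotide substitution fraction (default
#'   0.01; must satisfy `100 * (1 - 2d) >= 95`).
#' @param planted_hccds data.frame with columns `family`, `presence_frac`,
#'   `n_components` (default: one anti-R-M block in every member and one
#'   anti-CRISPR block at 11/12ths presence).
#' @param contig_len ancestor contig length in bp.
#' @param genes_per_contig genes per contig.
#' @param rng_seed integer seed.
#' @return list with `dataset` (contig manifest/genes/systems/proteins),
#'   `contigs` (`DNAStringSet`), `ani` (sparse intra-vOTU table computed by
#'   direct column comparison) and `truth` (vOTU membership and HCCDS
#'   labels).
#' @export
simulate_phage_contigs <- function(n_votus = 3,
                                   members_per_votu = 10,
                                   within_votu_divergence = 0.01,
                                   planted_hccds = default_planted_hccds(),
                                   contig_len = 4000L,
                                   genes_per_contig = 12L,
                                   rng_seed = 42L) {
  if (100 * (1 - 2 * within_votu_divergence) < 95) {
    stop("within_votu_divergence too high: intra-vOTU ANI would drop below 95",
         call. = FALSE)
  }
  set.seed(rng_seed)
  contigs <- character(0)
  manifest <- list(); genes <- list(); systems <- list()
  proteins <- character(0)
  ani_rows <- list(); truth_votus <- list(); truth_hccds <- list()

  for (v in seq_len(n_votus)) {
    vid <- sprintf("votu%02d", v)
    cids <- sprintf("%s_c%02d", vid, seq_len(members_per_votu))
    anc_dna <- paste(sample(DNA4, contig_len, TRUE), collapse = "")
    n_sub <- round(within_votu_divergence * contig_len)
    member_seq <- vapply(cids, function(x) mutate_dna(anc_dna, n_sub),
                         character(1))
    contigs <- c(contigs, member_seq)

    anc_prot <- lapply(seq_len(nrow(planted_hccds)), function(bi) {
      vapply(seq_len(planted_hccds$n_components[bi]),
             function(j) random_protein(sample(120:200, 1)), character(1))
    })
    carriers <- lapply(planted_hccds$presence_frac, function(p) {
      cids[seq_len(round(p * members_per_votu))]
    })

    for (m in seq_len(members_per_votu)) {
      cid <- cids[m]
      aa_len <- sample(80:150, genes_per_contig, TRUE)
      seqs <- character(genes_per_contig)
      slot_ptr <- 2L
      for (bi in seq_len(nrow(planted_hccds))) {
        if (!cid %in% carriers[[bi]]) {
          slot_ptr <- slot_ptr + planted_hccds$n_components[bi] + 1L
          next
        }
        uid <- sprintf("%s_%s_sys", cid, planted_hccds$family[bi])
        slots <- seq.int(slot_ptr, length.out = planted_hccds$n_components[bi])
        comp_ids <- sprintf("%s_g%03d", cid, slots)
        for (j in seq_along(slots)) {
          s <- anc_prot[[bi]][j]
          seqs[slots[j]] <- mutate_protein(s, round(0.02 * nchar(s)))
          aa_len[slots[j]] <- nchar(s)
        }
        systems[[length(systems) + 1L]] <- {
          df <- data.frame(system_uid = uid, genome_id = cid,
                           replicon_id = cid,
                           family = planted_hccds$family[bi],
                           polarity = "counter_defense", complete = TRUE,
                           stringsAsFactors = FALSE)
          df$component_gene_ids <- list(comp_ids)
          df
        }
        slot_ptr <- slot_ptr + planted_hccds$n_components[bi] + 1L
      }
      bg <- which(seqs == "")
      seqs[bg] <- vapply(aa_len[bg], random_protein, character(1))
      gene_bp <- aa_len * 3L + 3L
      starts <- cumsum(c(51L, utils::head(gene_bp + 50L, -1L)))
      gene_ids <- sprintf("%s_g%03d", cid, seq_len(genes_per_contig))
      genes[[cid]] <- data.frame(
        genome_id = cid, replicon_id = cid, gene_id = gene_ids,
        rank = seq_len(genes_per_contig) - 1L, start = starts,
        end = starts + gene_bp - 1L, strand = "+",
        is_circular_replicon = FALSE, stringsAsFactors = FALSE)
      names(seqs) <- gene_ids
      proteins <- c(proteins, seqs)
      manifest[[cid]] <- data.frame(
        species_id = "phage", genome_id = cid,
        genome_size_bp = contig_len, completeness_pct = 100,
        contamination_pct = 0, stringsAsFactors = FALSE)
    }

    # sparse ANI table: intra-vOTU pairs by direct column comparison
    for (i in seq_len(members_per_votu - 1)) {
      for (j in seq.int(i + 1, members_per_votu)) {
        ani_rows[[length(ani_rows) + 1L]] <- data.frame(
          query_contig = cids[i], target_contig = cids[j],
          ani_pct = hamming_identity_pct(member_seq[i], member_seq[j]),
          query_cov_frac = 1, target_cov_frac = 1,
          stringsAsFactors = FALSE)
      }
    }
    truth_votus[[vid]] <- cids
    pres <- vapply(carriers, length, integer(1))
    truth_hccds[[vid]] <- data.frame(
      votu = vid, family = planted_hccds$family,
      presence_count = pres, member_count = members_per_votu,
      classification = if (members_per_votu >= 10) {
        classify_presence(pres / members_per_votu)
      } else "skipped",
      stringsAsFactors = FALSE)
  }

  manifest <- do.call(rbind, manifest)
  genes <- do.call(rbind, genes)
  systems <- if (length(systems)) do.call(rbind, systems) else {
    s <- data.frame(system_uid = character(0), genome_id = character(0),
                    replicon_id = character(0), family = character(0),
                    polarity = character(0), complete = logical(0),
                    stringsAsFactors = FALSE)
    s$component_gene_ids <- list(); s
  }
  rownames(manifest) <- rownames(genes) <- rownames(systems) <- NULL
  ds <- new_dataset(manifest, genes, systems,
                    proteins = Biostrings::AAStringSet(proteins))
  list(
    dataset = ds,
    contigs = Biostrings::DNAStringSet(contigs),
    ani = if (length(ani_rows)) do.call(rbind, ani_rows) else
      data.frame(query_contig = character(0), target_contig = character(0),
                 ani_pct = numeric(0), query_cov_frac = numeric(0),
                 target_cov_frac = numeric(0)),
    truth = list(votus = truth_votus,
                 hccds = do.call(rbind, truth_hccds))
  )
}

#' Default planted counter-defense blocks
#' @return data.frame of two planted HCCDS blocks.
#' @export
default_planted_hccds <- function() {
  data.frame(family = c("anti_RM", "anti_CRISPR"),
             presence_frac = c(1.0, 0.9),
             n_components = c(2L, 1L),
             stringsAsFactors = FALSE)
}
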