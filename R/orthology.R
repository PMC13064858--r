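# Reciprocal-best-hit orthology between defense-system proteins of genome
# pairs within a species, lifted to a system-level conservation relation.

# Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1
# (BLAST's gapped defaults). E = K * m * n * exp(-lambda * S);
# bitscore = (lambda * S - ln K) / ln 2.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local similarity of two protein sequences
#'
#' The built-in backend performs Smith-Waterman local alignment under
#' BLOSUM62 with gap open 11 / extend 1 and reports percent identity over
#' alignment columns (gaps included), per-sequence coverage (aligned span /
#' sequence length) and a Karlin-Altschul e-value computed from the raw
#' score with the gapped BLOSUM62 constants (lambda = 0.267, K = 0.041).
#' It is a desk-scale stand-in for an external all-vs-all search; production
#' runs can instead feed a precomputed hit table to [build_hit_table()].
#'
#' The `"identity"` backend is an alignment-free test mode: equal-length
#' sequences are compared column by column (no indels assumed) and the
#' e-value is set to 0 so the e-value criterion is vacuously satisfied;
#' unequal-length pairs score 0.
#'
#' @param protein_a,protein_b amino-acid sequences (character or
#'   `AAString`); nonempty, 20-letter alphabet plus X.
#' @param backend `"builtin"` (Smith-Waterman) or `"identity"`.
#' @return one-row data.frame: `pct_identity`, `query_coverage_frac`,
#'   `subject_coverage_frac`, `evalue`, `bitscore`.
#' @examples
#' pairwise_similarity("MKVLATTLLG", "MKVLATTLLG")$pct_identity
#' @export
pairwise_similarity <- function(protein_a, protein_b,
                                backend = c("builtin", "identity")) {
  backend <- match.arg(backend)
  a <- as.character(protein_a)
  b <- as.character(protein_b)
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("empty protein sequence", call. = FALSE)
  }
  if (backend == "identity") {
    return(identity_similarity(a, b))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  hit_from_alignment(aln, nchar(a), nchar(b))
}

identity_similarity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    return(data.frame(pct_identity = 0, query_coverage_frac = 0,
                      subject_coverage_frac = 0, evalue = 0, bitscore = 0))
  }
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  ident <- sum(va == vb)
  data.frame(pct_identity = 100 * ident / nchar(a),
             query_coverage_frac = 1, subject_coverage_frac = 1,
             evalue = 0, bitscore = as.numeric(ident))
}

hit_from_alignment <- function(aln, len_a, len_b) {
  raw <- Biostrings::score(aln)
  bit <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  ev <- len_a * len_b * 2^(-bit)
  data.frame(
    pct_identity = Biostrings::pid(aln, type = "PID1"),
    query_coverage_frac =
      IRanges::width(Biostrings::pattern(aln)@range) / len_a,
    subject_coverage_frac =
      IRanges::width(Biostrings::subject(aln)@range) / len_b,
    evalue = ev,
    bitscore = bit
  )
}

# Pairs of sequence indices sharing at least one exact k-mer. Mirrors
# BLAST's seeding: any pair that could pass the 95% identity filter over a
# >= 24-column span must share a 6-mer (pigeonhole), so admissible hits are
# never lost to the prefilter.
kmer_seeded_pairs <- function(seqs, k = 6L) {
  n <- length(seqs)
  L <- nchar(seqs)
  kmer_list <- lapply(seq_len(n), function(i) {
    if (L[i] < k) return(seqs[[i]])
    unique(substring(seqs[[i]], seq_len(L[i] - k + 1L),
                     seq.int(k, L[i])))
  })
  posting <- split(rep(seq_len(n), lengths(kmer_list)), unlist(kmer_list))
  posting <- posting[lengths(posting) >= 2]
  if (!length(posting)) return(matrix(integer(0), ncol = 2))
  plists <- lapply(posting, function(v) {
    v <- sort.int(unique(v))
    if (length(v) < 2) return(NULL)
    utils::combn(v, 2)
  })
  plists <- plists[!vapply(plists, is.null, logical(1))]
  if (!length(plists)) return(matrix(integer(0), ncol = 2))
  pairs <- do.call(cbind, plists)
  enc <- unique(pairs[1, ] * (n + 1) + pairs[2, ])
  cbind(as.integer(enc %/% (n + 1)), as.integer(enc %% (n + 1)))
}

#' Build the all-vs-all cross-genome hit table for one species
#'
#' Compares every protein that is a component of a complete system of the
#' requested polarity against every such protein of every other genome of
#' the species (self-genome pairs excluded) and returns all ordered hit
#' rows. With the built-in backend, pairs that share no exact 6-mer are
#' reported with zero scores without alignment (they cannot be admissible).
#' In `external_tsv` mode the table is read from a precomputed all-vs-all
#' TSV with columns `query_gene_id`, `subject_gene_id`, `pct_identity`,
#' `query_coverage_frac`, `subject_coverage_frac`, `evalue`, `bitscore`.
#'
#' @param dataset `defensome_dataset`.
#' @param species_id species to process.
#' @param backend `"builtin"`, `"identity"` or `"external_tsv"`.
#' @param external_path hit-table TSV for `external_tsv` mode.
#' @param polarity `"defense"` (HCADS arm) or `"counter_defense"` (HCCDS).
#' @return data.frame of ordered hit rows, one per (query, subject) pair,
#'   with genome ids attached.
#' @export
build_hit_table <- function(dataset, species_id,
                            backend = c("builtin", "identity",
                                        "external_tsv"),
                            external_path = NULL,
                            polarity = "defense") {
  backend <- match.arg(backend)
  genomes <- dataset$manifest$genome_id[
    dataset$manifest$species_id == species_id]
  sys <- dataset$systems
  sys <- sys[sys$complete & sys$polarity == polarity &
               sys$genome_id %in% genomes, , drop = FALSE]
  gene_ids <- unique(unlist(sys$component_gene_ids))
  gene_genome <- rep(sys$genome_id, lengths(sys$component_gene_ids))
  names(gene_genome) <- unlist(sys$component_gene_ids)
  gene_genome <- gene_genome[gene_ids]

  if (backend == "external_tsv") {
    hits <- read_hit_table(external_path)
    unknown <- setdiff(unique(c(hits$query_gene_id, hits$subject_gene_id)),
                       gene_ids)
    if (length(unknown)) {
      stop("external hit table references unknown gene id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    hits$query_genome_id <- unname(gene_genome[hits$query_gene_id])
    hits$subject_genome_id <- unname(gene_genome[hits$subject_gene_id])
    hits <- hits[hits$query_genome_id != hits$subject_genome_id, ,
                 drop = FALSE]
    rownames(hits) <- NULL
    return(hits)
  }

  n <- length(gene_ids)
  if (n < 2 || length(unique(gene_genome)) < 2) {
    return(empty_hit_table())
  }
  seqs <- as.character(dataset$proteins[gene_ids])

  # candidate unordered cross-genome pairs
  cross <- which(outer(gene_genome, gene_genome, "!="), arr.ind = TRUE)
  cross <- cross[cross[, 1] < cross[, 2], , drop = FALSE]

  if (backend == "identity") {
    res <- lapply(seq_len(nrow(cross)), function(r) {
      identity_similarity(seqs[cross[r, 1]], seqs[cross[r, 2]])
    })
    res <- do.call(rbind, res)
  } else {
    seeded <- kmer_seeded_pairs(seqs)
    seed_key <- paste(seeded[, 1], seeded[, 2])
    is_seeded <- paste(cross[, 1], cross[, 2]) %in% seed_key
    res <- data.frame(pct_identity = numeric(nrow(cross)),
                      query_coverage_frac = 0, subject_coverage_frac = 0,
                      evalue = Inf, bitscore = 0)
    idx <- which(is_seeded)
    if (length(idx)) {
      # vectorize by grouping on the subject sequence
      by_subject <- split(idx, cross[idx, 2])
      for (sj in names(by_subject)) {
        rows <- by_subject[[sj]]
        j <- as.integer(sj)
        pats <- Biostrings::AAStringSet(seqs[cross[rows, 1]])
        aln <- Biostrings::pairwiseAlignment(
          pats, Biostrings::AAString(seqs[j]), type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
        res[rows, ] <- hit_from_alignment(aln, nchar(seqs[cross[rows, 1]]),
                                          nchar(seqs[j]))
      }
    }
  }

  forward <- data.frame(
    query_gene_id = gene_ids[cross[, 1]],
    subject_gene_id = gene_ids[cross[, 2]],
    pct_identity = res$pct_identity,
    query_coverage_frac = res$query_coverage_frac,
    subject_coverage_frac = res$subject_coverage_frac,
    evalue = res$evalue,
    bitscore = res$bitscore,
    query_genome_id = unname(gene_genome[gene_ids[cross[, 1]]]),
    subject_genome_id = unname(gene_genome[gene_ids[cross[, 2]]]),
    stringsAsFactors = FALSE
  )
  backward <- forward
  backward$query_gene_id <- forward$subject_gene_id
  backward$subject_gene_id <- forward$query_gene_id
  backward$query_coverage_frac <- forward$subject_coverage_frac
  backward$subject_coverage_frac <- forward$query_coverage_frac
  backward$query_genome_id <- forward$subject_genome_id
  backward$subject_genome_id <- forward$query_genome_id
  out <- rbind(forward, backward)
  rownames(out) <- NULL
  out
}

empty_hit_table <- function() {
  data.frame(query_gene_id = character(0), subject_gene_id = character(0),
             pct_identity = numeric(0), query_coverage_frac = numeric(0),
             subject_coverage_frac = numeric(0), evalue = numeric(0),
             bitscore = numeric(0), query_genome_id = character(0),
             subject_genome_id = character(0), stringsAsFactors = FALSE)
}

#' Read a precomputed all-vs-all hit table
#' @param path TSV with the seven hit columns (outfmt-6-like plus both
#'   coverages).
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  df <- read_tsv_strict(path, c("query_gene_id", "subject_gene_id",
                                "pct_identity", "query_coverage_frac",
                                "subject_coverage_frac", "evalue",
                                "bitscore"), "hit")
  for (col in c("pct_identity", "query_coverage_frac",
                "subject_coverage_frac", "evalue", "bitscore")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write a hit table TSV
#' @param hits hit data.frame from [build_hit_table()].
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  write_tsv(hits[, c("query_gene_id", "subject_gene_id", "pct_identity",
                     "query_coverage_frac", "subject_coverage_frac",
                     "evalue", "bitscore")], path)
}

#' Compute reciprocal best hits
#'
#' For every gene and every partner genome, the best hit is the one with
#' maximum bitscore over ALL hits against that genome; ties are broken by
#' minimum e-value, then maximum identity, then lexicographically smallest
#' subject gene id. A reciprocal best-hit pair is emitted iff each gene is
#' the other's best hit in its genome AND both directed best hits satisfy
#' the admissibility thresholds: percent identity >= 95, coverage >= 0.80
#' (by default on both sequences: min of query and subject coverage) and
#' e-value <= 1e-4. Computing the reciprocal best first and filtering the
#' resulting pair ("a reciprocal best hit existed among them, and both
#' hits" pass the thresholds) makes the output monotone: raising any
#' threshold can only shrink the RBH set. Pairs are canonically ordered
#' (`gene_a < gene_b`) and deduplicated.
#'
#' @param hits hit table with genome id columns (see [build_hit_table()]).
#' @param cfg [defensome_config()].
#' @return data.frame: `gene_a`, `gene_b`, `genome_a`, `genome_b`.
#' @export
compute_rbh <- function(hits, cfg = defensome_config()) {
  if (nrow(hits) == 0) return(empty_rbh())
  h <- hits[hits$query_genome_id != hits$subject_genome_id, , drop = FALSE]
  if (nrow(h) == 0) return(empty_rbh())

  # integer-encode genes and genomes for fast keying
  ids <- unique(c(h$query_gene_id, h$subject_gene_id))
  qi <- match(h$query_gene_id, ids)
  si <- match(h$subject_gene_id, ids)
  genomes <- unique(h$subject_genome_id)
  gk <- match(h$subject_genome_id, genomes)
  ng <- length(genomes)

  # best hit per (query gene, subject genome) over all hits
  ord <- order((qi - 1) * ng + gk,
               -h$bitscore, h$evalue, -h$pct_identity, h$subject_gene_id,
               method = "radix")
  h <- h[ord, , drop = FALSE]
  qi <- qi[ord]; si <- si[ord]; gk <- gk[ord]
  keep <- !duplicated((qi - 1) * ng + gk)
  best <- h[keep, , drop = FALSE]
  qi <- qi[keep]; si <- si[keep]

  # mutual-best: the directed best-hit edge set intersected with its
  # transpose; then both directed hits must pass the thresholds
  cov <- if (cfg$coverage_mode == "both") {
    pmin(best$query_coverage_frac, best$subject_coverage_frac)
  } else {
    best$query_coverage_frac
  }
  adm <- best$pct_identity >= cfg$min_identity_pct &
    cov >= cfg$min_coverage_frac &
    best$evalue <= cfg$max_evalue
  k <- length(ids)
  j <- match((si - 1) * k + qi, (qi - 1) * k + si)  # reverse best row
  pass <- !is.na(j) & adm & adm[ifelse(is.na(j), 1L, j)]
  mutual <- best[pass, , drop = FALSE]
  if (nrow(mutual) == 0) return(empty_rbh())

  a_first <- mutual$query_gene_id < mutual$subject_gene_id
  out <- data.frame(
    gene_a = ifelse(a_first, mutual$query_gene_id, mutual$subject_gene_id),
    gene_b = ifelse(a_first, mutual$subject_gene_id, mutual$query_gene_id),
    genome_a = ifelse(a_first, mutual$query_genome_id,
                      mutual$subject_genome_id),
    genome_b = ifelse(a_first, mutual$subject_genome_id,
                      mutual$query_genome_id),
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(paste(out$gene_a, out$gene_b)), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_rbh <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             genome_a = character(0), genome_b = character(0),
             stringsAsFactors = FALSE)
}

#' Lift gene-level RBH pairs to system-level ortholog links
#'
#' Two complete system instances in different genomes are linked iff they
#' belong to the same family and every component gene of each instance has
#' an RBH partner among the component genes of the other (the all-components
#' rule; `min_component_match_frac < 1` relaxes it for sensitivity
#' analysis). Links are symmetric and stored once with canonical ordering.
#'
#' @param rbh RBH pairs from [compute_rbh()], restricted to one species.
#' @param systems systems table (complete instances of that species).
#' @param cfg [defensome_config()].
#' @return data.frame: `system_uid_a`, `system_uid_b`, `family`,
#'   `matched_component_count`, `total_component_count_a`,
#'   `total_component_count_b`.
#' @export
link_systems <- function(rbh, systems, cfg = defensome_config()) {
  empty <- data.frame(system_uid_a = character(0),
                      system_uid_b = character(0), family = character(0),
                      matched_component_count = integer(0),
                      total_component_count_a = integer(0),
                      total_component_count_b = integer(0),
                      stringsAsFactors = FALSE)
  systems <- systems[systems$complete, , drop = FALSE]
  if (nrow(rbh) == 0 || nrow(systems) == 0) return(empty)

  comp_gene <- unlist(systems$component_gene_ids)
  comp_sys <- rep(systems$system_uid, lengths(systems$component_gene_ids))
  comp_genome <- rep(systems$genome_id, lengths(systems$component_gene_ids))
  # gene ids are genome-scoped; qualify with genome to map genes to systems
  gene2sys <- split(comp_sys, paste(comp_genome, comp_gene))

  sys_of <- function(genes, genomes) {
    lst <- gene2sys[paste(genomes, genes)]
    lst[vapply(lst, is.null, logical(1))] <- list(character(0))
    lst
  }
  sys_a <- sys_of(rbh$gene_a, rbh$genome_a)
  sys_b <- sys_of(rbh$gene_b, rbh$genome_b)

  # expand each RBH pair into (system_a, system_b, gene_a, gene_b) tuples
  na <- lengths(sys_a); nb <- lengths(sys_b)
  reps <- na * nb
  if (sum(reps) == 0) return(empty)
  row_idx <- rep(seq_len(nrow(rbh)), reps)
  sa <- unlist(mapply(function(s, k) rep(s, each = k), sys_a, nb,
                      SIMPLIFY = FALSE))
  sb <- unlist(mapply(function(s, k) rep(s, times = k), sys_b, na,
                      SIMPLIFY = FALSE))
  tup <- data.frame(sys_a = sa, sys_b = sb,
                    gene_a = rbh$gene_a[row_idx],
                    gene_b = rbh$gene_b[row_idx],
                    stringsAsFactors = FALSE)

  fam <- systems$family[match(tup$sys_a, systems$system_uid)]
  fam_b <- systems$family[match(tup$sys_b, systems$system_uid)]
  tup <- tup[fam == fam_b, , drop = FALSE]
  if (nrow(tup) == 0) return(empty)

  # canonical system-pair key; count matched components on each side
  flip <- tup$sys_a > tup$sys_b
  key <- ifelse(flip, paste(tup$sys_b, tup$sys_a, sep = "\r"),
                paste(tup$sys_a, tup$sys_b, sep = "\r"))
  g1 <- ifelse(flip, tup$gene_b, tup$gene_a)
  g2 <- ifelse(flip, tup$gene_a, tup$gene_b)
  matched_1 <- vapply(split(g1, key), function(g) length(unique(g)),
                      integer(1))
  matched_2 <- vapply(split(g2, key), function(g) length(unique(g)),
                      integer(1))
  pair_ids <- do.call(rbind, strsplit(names(matched_1), "\r", fixed = TRUE))

  n_comp <- lengths(systems$component_gene_ids)
  names(n_comp) <- systems$system_uid
  tot_1 <- n_comp[pair_ids[, 1]]
  tot_2 <- n_comp[pair_ids[, 2]]
  need_1 <- ceiling(cfg$min_component_match_frac * tot_1)
  need_2 <- ceiling(cfg$min_component_match_frac * tot_2)
  ok <- matched_1 >= need_1 & matched_2 >= need_2

  out <- data.frame(
    system_uid_a = pair_ids[ok, 1],
    system_uid_b = pair_ids[ok, 2],
    family = systems$family[match(pair_ids[ok, 1], systems$system_uid)],
    matched_component_count = pmin(matched_1[ok], matched_2[ok]),
    total_component_count_a = unname(tot_1[ok]),
    total_component_count_b = unname(tot_2[ok]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$system_uid_a, out$system_uid_b, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
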