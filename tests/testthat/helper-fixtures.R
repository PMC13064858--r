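# Fixture builders and independent oracles shared across test files.

# --- tiny hand-built dataset: 2 genomes, 1 species -------------------------

tiny_manifest <- function() {
  data.frame(
    species_id = "S", genome_id = c("gA", "gB"),
    genome_size_bp = c(12000L, 12000L),
    completeness_pct = c(99, 98), contamination_pct = c(0.5, 1),
    stringsAsFactors = FALSE
  )
}

tiny_genes <- function() {
  g <- expand.grid(i = 1:10, genome_id = c("gA", "gB"),
                   stringsAsFactors = FALSE)
  data.frame(
    genome_id = g$genome_id,
    replicon_id = paste0(g$genome_id, "_chr"),
    gene_id = sprintf("%s_g%02d", g$genome_id, g$i),
    rank = g$i - 1L,
    start = (g$i - 1L) * 1000L + 101L,
    end = (g$i - 1L) * 1000L + 1000L,
    strand = "+",
    is_circular_replicon = FALSE,
    stringsAsFactors = FALSE
  )
}

tiny_proteins <- function() {
  set.seed(99)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  ids <- tiny_genes()$gene_id
  seqs <- vapply(ids, function(x) {
    paste(sample(aa, 120, TRUE), collapse = "")
  }, character(1))
  # make the Gabija components identical across the two genomes
  seqs["gB_g02"] <- seqs["gA_g02"]
  seqs["gB_g03"] <- seqs["gA_g03"]
  seqs
}

tiny_systems <- function() {
  s <- data.frame(
    system_uid = c("gA_gabija", "gB_gabija", "gA_rm"),
    genome_id = c("gA", "gB", "gA"),
    replicon_id = c("gA_chr", "gB_chr", "gA_chr"),
    family = c("Gabija", "Gabija", "RM_Type_I"),
    polarity = "defense",
    complete = TRUE,
    stringsAsFactors = FALSE
  )
  s$component_gene_ids <- list(c("gA_g02", "gA_g03"),
                               c("gB_g02", "gB_g03"),
                               "gA_g07")
  s
}

tiny_dataset <- function() {
  new_dataset(tiny_manifest(), tiny_genes(), tiny_systems(),
              proteins = tiny_proteins())
}

# --- hit-table builder for RBH unit tests ---------------------------------

make_hits <- function(q, s, qg, sg, id = 99, qc = 1, sc = 1, ev = 1e-30,
                      bit = 100) {
  if (!length(q)) {
    return(data.frame(query_gene_id = character(0),
                      subject_gene_id = character(0),
                      pct_identity = numeric(0),
                      query_coverage_frac = numeric(0),
                      subject_coverage_frac = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      query_genome_id = character(0),
                      subject_genome_id = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(query_gene_id = q, subject_gene_id = s,
             pct_identity = id, query_coverage_frac = qc,
             subject_coverage_frac = sc, evalue = ev, bitscore = bit,
             query_genome_id = qg, subject_genome_id = sg,
             stringsAsFactors = FALSE)
}

# Hit table for two genomes with an n x n admissible bitscore matrix;
# gene i of genome A is "a_i", gene j of genome B is "b_j". Built as a
# single data.frame for speed (the acceptance loop runs 1,000 of these).
hits_from_matrix <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  a <- sprintf("a%02d", i)
  b <- sprintf("b%02d", j)
  bit <- as.vector(m)
  k <- n1 * n2
  data.frame(query_gene_id = c(a, b), subject_gene_id = c(b, a),
             pct_identity = 99, query_coverage_frac = 1,
             subject_coverage_frac = 1, evalue = 1e-30,
             bitscore = c(bit, bit),
             query_genome_id = rep(c("A", "B"), each = k),
             subject_genome_id = rep(c("B", "A"), each = k),
             stringsAsFactors = FALSE)
}

# Brute-force mutual-best oracle over a score matrix: exhaustive scan with
# the same tie chain (here scores are made distinct so ties cannot occur).
rbh_oracle_matrix <- function(m) {
  pairs <- list()
  for (i in seq_len(nrow(m))) {
    best_j <- which.max(m[i, ])
    best_i_for_j <- which.max(m[, best_j])
    if (best_i_for_j == i) {
      pairs[[length(pairs) + 1L]] <- c(sprintf("a%02d", i),
                                       sprintf("b%02d", best_j))
    }
  }
  if (!length(pairs)) return(character(0))
  sort(vapply(pairs, paste, character(1), collapse = "|"))
}

# --- island brute-force oracle --------------------------------------------

# Independent route: graph over defense ranks with an edge between
# CONSECUTIVE defense genes (in replicon order, wrap included when
# circular) whose intervening-gene gap is within the bound; clusters are
# the connected components; filter by min genes / families.
island_oracle <- function(def_ranks, fams, n_genes, circular,
                          max_gap = 10, min_genes = 5, min_fams = 3) {
  k <- length(def_ranks)
  if (k == 0) return(list())
  ord <- order(def_ranks)
  r <- def_ranks[ord]
  f <- fams[ord]
  if (k == 1) {
    comps <- list(1L)
  } else {
    edges <- cbind(seq_len(k - 1), 2:k)[(r[-1] - r[-k] - 1) <= max_gap, ,
                                        drop = FALSE]
    if (circular) {
      wrap_gap <- (r[1] + n_genes) - r[k] - 1
      if (wrap_gap <= max_gap) edges <- rbind(edges, c(k, 1L))
    }
    # label propagation to fixpoint (independent of the package's greedy
    # chaining and union-find)
    labels <- seq_len(k)
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        u <- edges[e, 1]; v <- edges[e, 2]
        if (labels[u] != labels[v]) {
          lab <- min(labels[u], labels[v])
          labels[labels == labels[u] | labels == labels[v]] <- lab
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    comps <- split(seq_len(k), labels)
  }
  out <- Filter(function(idx) {
    length(idx) >= min_genes && length(unique(f[idx])) >= min_fams
  }, comps)
  lapply(unname(out), function(idx) sort(r[idx]))
}

# Build a one-genome dataset whose defense genes sit at the given ranks
# with the given families (one single-gene system per defense gene, so
# family counts are controlled exactly).
island_fixture <- function(def_ranks, fams, n_genes, circular = FALSE) {
  genes <- data.frame(
    genome_id = "g1", replicon_id = "chr",
    gene_id = sprintf("g1_%03d", seq_len(n_genes)),
    rank = seq_len(n_genes) - 1L,
    start = (seq_len(n_genes) - 1L) * 1000L + 1L,
    end = (seq_len(n_genes) - 1L) * 1000L + 900L,
    strand = "+", is_circular_replicon = circular,
    stringsAsFactors = FALSE
  )
  if (!length(def_ranks)) {
    systems <- data.frame(system_uid = character(0),
                          genome_id = character(0),
                          replicon_id = character(0),
                          family = character(0), polarity = character(0),
                          complete = logical(0), stringsAsFactors = FALSE)
    systems$component_gene_ids <- list()
  } else {
    systems <- data.frame(
      system_uid = sprintf("sys_%03d", seq_along(def_ranks)),
      genome_id = "g1", replicon_id = "chr", family = fams,
      polarity = "defense", complete = TRUE, stringsAsFactors = FALSE
    )
    systems$component_gene_ids <-
      as.list(sprintf("g1_%03d", def_ranks + 1L))
  }
  list(genes = genes, systems = systems)
}

# --- Mann-Whitney enumeration oracle --------------------------------------

mww_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  us <- apply(picks, 2, function(idx) sum(seq_len(n1 + n2)[idx]) -
                n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- greedy vOTU oracle (literal re-execution of the definition) ----------

votu_oracle <- function(lengths, ani, min_ani = 95, min_tcov = 0.85,
                        min_qcov = 0) {
  # explicit length-desc, id-asc order
  ids <- names(lengths)[order(-lengths, names(lengths))]
  # admissible member>centroid edges, both row orientations, built by a
  # single literal pass over the table
  edges <- character(0)
  for (i in seq_len(nrow(ani))) {
    if (ani$ani_pct[i] >= min_ani && ani$query_cov_frac[i] >= min_tcov &&
        ani$target_cov_frac[i] >= min_qcov) {
      edges <- c(edges, paste0(ani$query_contig[i], ">",
                               ani$target_contig[i]))
    }
    if (ani$ani_pct[i] >= min_ani && ani$target_cov_frac[i] >= min_tcov &&
        ani$query_cov_frac[i] >= min_qcov) {
      edges <- c(edges, paste0(ani$target_contig[i], ">",
                               ani$query_contig[i]))
    }
  }
  unassigned <- ids
  clusters <- list()
  while (length(unassigned)) {
    centroid <- unassigned[1]
    members <- centroid
    for (m in setdiff(unassigned, centroid)) {
      if (paste0(m, ">", centroid) %in% edges) members <- c(members, m)
    }
    clusters[[length(clusters) + 1L]] <-
      list(rep = centroid, members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

random_ani_table <- function(ids) {
  n <- length(ids)
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < 0.4
  pairs <- pairs[, keep, drop = FALSE]
  if (!ncol(pairs)) {
    return(data.frame(query_contig = character(0),
                      target_contig = character(0), ani_pct = numeric(0),
                      query_cov_frac = numeric(0),
                      target_cov_frac = numeric(0)))
  }
  data.frame(
    query_contig = pairs[1, ], target_contig = pairs[2, ],
    ani_pct = round(stats::runif(ncol(pairs), 90, 100), 2),
    query_cov_frac = round(stats::runif(ncol(pairs), 0.5, 1), 2),
    target_cov_frac = round(stats::runif(ncol(pairs), 0.5, 1), 2),
    stringsAsFactors = FALSE
  )
}
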