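aa_sample <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, TRUE),
        collapse = "")
}

test_that("pairwise_similarity handles identity, truncation and planted
           substitutions", {
  s <- aa_sample(100, 1)
  hit <- pairwise_similarity(s, s)
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$query_coverage_frac, 1)
  expect_equal(hit$subject_coverage_frac, 1)
  expect_lt(hit$evalue, 1e-10)

  half <- substr(s, 1, 50)
  hit2 <- pairwise_similarity(s, half)
  expect_equal(hit2$subject_coverage_frac, 1.0)
  expect_equal(hit2$query_coverage_frac, 0.5)

  # 4 substitutions planted away from the termini: the local alignment is
  # full length and ungapped, so identity is exactly 96/100 (column-count
  # oracle on the known alignment)
  v <- strsplit(s, "")[[1]]
  for (p in c(20, 40, 60, 80)) v[p] <- if (v[p] == "A") "W" else "A"
  hit3 <- pairwise_similarity(s, paste(v, collapse = ""))
  expect_equal(hit3$pct_identity, 96.0)

  expect_error(pairwise_similarity("", s), "empty")
})

test_that("identity backend is exact on equal-length pairs and vacuous on
           the e-value criterion", {
  s <- aa_sample(60, 2)
  v <- strsplit(s, "")[[1]]
  v[10] <- if (v[10] == "C") "M" else "C"
  hit <- pairwise_similarity(s, paste(v, collapse = ""),
                             backend = "identity")
  expect_equal(hit$pct_identity, 100 * 59 / 60)
  expect_identical(hit$evalue, 0)
})

test_that("build_hit_table emits all ordered cross-genome pairs", {
  ds <- tiny_dataset()
  # gA has 3 defense proteins (2 Gabija + 1 RM), gB has 2
  hits <- build_hit_table(ds, "S", backend = "identity")
  expect_identical(nrow(hits), 12L)
  expect_true(all(hits$query_genome_id != hits$subject_genome_id))

  # builtin mode agrees on the pair universe
  hits_b <- build_hit_table(ds, "S", backend = "builtin")
  expect_identical(nrow(hits_b), 12L)

  # external round-trip: dumping the builtin table and re-reading it
  # yields the identical downstream RBH set
  dir <- withr::local_tempdir()
  write_hit_table(hits_b, file.path(dir, "hits.tsv"))
  hits_ext <- build_hit_table(ds, "S", backend = "external_tsv",
                              external_path = file.path(dir, "hits.tsv"))
  expect_identical(compute_rbh(hits_ext), compute_rbh(hits_b))

  # external table with unknown ids is fatal
  bad <- read_hit_table(file.path(dir, "hits.tsv"))
  bad$query_gene_id[1] <- "gX_g99"
  write_hit_table(bad, file.path(dir, "bad.tsv"))
  expect_error(build_hit_table(ds, "S", backend = "external_tsv",
                               external_path = file.path(dir, "bad.tsv")),
               "gX_g99")
})

test_that("single-genome species produce an empty hit table", {
  ds <- tiny_dataset()
  ds$manifest$species_id <- c("S1", "S2")
  expect_identical(nrow(build_hit_table(ds, "S1", backend = "identity")),
                   0L)
})

test_that("compute_rbh applies the published admissibility thresholds", {
  # mutual hits at identity 97, coverage 0.9/0.9, e-value 1e-30 -> 1 pair
  h <- rbind(make_hits("a1", "b1", "A", "B", id = 97, qc = .9, sc = .9),
             make_hits("b1", "a1", "B", "A", id = 97, qc = .9, sc = .9))
  expect_identical(nrow(compute_rbh(h)), 1L)

  # identity 94.9 fails ">= 95"
  h$pct_identity <- 94.9
  expect_identical(nrow(compute_rbh(h)), 0L)

  # coverage rule uses min of the two coverages under mode "both"
  h2 <- rbind(make_hits("a1", "b1", "A", "B", qc = .79, sc = 1),
              make_hits("b1", "a1", "B", "A", qc = 1, sc = .79))
  expect_identical(nrow(compute_rbh(h2)), 0L)
  cfg_q <- defensome_config(coverage_mode = "query")
  h3 <- rbind(make_hits("a1", "b1", "A", "B", qc = .9, sc = .5),
              make_hits("b1", "a1", "B", "A", qc = .9, sc = .5))
  expect_identical(nrow(compute_rbh(h3, cfg_q)), 1L)

  # e-value bound inclusive at 1e-4
  h4 <- rbind(make_hits("a1", "b1", "A", "B", ev = 1e-4),
              make_hits("b1", "a1", "B", "A", ev = 1e-4))
  expect_identical(nrow(compute_rbh(h4)), 1L)
  h4$evalue <- 2e-4
  expect_identical(nrow(compute_rbh(h4)), 0L)

  expect_identical(nrow(compute_rbh(empty_hits <- make_hits(
    character(0), character(0), character(0), character(0)))), 0L)
})

test_that("RBH equals the brute-force mutual-best oracle on random score
           matrices", {
  set.seed(1234)
  for (trial in 1:100) {
    n <- sample(2:6, 1)
    m <- matrix(sample(1000:9999, n * n), n)  # distinct bitscores
    got <- compute_rbh(hits_from_matrix(m))
    got_keys <- sort(paste(got$gene_a, got$gene_b, sep = "|"))
    expect_identical(got_keys, rbh_oracle_matrix(m))
  }
})

test_that("RBH output is symmetric, deduplicated and bounded", {
  set.seed(99)
  m <- matrix(sample(1000:9999, 25), 5)
  rbh <- compute_rbh(hits_from_matrix(m))
  expect_false(any(duplicated(paste(rbh$gene_a, rbh$gene_b))))
  expect_lte(nrow(rbh), 5)
  expect_true(all(rbh$gene_a < rbh$gene_b))
})

test_that("raising any threshold never grows the RBH set (monotonicity)", {
  set.seed(7)
  h <- hits_from_matrix(matrix(sample(1000:9999, 16), 4))
  h$pct_identity <- round(runif(nrow(h), 90, 100), 1)
  h$query_coverage_frac <- round(runif(nrow(h), 0.6, 1), 2)
  h$subject_coverage_frac <- h$query_coverage_frac
  base <- compute_rbh(h, defensome_config(min_identity_pct = 90,
                                          min_coverage_frac = 0.6))
  for (idt in c(92, 95, 98)) {
    for (cov in c(0.7, 0.8, 0.9)) {
      sub <- compute_rbh(h, defensome_config(min_identity_pct = idt,
                                             min_coverage_frac = cov))
      expect_true(all(paste(sub$gene_a, sub$gene_b) %in%
                        paste(base$gene_a, base$gene_b)))
      expect_lte(nrow(sub), nrow(base))
    }
  }
})

test_that("link_systems requires all components matched within one family", {
  sys <- data.frame(
    system_uid = c("sysA", "sysB", "rmA", "rmB"),
    genome_id = c("A", "B", "A", "B"),
    replicon_id = "chr", family = c("Gabija", "Gabija", "RM", "RM"),
    polarity = "defense", complete = TRUE, stringsAsFactors = FALSE)
  sys$component_gene_ids <- list(c("a1", "a2", "a3"),
                                 c("b1", "b2", "b3"),
                                 "a9", "b9")
  full <- data.frame(gene_a = c("a1", "a2", "a3"),
                     gene_b = c("b1", "b2", "b3"),
                     genome_a = "A", genome_b = "B",
                     stringsAsFactors = FALSE)
  links <- link_systems(full, sys)
  expect_identical(nrow(links), 1L)
  expect_identical(links$system_uid_a, "sysA")
  expect_identical(links$matched_component_count, 3L)

  # 2 of 3 components matched -> no link (set-comparison oracle)
  partial <- full[1:2, ]
  expect_identical(nrow(link_systems(partial, sys)), 0L)
  # ... unless the component-match fraction is relaxed
  relaxed <- link_systems(partial, sys,
                          defensome_config(min_component_match_frac = 0.6))
  expect_identical(nrow(relaxed), 1L)

  # cross-family RBH pairs never contribute a link
  xfam <- data.frame(gene_a = "a1", gene_b = "b9", genome_a = "A",
                     genome_b = "B", stringsAsFactors = FALSE)
  expect_identical(nrow(link_systems(xfam, sys)), 0L)

  # symmetry: links are stored canonically regardless of input order
  rev_rbh <- full[3:1, ]
  expect_identical(link_systems(rev_rbh, sys), links)
})
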