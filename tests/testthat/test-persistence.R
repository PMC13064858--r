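# helpers to build a species of one-instance-per-genome systems plus an
# arbitrary link graph
species_systems <- function(genomes, family = "Gabija") {
  s <- data.frame(
    system_uid = paste0(genomes, "_sys"),
    genome_id = genomes, replicon_id = "chr", family = family,
    polarity = "defense", complete = TRUE, stringsAsFactors = FALSE)
  s$component_gene_ids <- as.list(paste0(genomes, "_g1"))
  s
}

links_between <- function(uids_a, uids_b, family = "Gabija") {
  if (!length(uids_a)) {
    return(data.frame(system_uid_a = character(0),
                      system_uid_b = character(0), family = character(0),
                      matched_component_count = integer(0),
                      total_component_count_a = integer(0),
                      total_component_count_b = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(system_uid_a = pmin(uids_a, uids_b),
             system_uid_b = pmax(uids_a, uids_b),
             family = family, matched_component_count = 1L,
             total_component_count_a = 1L, total_component_count_b = 1L,
             stringsAsFactors = FALSE)
}

test_that("a fully linked instance set forms one core block", {
  genomes <- sprintf("g%02d", 1:20)
  sys <- species_systems(genomes)
  prs <- t(utils::combn(sys$system_uid, 2))
  links <- links_between(prs[, 1], prs[, 2])
  blocks <- build_blocks(links, sys, genomes, "sp")
  expect_identical(nrow(blocks), 1L)
  expect_identical(blocks$presence_count, 20L)
  expect_identical(blocks$classification, "core")
  expect_setequal(blocks$member_system_uids[[1]], sys$system_uid)
})

test_that("presence 18/20 is quasi-core (inclusive 90% boundary)", {
  genomes <- sprintf("g%02d", 1:20)
  sys <- species_systems(genomes[1:18])
  prs <- t(utils::combn(sys$system_uid, 2))
  blocks <- build_blocks(links_between(prs[, 1], prs[, 2]), sys, genomes,
                         "sp")
  expect_equal(blocks$presence_frac, 0.90)
  expect_identical(blocks$classification, "quasi_core")
})

test_that("link components equal an independent connected-components
           oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(4:12, 1)
    genomes <- sprintf("g%02d", seq_len(n))
    sys <- species_systems(genomes)
    prs <- t(utils::combn(sys$system_uid, 2))
    keep <- runif(nrow(prs)) < 0.25
    links <- links_between(prs[keep, 1], prs[keep, 2])
    blocks <- build_blocks(links, sys, genomes, "sp")

    g <- igraph::graph_from_data_frame(
      links[, c("system_uid_a", "system_uid_b")], directed = FALSE,
      vertices = sys$system_uid)
    oracle <- split(names(igraph::components(g)$membership),
                    igraph::components(g)$membership)
    oracle <- sort(vapply(oracle, function(x) paste(sort(x), collapse = ","),
                          character(1)))
    got <- sort(vapply(blocks$member_system_uids, paste, character(1),
                       collapse = ","))
    expect_identical(unname(got), unname(oracle))
  }
})

test_that("two link components of the same family stay distinct blocks", {
  genomes <- sprintf("g%02d", 1:4)
  sys <- species_systems(genomes)
  links <- links_between(c("g01_sys", "g03_sys"),
                         c("g02_sys", "g04_sys"))
  blocks <- build_blocks(links, sys, genomes, "sp")
  expect_identical(nrow(blocks), 2L)
  expect_true(all(blocks$family == "Gabija"))
})

test_that("every instance lies in exactly one block (partition property)", {
  set.seed(7)
  genomes <- sprintf("g%02d", 1:10)
  sys <- rbind(species_systems(genomes, "Gabija"),
               species_systems(genomes[1:5], "RM"))
  sys$system_uid <- make.unique(sys$system_uid)
  blocks <- build_blocks(empty_links <- links_between(character(0),
                                                      character(0)),
                         sys, genomes, "sp")
  members <- unlist(blocks$member_system_uids)
  expect_identical(sort(members), sort(sys$system_uid))
  expect_false(any(duplicated(members)))
  expect_identical(sum(lengths(blocks$member_system_uids)), nrow(sys))
})

test_that("threshold boundaries: 1.0 core, 0.90 quasi, below accessory", {
  expect_identical(classify_presence(1.0), "core")
  expect_identical(classify_presence(0.90), "quasi_core")
  expect_identical(classify_presence(0.90 - 1e-9), "accessory")
  expect_identical(classify_presence(0.95), "quasi_core")
  expect_identical(classify_presence(17 / 20), "accessory")
})

test_that("adding an empty genome lowers every presence fraction", {
  genomes <- sprintf("g%02d", 1:10)
  sys <- species_systems(genomes)
  prs <- t(utils::combn(sys$system_uid, 2))
  links <- links_between(prs[, 1], prs[, 2])
  b1 <- build_blocks(links, sys, genomes, "sp")
  b2 <- build_blocks(links, sys, c(genomes, "g_empty"), "sp")
  expect_true(all(b2$presence_frac < b1$presence_frac))
  expect_identical(b2$classification, "quasi_core")  # 10/11 = 0.909
})

test_that("call_hcads summarises classifications and instance fractions", {
  genomes <- sprintf("g%02d", 1:20)
  mk <- function(fam, k) {
    s <- species_systems(genomes[seq_len(k)], fam)
    prs <- if (k > 1) t(utils::combn(s$system_uid, 2)) else
      matrix(character(0), ncol = 2)
    list(sys = s, links = links_between(prs[, 1], prs[, 2], fam))
  }
  a <- mk("FamCore", 20); b <- mk("FamQuasi", 19); cc <- mk("FamAcc", 10)
  sys <- rbind(a$sys, b$sys, cc$sys)
  sys$system_uid <- paste0(sys$family, "_", sys$system_uid)
  links <- rbind(a$links, b$links, cc$links)
  links$system_uid_a <- paste0(links$family, "_", links$system_uid_a)
  links$system_uid_b <- paste0(links$family, "_", links$system_uid_b)
  blocks <- build_blocks(links, sys, genomes, "sp")
  res <- call_hcads(blocks)
  expect_identical(res$summary$n_blocks, 3L)
  expect_identical(res$summary$n_hcads, 2L)
  expect_identical(res$summary$n_core, 1L)
  expect_identical(res$summary$n_quasi, 1L)
  expect_equal(res$summary$frac_instances_hcads, 39 / 49)
  expect_equal(res$summary$pct_core_of_hcads, 50)

  # no blocks -> zero summary
  res0 <- call_hcads(empty_blocks <- blocks[0, ])
  expect_identical(res0$summary$n_hcads, 0L)
  expect_identical(res0$summary$frac_instances_hcads, 0)
})

test_that("call_hccds applies the 10-member floor and reuses the block
           logic", {
  mk_votu <- function(vid, n) {
    data.frame(votu_id = vid, representative_contig = paste0(vid, "_c01"),
               n_members = n, stringsAsFactors = FALSE)
  }
  v10 <- mk_votu("v10", 10L); v10$member_contigs <- list(sprintf("v10_c%02d", 1:10))
  v9 <- mk_votu("v9", 9L); v9$member_contigs <- list(sprintf("v9_c%02d", 1:9))
  votus <- rbind(v10, v9)

  contigs <- votus$member_contigs[[1]]
  sys <- species_systems(contigs, "anti_RM")
  sys$polarity <- "counter_defense"
  prs <- t(utils::combn(sys$system_uid, 2))
  links <- list(v10 = links_between(prs[, 1], prs[, 2], "anti_RM"))

  res <- call_hccds(votus, sys, links)
  expect_identical(res$skipped, "v9")
  expect_identical(nrow(res$hccds), 1L)
  expect_identical(res$hccds$classification, "core")

  # 11 of 12 members (0.917) -> quasi-core
  v12 <- mk_votu("v12", 12L)
  v12$member_contigs <- list(sprintf("v12_c%02d", 1:12))
  sys12 <- species_systems(sprintf("v12_c%02d", 1:11), "anti_CRISPR")
  sys12$polarity <- "counter_defense"
  prs12 <- t(utils::combn(sys12$system_uid, 2))
  res12 <- call_hccds(v12, sys12,
                      list(v12 = links_between(prs12[, 1], prs12[, 2],
                                               "anti_CRISPR")))
  expect_equal(res12$blocks$presence_frac, 11 / 12)
  expect_identical(res12$hccds$classification, "quasi_core")
})
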