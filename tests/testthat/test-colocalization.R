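mk_mges <- function(start, end, cls = "prophage", genome = "g1") {
  if (!length(start)) {
    return(data.frame(mge_uid = character(0), genome_id = character(0),
                      replicon_id = character(0), start = integer(0),
                      end = integer(0), mge_class = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(mge_uid = sprintf("m%02d", seq_along(start)),
             genome_id = genome, replicon_id = paste0(genome, "_chr"),
             start = as.integer(start), end = as.integer(end),
             mge_class = cls, stringsAsFactors = FALSE)
}

test_that("overlapping MGEs are removed pairwise and chains drop entirely", {
  # integron inside a plasmid -> both removed
  m <- mk_mges(c(100, 200), c(1000, 400), c("plasmid", "integron_mobile"))
  res <- resolve_mge_overlaps(m)
  expect_identical(nrow(res$kept), 0L)
  expect_identical(nrow(res$removed), 2L)
  expect_equal(res$removed_fraction, 1)

  # disjoint prophages survive
  m2 <- mk_mges(c(100, 5000), c(1000, 6000))
  res2 <- resolve_mge_overlaps(m2)
  expect_identical(nrow(res2$kept), 2L)

  # chain A~B, B~C with A,C disjoint: all three removed (non-isolated
  # nodes of the pairwise-intersection graph)
  m3 <- mk_mges(c(100, 900, 1800), c(1000, 2000, 2500))
  expect_true(m3$end[1] < m3$start[3])
  res3 <- resolve_mge_overlaps(m3)
  expect_identical(nrow(res3$kept), 0L)

  # same coordinates on different replicons never interact
  m4 <- rbind(mk_mges(100, 1000, genome = "g1"),
              mk_mges(100, 1000, genome = "g2"))
  expect_identical(nrow(resolve_mge_overlaps(m4)$kept), 2L)
})

test_that("overlap resolution is order-independent and idempotent", {
  set.seed(3)
  for (trial in 1:10) {
    n <- 12
    s <- sample(1:5000, n)
    m <- mk_mges(s, s + sample(100:2000, n),
                 sample(c("plasmid", "prophage", "ICE"), n, TRUE))
    m$mge_uid <- sprintf("m%02d", 1:n)
    a <- resolve_mge_overlaps(m)
    b <- resolve_mge_overlaps(m[sample(n), ])
    expect_setequal(a$kept$mge_uid, b$kept$mge_uid)
    again <- resolve_mge_overlaps(a$kept)
    expect_identical(nrow(again$removed), 0L)
    expect_setequal(again$kept$mge_uid, a$kept$mge_uid)
  }
})

test_that("nested-only mode removes just the contained interval", {
  m <- mk_mges(c(100, 200), c(1000, 400), c("plasmid", "integron_mobile"))
  res <- resolve_mge_overlaps(m, defensome_config(mge_overlap_mode = "nested"))
  expect_identical(res$kept$mge_uid, "m01")
  expect_identical(res$removed$mge_uid, "m02")
})

test_that("context requires whole-system containment in a single MGE", {
  genes <- tiny_genes()
  sys <- tiny_systems()
  # gA Gabija components span genes 2-3: bp [1101, 2000] and [2101, 3000]
  mges <- mk_mges(1000, 3100, "prophage", "gA")
  ctx <- assign_context(sys, genes, mges)
  expect_identical(ctx$context[ctx$system_uid == "gA_gabija"], "prophage")
  expect_identical(ctx$mge_uid[ctx$system_uid == "gA_gabija"], "m01")
  expect_identical(ctx$context[ctx$system_uid == "gB_gabija"], "chromosome")

  # covering only the first component -> chromosome with partial flag
  mges2 <- mk_mges(1000, 2050, "ICE", "gA")
  ctx2 <- assign_context(sys, genes, mges2)
  expect_identical(ctx2$context[ctx2$system_uid == "gA_gabija"],
                   "chromosome")
  expect_true(ctx2$partial_overlap[ctx2$system_uid == "gA_gabija"])

  # no MGEs at all -> everything chromosomal
  ctx3 <- assign_context(sys, genes, mk_mges(integer(0), integer(0)))
  expect_true(all(ctx3$context == "chromosome"))

  # conservation: one context per instance
  expect_identical(nrow(ctx), nrow(sys))
})

test_that("densities are count/span with zero counts kept and zero spans
           NA", {
  manifest <- data.frame(species_id = "S", genome_id = c("g1", "g2"),
                         genome_size_bp = c(5e6L, 2e6L),
                         completeness_pct = 99, contamination_pct = 0,
                         stringsAsFactors = FALSE)
  sys <- data.frame(system_uid = c("s1", "s2"), genome_id = "g1",
                    replicon_id = "chr", family = "Gabija",
                    polarity = "defense", complete = TRUE,
                    stringsAsFactors = FALSE)
  sys$component_gene_ids <- list("a", "b")
  ctx <- data.frame(system_uid = c("s1", "s2"),
                    context = c("chromosome", "integron_sedentary"),
                    mge_uid = c(NA, "m1"), partial_overlap = FALSE,
                    stringsAsFactors = FALSE)
  mges <- data.frame(mge_uid = "m1", genome_id = "g1",
                     replicon_id = "chr", start = 1L, end = 500000L,
                     mge_class = "integron_sedentary",
                     stringsAsFactors = FALSE)
  d <- compute_densities(ctx, sys, empty_isl <- data.frame(
    genome_id = character(0)), manifest, mges)
  wg1 <- d[d$genome_id == "g1" & d$scope == "whole_genome", ]
  expect_equal(wg1$density_per_mb, 2 / 5)
  wg2 <- d[d$genome_id == "g2" & d$scope == "whole_genome", ]
  expect_equal(wg2$count, 0)
  expect_equal(wg2$density_per_mb, 0)  # null values included
  is1 <- d[d$genome_id == "g1" & d$scope == "integron_sedentary", ]
  expect_equal(is1$density_per_mb, 1 / 0.5)
  im2 <- d[d$genome_id == "g2" & d$scope == "integron_mobile", ]
  expect_true(is.na(im2$density_per_mb))  # zero span -> undefined
})

test_that("densities scale inversely with genome size at fixed counts", {
  manifest <- data.frame(species_id = "S",
                         genome_id = sprintf("g%d", 1:4),
                         genome_size_bp = as.integer(c(2, 4, 6, 8) * 1e6),
                         completeness_pct = 99, contamination_pct = 0,
                         stringsAsFactors = FALSE)
  sys <- data.frame(system_uid = sprintf("s%d", 1:4),
                    genome_id = sprintf("g%d", 1:4), replicon_id = "chr",
                    family = "Gabija", polarity = "defense",
                    complete = TRUE, stringsAsFactors = FALSE)
  sys$component_gene_ids <- as.list(letters[1:4])
  ctx <- data.frame(system_uid = sys$system_uid, context = "chromosome",
                    mge_uid = NA, partial_overlap = FALSE,
                    stringsAsFactors = FALSE)
  d <- compute_densities(ctx, sys, data.frame(genome_id = character(0)),
                         manifest)
  wg <- d[d$scope == "whole_genome", ]
  expect_true(all(diff(wg$density_per_mb) < 0))
})
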