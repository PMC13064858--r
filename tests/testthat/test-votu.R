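test_that("edge cases: identical pair, isolated contig, empty table", {
  ani <- data.frame(query_contig = "c1", target_contig = "c2",
                    ani_pct = 100, query_cov_frac = 1, target_cov_frac = 1,
                    stringsAsFactors = FALSE)
  v <- cluster_votus(c(c1 = 4000, c2 = 4000), ani)
  expect_identical(nrow(v), 1L)
  expect_identical(v$representative_contig, "c1")  # length tie: lexicographic
  expect_identical(v$member_contigs[[1]], c("c1", "c2"))

  v2 <- cluster_votus(c(c1 = 4000, lonely = 3000), ani[0, ])
  expect_identical(nrow(v2), 2L)
  expect_identical(sort(v2$n_members), c(1L, 1L))

  expect_error(cluster_votus(c(c1 = 10, c2 = 10),
                             transform(ani, ani_pct = 105)),
               "outside")
})

test_that("the member, not the centroid, must be covered >= 85%", {
  # c_small aligns fully over itself but covers only half of c_big
  ani <- data.frame(query_contig = "c_small", target_contig = "c_big",
                    ani_pct = 99, query_cov_frac = 1.0,
                    target_cov_frac = 0.5, stringsAsFactors = FALSE)
  v <- cluster_votus(c(c_big = 8000, c_small = 4000), ani)
  expect_identical(nrow(v), 1L)
  # reversed orientation in the table gives the same clustering
  ani_rev <- data.frame(query_contig = "c_big", target_contig = "c_small",
                        ani_pct = 99, query_cov_frac = 0.5,
                        target_cov_frac = 1.0, stringsAsFactors = FALSE)
  v2 <- cluster_votus(c(c_big = 8000, c_small = 4000), ani_rev)
  expect_identical(v2$n_members, 2L)
  # a member covered only 50% does not join
  ani_low <- transform(ani, query_cov_frac = 0.5, target_cov_frac = 1.0)
  v3 <- cluster_votus(c(c_big = 8000, c_small = 4000), ani_low)
  expect_identical(nrow(v3), 2L)
})

test_that("hand-built 5-contig table matches the literal greedy oracle", {
  lens <- c(c1 = 9000, c2 = 8000, c3 = 7000, c4 = 6000, c5 = 5000)
  ani <- data.frame(
    query_contig = c("c2", "c3", "c4", "c5"),
    target_contig = c("c1", "c1", "c3", "c4"),
    ani_pct = c(98, 96, 99, 97),
    query_cov_frac = c(0.95, 0.70, 0.90, 0.99),
    target_cov_frac = c(0.90, 0.95, 0.85, 0.90),
    stringsAsFactors = FALSE)
  # c2 joins c1; c3 fails member coverage (0.70 < 0.85) so it seeds its
  # own cluster and captures c4; c5's only link is to c4, which is not a
  # centroid, so c5 is a singleton
  got <- cluster_votus(lens, ani)
  expect_identical(got$representative_contig, c("c1", "c3", "c5"))
  expect_identical(got$member_contigs,
                   list(c("c1", "c2"), c("c3", "c4"), "c5"))
  oracle <- votu_oracle(lens, ani)
  expect_identical(got$member_contigs, lapply(oracle, `[[`, "members"))
  expect_identical(got$representative_contig,
                   vapply(oracle, `[[`, character(1), "rep"))
})

test_that("clustering equals the greedy oracle on random sparse tables", {
  set.seed(404)
  for (trial in 1:50) {
    n <- sample(3:12, 1)
    ids <- sprintf("c%02d", seq_len(n))
    lens <- setNames(sample(2000:9999, n), ids)
    ani <- random_ani_table(ids)
    got <- cluster_votus(lens, ani)
    oracle <- votu_oracle(lens, ani)
    expect_identical(got$member_contigs, lapply(oracle, `[[`, "members"))
    # partition property
    members <- unlist(got$member_contigs)
    expect_setequal(members, ids)
    expect_false(any(duplicated(members)))
    # determinism under row shuffling
    if (nrow(ani) > 1) {
      got2 <- cluster_votus(lens, ani[sample(nrow(ani)), ])
      expect_identical(got$member_contigs, got2$member_contigs)
    }
  }
})

test_that("all-identical and fully-sparse limits behave as stated", {
  ids <- sprintf("c%d", 1:6)
  lens <- setNames(rep(5000, 6) + 6:1, ids)
  prs <- t(utils::combn(ids, 2))
  full <- data.frame(query_contig = prs[, 1], target_contig = prs[, 2],
                     ani_pct = 100, query_cov_frac = 1,
                     target_cov_frac = 1, stringsAsFactors = FALSE)
  expect_identical(nrow(cluster_votus(lens, full)), 1L)
  expect_identical(nrow(cluster_votus(lens, full[0, ])), 6L)
})

test_that("builtin ANI backend is exact on substitution-only divergence", {
  set.seed(55)
  bases <- c("A", "C", "G", "T")
  s <- paste(sample(bases, 10000, TRUE), collapse = "")
  hit <- compute_contig_ani(s, s)
  expect_equal(hit$ani_pct, 100)
  expect_equal(hit$query_cov_frac, 1)

  # 2% planted substitutions -> ani approx 98 within 0.5
  v <- strsplit(s, "")[[1]]
  pos <- sample(10000, 200)
  v[pos] <- vapply(v[pos], function(x) sample(setdiff(bases, x), 1), "")
  hit2 <- compute_contig_ani(s, paste(v, collapse = ""))
  expect_lt(abs(hit2$ani_pct - 98), 0.5)

  # 40% substring as target: full target coverage, 40% query coverage
  sub <- substr(s, 2001, 2000 + 4000)
  hit3 <- compute_contig_ani(s, sub)
  expect_equal(hit3$target_cov_frac, 1.0)
  expect_equal(hit3$query_cov_frac, 0.4)
  expect_equal(hit3$ani_pct, 100)

  expect_error(compute_contig_ani("", s), "empty")
})
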