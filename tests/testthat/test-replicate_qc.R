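rep_fixture <- function() fixture_suite()$repro

test_that("replicate pairs enumerate g*(g-1)/2 pairs per group", {
  m <- rand_matrix(5, 5)
  sheet <- tiny_sheet(m$samples,
                      replicate_group = c("g1", "g1", "g1", "g2", NA))
  pairs <- replicate_pairs(sheet, m)
  expect_equal(nrow(pairs), 3L)   # triple -> 3 pairs; singleton g2 -> none
  expect_false(any(duplicated(paste(pairs$sample_a, pairs$sample_b))))
})

test_that("locus reproducibility counts identical over comparable pairs", {
  fx <- rep_fixture()
  pairs <- replicate_pairs(fx$sheet, fx$matrix)
  expect_equal(unname(locus_reproducibility(fx$matrix, pairs)),
               fx$expect$reproducibility)

  # hand-counted case with a missing member: (AA,AB),(AA,AA),(miss,AA)
  g <- rbind(c(0L, 0L, NA, 1L, 0L, 0L))
  m <- genotype_matrix(g, data.frame(contig = "c", pos = 10L,
                                     ref = "A", alt = "G"),
                       c("a1", "a2", "a3", "b1", "b2", "b3"))
  sheet <- tiny_sheet(m$samples,
                      replicate_group = rep(c("i1", "i2", "i3"), 2))
  expect_equal(unname(locus_reproducibility(
    m, replicate_pairs(sheet, m))), 0.5)

  # zero comparable pairs -> NA, never 1.0
  g2 <- rbind(c(NA, 0L), c(0L, 0L))
  m2 <- genotype_matrix(g2, data.frame(contig = "c", pos = c(10L, 20L),
                                       ref = "A", alt = "G"), c("x", "x_r"))
  sheet2 <- tiny_sheet(m2$samples, replicate_group = c("x", "x"))
  r <- locus_reproducibility(m2, replicate_pairs(sheet2, m2))
  expect_true(is.na(r[1]) && r[2] == 1)
  expect_error(locus_reproducibility(m2, replicate_pairs(sheet2, m2)[0, ]),
               "empty")
})

test_that("reproducibility filter is strict at the boundary, keeps undefined", {
  fx <- rep_fixture()
  pairs <- replicate_pairs(fx$sheet, fx$matrix)
  res <- filter_reproducibility(fx$matrix, pairs, 0.85)
  expect_setequal(res$entry$removed_ids[[1]], fx$expect$removed_at_0.85)

  # all-concordant matrix: nothing removed
  g <- matrix(rep(c(0L, 1L, 2L), 4), nrow = 3, ncol = 4)
  m <- genotype_matrix(g, data.frame(contig = "c", pos = c(1L, 2L, 3L) * 10L,
                                     ref = "A", alt = "G"),
                       c("a", "a_r", "b", "b_r"))
  sheet <- tiny_sheet(m$samples, replicate_group = c("a", "a", "b", "b"))
  expect_equal(filter_reproducibility(
    m, replicate_pairs(sheet, m), 0.85)$entry$loci_removed, 0L)
})

test_that("error rate pools discordant over comparable calls", {
  fx <- rep_fixture()
  pairs <- replicate_pairs(fx$sheet, fx$matrix)
  # 0 + 3 + 10 discordant of 60 comparable
  expect_equal(error_rate(fx$matrix, pairs), 13 / 60)
  # identity: pooled error = 1 - weighted mean reproducibility
  r <- locus_reproducibility(fx$matrix, pairs)
  expect_equal(error_rate(fx$matrix, pairs), 1 - mean(r))  # equal weights here
  set.seed(17)
  sim <- simulate_dataset(sim_config(n_loci = 200, n_per_pop = c(20, 20),
                                     n_replicate_pairs = 8, flip_prob = 0.1,
                                     seed = 17))
  pr <- replicate_pairs(sim$sheet, sim$matrix)
  er <- error_rate(sim$matrix, pr)
  expect_equal(er, sim$truth$realized$replicate_discordance)
  # post-filter error never exceeds pre-filter error
  post <- filter_reproducibility(sim$matrix, pr, 0.85)$matrix
  expect_lte(error_rate(post, pr), er)
})

test_that("deduplication keeps the least-missing member deterministically", {
  g <- rbind(c(0L, 0L, 1L), c(NA, 0L, 1L), c(NA, 0L, NA))
  m <- genotype_matrix(g, data.frame(contig = "c", pos = c(1:3) * 10L,
                                     ref = "A", alt = "G"),
                       c("s1", "s2", "t1"))
  sheet <- tiny_sheet(m$samples, replicate_group = c("g1", "g1", NA))
  dd <- deduplicate_replicates(m, sheet)
  expect_setequal(dd$samples, c("s2", "t1"))        # s1 has 2 missing
  # explicit keep-list overrides the ranking
  dd2 <- deduplicate_replicates(m, sheet, keep = "s1")
  expect_setequal(dd2$samples, c("s1", "t1"))
  # no replicate groups: identity
  plain <- tiny_sheet(m$samples)
  expect_identical(deduplicate_replicates(m, plain)$samples, m$samples)
  # sample count drops by sum(group size - 1)
  sim <- simulate_dataset(sim_config(n_loci = 50, n_per_pop = c(10, 10),
                                     n_replicate_pairs = 6, seed = 3))
  dd3 <- deduplicate_replicates(sim$matrix, sim$sheet)
  expect_equal(n_samples(dd3), n_samples(sim$matrix) - 6L)
})
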