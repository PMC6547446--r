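mk <- function(g, dp_r = NULL, dp_a = NULL, samples = NULL) {
  g <- as.matrix(g)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(g)))
  genotype_matrix(g, data.frame(contig = "c1", pos = seq_len(nrow(g)) * 100L,
                                ref = "A", alt = "G"), samples, dp_r, dp_a)
}

test_that("call-rate filter boundary is inclusive", {
  g <- rbind(c(rep(0L, 7), rep(NA, 3)),    # 7/10 called
             c(rep(0L, 6), rep(NA, 4)))    # 6/10 called
  res <- filter_call_rate(mk(g), 0.70)
  expect_equal(res$matrix$loci$locus_id, "c1:100")
  expect_equal(res$entry$loci_removed, 1L)
  expect_equal(filter_call_rate(mk(g), 0)$entry$loci_removed, 0L)
})

test_that("MAF filter matches an explicit allele tally", {
  g <- rbind(c(rep(0L, 9), 1L),       # MAF 0.05 -> retained at 0.01
             rep(0L, 10))             # monomorphic -> removed
  res <- filter_maf(mk(g), 0.01)
  expect_equal(res$matrix$loci$locus_id, "c1:100")
  set.seed(21)
  for (i in 1:5) {
    m <- rand_matrix(40, 15, depth = FALSE)
    expect_equal(unname(locus_maf(m)), unname(oracle_maf(m$geno)))
  }
})

test_that("max-het filter removes heterozygosity excess", {
  g <- rbind(c(rep(1L, 8), 0L, 2L),   # 8/10 het -> removed at 0.70
             c(rep(1L, 7), 0L, 2L, 0L))  # 7/10 het -> retained
  res <- filter_max_het(mk(g), 0.70)
  expect_equal(res$entry$loci_removed, 1L)
  expect_equal(filter_max_het(mk(g), 1.0)$entry$loci_removed, 0L)
})

test_that("allele-depth filter means over carriers, no-carrier alleles fail", {
  # locus 1: single het (5,5) -> retained at 2.5
  # locus 2: alt carriers depths 2,2,2 -> mean 2.0 -> removed
  # locus 3: no alt carriers -> fails alt criterion
  g <- rbind(c(1L, 0L, 0L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  dp_r <- rbind(c(5L, 9L, 9L), c(6L, 6L, 6L), c(9L, 9L, 9L))
  dp_a <- rbind(c(5L, 0L, 0L), c(2L, 2L, 2L), c(0L, 0L, 0L))
  res <- filter_allele_depth(mk(g, dp_r, dp_a), 2.5)
  expect_equal(res$matrix$loci$locus_id, "c1:100")
  md <- locus_mean_allele_depth(mk(g, dp_r, dp_a))
  expect_equal(unname(md[2, ]), c(6, 2))
})

test_that("coverage-diff filter uses the symmetric percentage formula", {
  fx <- fixture_suite()$covdiff
  expect_equal(unname(locus_coverage_diff(fx$matrix)),
               fx$expect$coverage_diff)
  res <- filter_coverage_diff(fx$matrix, 80)
  expect_equal(res$entry$removed_ids[[1]], fx$expect$removed_at_80)
  # zero-het loci pass: no evidence of imbalance
  g <- rbind(c(0L, 2L))
  dp_r <- rbind(c(20L, 0L)); dp_a <- rbind(c(0L, 1L))
  expect_equal(filter_coverage_diff(mk(g, dp_r, dp_a), 80)$entry$loci_removed,
               0L)
})

test_that("sex-linkage rule flags hom-male/het-female loci only", {
  sheet <- tiny_sheet(sprintf("s%02d", 1:8),
                      sex = rep(c("female", "male"), each = 4))
  g <- rbind(c(1L, 1L, 1L, 0L, 0L, 2L, 0L, 2L),  # flagged: 3 het F, 0 het M
             c(1L, 1L, 1L, 0L, 1L, 2L, 0L, 2L),  # het male -> not flagged
             c(0L, 0L, 0L, 0L, 0L, 2L, 0L, 2L),  # no het at all -> not
             c(1L, 0L, 0L, 0L, NA, NA, NA, NA))  # no called male -> not
  res <- filter_sex_linked(mk(g), sheet, "XY")
  expect_equal(res$flagged, "c1:100")
  expect_equal(res$entry$loci_removed, 1L)
  # ZW reverses the heterogametic sex
  res_zw <- filter_sex_linked(mk(g), sheet, "ZW")
  expect_false("c1:100" %in% res_zw$flagged)
  expect_error(filter_sex_linked(mk(g), tiny_sheet(sprintf("s%02d", 1:8))),
               "both sexes")
})

test_that("thinning chains SNPs by single linkage and is seed-deterministic", {
  m <- genotype_matrix(matrix(0L, 3, 2),
                       data.frame(contig = "c1", pos = c(100L, 150L, 400L),
                                  ref = "A", alt = "G"), c("s1", "s2"))
  res <- thin_one_snp_per_locus(m, window = 77, seed = 9)
  expect_equal(n_loci(res$matrix), 2L)            # {100,150} + {400}
  expect_true("c1:400" %in% res$matrix$loci$locus_id)
  res2 <- thin_one_snp_per_locus(m, window = 77, seed = 9)
  expect_identical(res$matrix$loci, res2$matrix$loci)
  # all SNPs farther apart than the window: identity
  set.seed(2)
  far <- rand_matrix(20, 5)                        # spacing 100 > window 77
  expect_equal(n_loci(thin_one_snp_per_locus(far, 77, 1)$matrix), 20L)
})

test_that("filters are idempotent, monotone in threshold, call-preserving", {
  set.seed(31)
  m <- rand_matrix(80, 12)
  cases <- list(
    list(fn = filter_call_rate, th = c(0.3, 0.7)),
    list(fn = filter_maf, th = c(0.01, 0.1)),
    list(fn = filter_max_het, th = c(0.7, 0.5)),
    list(fn = filter_allele_depth, th = c(2.5, 5)))
  for (cs in cases) {
    loose <- cs$fn(m, cs$th[1])
    again <- cs$fn(loose$matrix, cs$th[1])
    expect_equal(again$entry$loci_removed, 0L)     # idempotent
    tight <- cs$fn(m, cs$th[2])
    # tighter threshold never retains a locus the looser one removed
    expect_true(all(tight$matrix$loci$locus_id %in%
                      loose$matrix$loci$locus_id))
    # retained + removed partition the input exactly
    expect_setequal(c(loose$matrix$loci$locus_id,
                      loose$entry$removed_ids[[1]]), m$loci$locus_id)
    # calls never altered
    kept <- m$loci$locus_id %in% loose$matrix$loci$locus_id
    expect_identical(loose$matrix$geno, m$geno[kept, , drop = FALSE])
  }
})

test_that("run_filter_chain chains report entries consistently", {
  set.seed(41)
  m <- rand_matrix(100, 16)
  sheet <- tiny_sheet(m$samples, sex = rep_len(c("female", "male"), 16))
  res <- run_filter_chain(m, sheet)
  rep <- res$report
  expect_equal(rep$loci_after, rep$loci_before - rep$loci_removed)
  expect_equal(rep$loci_before[-1], rep$loci_after[-nrow(rep)])
  expect_equal(n_loci(res$matrix),
               n_loci(m) - sum(rep$loci_removed))
  # empty order is the identity
  id <- run_filter_chain(m, order = character(0))
  expect_identical(id$matrix$geno, m$geno)
  # unavailable stages: skipped by default, strict errors on request
  nodepth <- rand_matrix(10, 4, depth = FALSE)
  sk <- run_filter_chain(nodepth, order = c("allele_depth", "maf"))
  expect_equal(sk$report$threshold[1], "skipped")
  expect_error(run_filter_chain(nodepth, order = "allele_depth",
                                skip_unavailable = FALSE),
               "allele_depth")
})

test_that("filter config file parsing and validation", {
  f <- tempfile()
  writeLines(c("call_rate_min = 0.30   # relaxed genotyping rate",
               "maf_min = 0.05", "sex_system = ZW"), f)
  cfg <- read_filter_config(f)
  expect_equal(cfg$call_rate_min, 0.30)
  expect_equal(cfg$maf_min, 0.05)
  expect_equal(cfg$sex_system, "ZW")
  writeLines("nonsense = 1", f)
  expect_error(read_filter_config(f), "unknown config keys")
  expect_error(filter_config(maf_min = 0.9))
})
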