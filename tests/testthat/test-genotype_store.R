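write_lines_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                            ad = TRUE) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (ad)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

test_that("read_vcf ingests biallelic SNPs and excludes the rest, logged", {
  path <- write_lines_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/0:10,0\t0/1:6,5",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD\t1/1:0,9\t1|0:4,4",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT:AD\t0/1:4,5,0\t0/2:3,0,4",
    "chr1\t400\t.\tT\tTA\t.\tPASS\t.\tGT:AD\t0/0:8,0\t0/1:4,4",
    "chr2\t50\t.\tG\tC\t.\tPASS\t.\tGT:AD\t./.:.\t0/.:3,1"))
  m <- read_vcf(path)
  expect_equal(n_loci(m), 3L)           # triallelic + indel excluded
  expect_equal(n_samples(m), 2L)
  log <- attr(m, "ingest_log")
  expect_equal(log$count[log$reason == "multiallelic"], 1L)
  expect_equal(log$count[log$reason == "non_snp"], 1L)
  # retained + excluded = input records
  expect_equal(n_loci(m) + sum(log$count), attr(m, "n_input_records"))
  # states: phased 1|0 is het; ./. and half-call 0/. are missing
  expect_equal(unname(m$geno[, "s1"]), c(0L, 2L, NA))
  expect_equal(unname(m$geno[, "s2"]), c(1L, 1L, NA))
  # depths follow AD, missing cells NA
  expect_equal(unname(m$dp_ref[1, ]), c(10L, 6L))
  expect_equal(unname(m$dp_alt[2, ]), c(9L, 4L))
  expect_true(all(is.na(m$dp_ref[3, ])))
  expect_true(has_depth(m))
})

test_that("read_vcf errors usefully on missing GT and unsorted records", {
  nogt <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t10"), nogt)
  expect_error(read_vcf(nogt), "GT")

  unsorted <- write_lines_vcf(c(
    "chr1\t500\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/0:9,0\t0/0:9,0",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/0:9,0\t0/0:9,0"))
  expect_error(read_vcf(unsorted), "chr1:100")
})

test_that("AD-free VCF yields a depth-free matrix and depth filters refuse", {
  path <- write_lines_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1"), ad = FALSE)
  m <- read_vcf(path)
  expect_false(has_depth(m))
  expect_error(filter_allele_depth(m), "depth-free")
  expect_error(filter_coverage_diff(m), "depth-free")
})

test_that("VCF write/read round-trips random matrices exactly", {
  set.seed(11)
  for (depth in c(TRUE, FALSE)) {
    m <- rand_matrix(50, 20, depth = depth)
    f <- tempfile(fileext = ".vcf")
    write_vcf(m, f)
    m2 <- read_vcf(f)
    expect_identical(m2$geno, m$geno)
    expect_identical(m2$loci, m$loci)
    expect_identical(m2$samples, m$samples)
    if (depth) {
      expect_identical(m2$dp_ref, m$dp_ref)
      expect_identical(m2$dp_alt, m$dp_alt)
    }
  }
})

test_that("write_vcf is byte-stable and handles the empty matrix", {
  set.seed(3)
  m <- rand_matrix(3, 4)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(m, f1); write_vcf(m, f2)
  expect_identical(readLines(f1), readLines(f2))

  empty <- subset_loci(m, integer(0))
  fe <- tempfile(fileext = ".vcf")
  write_vcf(empty, fe)
  m0 <- read_vcf(fe)
  expect_equal(n_loci(m0), 0L)
  expect_equal(m0$samples, m$samples)
})

test_that("missing_fraction arithmetic and reordering invariance", {
  g <- matrix(c(0L, 1L, 2L, NA, 0L, 1L, 2L, 0L, 1L, 2L), nrow = 5)
  m <- genotype_matrix(g, data.frame(contig = "c", pos = 1:5 * 10L,
                                     ref = "A", alt = "C"),
                       c("s1", "s2"))
  expect_equal(missing_fraction(m)$dataset, 0.1)
  expect_equal(sum(missing_fraction(m)$per_sample) / 2, 0.1)

  set.seed(5)
  r <- rand_matrix(30, 10)
  shuf <- subset_samples(r, sample(n_samples(r)))
  expect_equal(missing_fraction(shuf)$dataset,
               missing_fraction(r)$dataset)
})

test_that("sample sheet round-trip and validation", {
  sheet <- tiny_sheet(c("a", "b", "c"), population = c("p1", "p1", "p2"),
                      sex = c("female", "male", "unknown"),
                      replicate_group = c("g1", "g1", NA))
  f <- tempfile(fileext = ".tsv")
  write_sample_sheet(sheet, f)
  back <- read_sample_sheet(f)
  expect_equal(as.data.frame(back), as.data.frame(sheet))
  expect_error(sample_sheet(data.frame(sample = c("a", "a"),
                                       population = "p")),
               "duplicate")
  expect_error(
    sample_sheet(data.frame(sample = "a", population = "p", sex = "boy")),
    "sex")
})
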