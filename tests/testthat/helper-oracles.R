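# Shared helpers: small random matrices and independent brute-force
# oracles kept deliberately scalar/naive, so they stay independent of
# the vectorised implementation paths they check.

rand_matrix <- function(n_loci, n_samples, miss = 0.1, depth = TRUE,
                        prefix = "s") {
  g <- matrix(sample(c(0:2, NA), n_loci * n_samples, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, miss) / (0.9 + miss)),
              n_loci, n_samples)
  dp_r <- dp_a <- NULL
  if (depth) {
    dp_r <- matrix(rpois(n_loci * n_samples, 6), n_loci, n_samples)
    dp_a <- matrix(rpois(n_loci * n_samples, 6), n_loci, n_samples)
    dp_r[is.na(g)] <- NA; dp_a[is.na(g)] <- NA
  }
  genotype_matrix(
    g,
    data.frame(contig = "chr1", pos = seq_len(n_loci) * 100L,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    sprintf("%s%03d", prefix, seq_len(n_samples)), dp_r, dp_a)
}

# scalar transcription of Weir & Cockerham (1984), ratio of summed
# components; geno_by_pop: list over loci, each a list of per-pop
# dose vectors (NA = missing)
oracle_wc_theta <- function(geno_by_pop) {
  A <- B <- C <- 0
  for (loc in geno_by_pop) {
    r <- length(loc)
    n <- sapply(loc, function(x) sum(!is.na(x)))
    if (any(n < 2)) next
    p <- sapply(loc, function(x) sum(x, na.rm = TRUE) /
                  (2 * sum(!is.na(x))))
    h <- sapply(loc, function(x) mean(x[!is.na(x)] == 1))
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

oracle_theta_from_matrix <- function(m, pop) {
  loc <- lapply(seq_len(n_loci(m)), function(i)
    split(m$geno[i, ], pop))
  oracle_wc_theta(loc)
}

# cell-by-cell concordance tally (same polarity assumed)
oracle_concordance <- function(ga, gb) {
  n_comp <- conc <- hh <- hhet <- heth <- 0L
  for (i in seq_len(nrow(ga))) for (j in seq_len(ncol(ga))) {
    a <- ga[i, j]; b <- gb[i, j]
    if (is.na(a) || is.na(b)) next
    n_comp <- n_comp + 1L
    if (a == b) conc <- conc + 1L
    else if (a != 1 && b != 1) hh <- hh + 1L
    else if (a != 1 && b == 1) hhet <- hhet + 1L
    else heth <- heth + 1L
  }
  list(n = n_comp, concordant = conc, hom_hom = hh, hom_het = hhet,
       het_hom = heth)
}

# naive per-locus MAF by explicit allele tally
oracle_maf <- function(g) {
  apply(g, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(0)
    alt <- sum(row)
    p <- alt / (2 * length(row))
    min(p, 1 - p)
  })
}

tiny_sheet <- function(samples, population = "p1", sex = "unknown",
                       replicate_group = NA_character_) {
  sample_sheet(data.frame(sample = samples, population = population,
                          sex = sex, replicate_group = replicate_group,
                          stringsAsFactors = FALSE))
}
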