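# Synthetic multi-sample SNP datasets with controlled population
# structure (Balding-Nichols), HWE genotypes, Poisson allelic depths,
# technical replicates with a known discordance rate, and planted
# filter-failure classes. Every planted quantity is recorded in a
# truth ledger so generator and estimator can be closed against each
# other in tests.

#' Simulation configuration
#'
#' The stated world of the generator. Defaults emulate a typical
#' reduced-representation dataset: two populations of 50 diploid
#' samples, 1000 biallelic SNPs with ancestral ALT frequency uniform
#' on [0.05, 0.5], Balding-Nichols differentiation at F_ST = 0.10,
#' ~13x mean read depth (Poisson), 13.4\% missing data, and a 6\%
#' per-call replicate discordance rate when replicate pairs are
#' requested — magnitudes typical of RADseq/DArTseq studies.
#'
#' @param n_loci number of SNP loci.
#' @param n_per_pop integer vector of samples per population
#'   (optionally named with population labels).
#' @param target_fst Balding-Nichols differentiation parameter.
#' @param maf_range uniform range of the ancestral ALT-allele
#'   frequency.
#' @param mean_depth Poisson mean total read depth per called genotype.
#' @param missing_rate per-cell missing probability.
#' @param flip_prob per-call probability that a replicate's called
#'   genotype is flipped to a random different state.
#' @param n_replicate_pairs number of samples duplicated as technical
#'   replicates.
#' @param n_sex_linked,n_low_call,n_high_het,n_imbalance,n_low_depth,n_low_maf
#'   planted counts of loci failing, respectively, the sex-linkage,
#'   call-rate, max-heterozygosity, coverage-difference, allelic-depth
#'   and MAF filters (disjoint classes; their sum must not exceed
#'   `n_loci`).
#' @param low_call_rate call rate of planted low-call loci.
#' @param high_het_rate heterozygous fraction of planted high-het
#'   (paralog-like) loci.
#' @param imbalance_split REF share of het read depth at planted
#'   allele-imbalanced loci (0.77 gives a coverage difference of
#'   ~108\%, failing the 80\% cut-off while each allele's mean depth
#'   stays above 2.5x).
#' @param low_depth_mean mean total depth at planted low-depth loci.
#' @param locus_spacing bp between consecutive SNPs (all on one contig;
#'   the default 1000 exceeds any realistic read length, so thinning
#'   keeps everything unless clusters are planted deliberately).
#' @param deterministic_depth use fixed (rounded) depths instead of
#'   Poisson draws — planted depth classes then fail or pass their
#'   filters exactly.
#' @param seed integer RNG seed; a fixed seed gives byte-identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 1000L, n_per_pop = c(50L, 50L),
                       target_fst = 0.10, maf_range = c(0.05, 0.5),
                       mean_depth = 13, missing_rate = 0.134,
                       flip_prob = 0.06, n_replicate_pairs = 0L,
                       n_sex_linked = 0L, n_low_call = 0L,
                       n_high_het = 0L, n_imbalance = 0L,
                       n_low_depth = 0L, n_low_maf = 0L,
                       low_call_rate = 0.4, high_het_rate = 0.95,
                       imbalance_split = 0.77, low_depth_mean = 2,
                       locus_spacing = 1000L,
                       deterministic_depth = FALSE, seed = 1L) {
  if (is.null(names(n_per_pop)))
    names(n_per_pop) <- paste0("pop", seq_along(n_per_pop))
  cfg <- as.list(environment())
  planted <- n_sex_linked + n_low_call + n_high_het + n_imbalance +
    n_low_depth + n_low_maf
  if (planted > n_loci)
    stop("planted counts (", planted, ") exceed n_loci (", n_loci, ")")
  stopifnot(target_fst >= 0, target_fst < 1,
            missing_rate >= 0, missing_rate < 1,
            flip_prob >= 0, flip_prob <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            n_replicate_pairs <= sum(n_per_pop))
  class(cfg) <- "sim_config"
  cfg
}

# Balding-Nichols population frequency draws around ancestral q
bn_freq <- function(q, fst) {
  if (fst < 1e-9) return(q)
  rbeta(length(q), q * (1 - fst) / fst, (1 - q) * (1 - fst) / fst)
}

sim_depths <- function(state, lambda, split, deterministic) {
  # state: integer vector of doses (0/1/2, no NA); returns cbind(ref, alt)
  n <- length(state)
  if (deterministic) {
    lr <- as.integer(round(lambda))
    ref <- ifelse(state == 0L, lr,
                  ifelse(state == 2L, 0L, as.integer(round(lambda * split))))
    alt <- ifelse(state == 0L, 0L,
                  ifelse(state == 2L, lr,
                         lr - as.integer(round(lambda * split))))
  } else {
    total <- rpois(n, lambda)
    alt <- ifelse(state == 0L, 0L,
                  ifelse(state == 2L, total,
                         rbinom(n, total, 1 - split)))
    ref <- total - alt
  }
  cbind(ref, alt)
}

#' Simulate a synthetic SNP dataset
#'
#' Draws a dataset under the model described in [sim_config()]:
#' ancestral frequencies from the MAF distribution, per-population
#' frequencies from the Balding-Nichols Beta, genotypes in
#' Hardy-Weinberg proportions within populations, depths Poisson with
#' a binomial REF/ALT split for heterozygotes, planted filter-failure
#' locus classes, and technical replicates whose called genotypes are
#' flipped to a random different state with the configured
#' probability.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a `genotype_matrix`), `sheet` (a
#'   `sample_sheet`) and `truth`, a ledger recording every planted
#'   locus class and realised rates (missingness, replicate
#'   discordance, per-population allele frequencies).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  L <- cfg$n_loci
  pops <- rep(names(cfg$n_per_pop), cfg$n_per_pop)
  n_base <- length(pops)
  ids <- sprintf("%s_s%03d", pops, unlist(lapply(cfg$n_per_pop, seq_len)))
  sex <- unlist(lapply(cfg$n_per_pop, function(n)
    rep_len(c("female", "male"), n)))

  # disjoint planted locus classes
  class_sizes <- c(sex_linked = cfg$n_sex_linked, low_call = cfg$n_low_call,
                   high_het = cfg$n_high_het, imbalance = cfg$n_imbalance,
                   low_depth = cfg$n_low_depth, low_maf = cfg$n_low_maf)
  planted_idx <- sample.int(L, sum(class_sizes))
  classes <- split(planted_idx, rep(names(class_sizes), class_sizes))
  locus_class <- rep("normal", L)
  for (cl in names(classes)) locus_class[classes[[cl]]] <- cl

  q_anc <- runif(L, cfg$maf_range[1], cfg$maf_range[2])
  q_pop <- vapply(names(cfg$n_per_pop),
                  function(p) bn_freq(q_anc, cfg$target_fst),
                  numeric(L))

  geno <- matrix(NA_integer_, L, n_base)
  for (j in seq_along(names(cfg$n_per_pop))) {
    cols <- which(pops == names(cfg$n_per_pop)[j])
    geno[, cols] <- rbinom(L * length(cols), 2L,
                           rep(q_pop[, j], length(cols)))
  }
  protected <- matrix(FALSE, L, n_base)   # cells exempt from missingness

  is_female <- sex == "female"
  # Planted classes other than sex_linked must not trip the sex-linkage
  # rule (zero heterogametic hets + >=1 homogametic het), or the filter
  # chain would remove them at the wrong stage. Singleton/guaranteed
  # heterozygotes are therefore placed in the heterogametic sex (XY
  # males here), which the rule can never flag.
  pick_het_carrier <- function() {
    males <- which(!is_female)
    if (length(males)) males[sample.int(length(males), 1L)]
    else sample.int(n_base, 1L)
  }
  for (i in classes$sex_linked) {
    # X-like under XY: hemizygous males typed as homozygous diploid
    geno[i, !is_female] <- 2L * rbinom(sum(!is_female), 1L, q_anc[i])
    geno[i, is_female] <- rbinom(sum(is_female), 2L, q_anc[i])
    fem <- which(is_female)
    if (!any(geno[i, fem] == 1L)) geno[i, sample(fem, 1L)] <- 1L
    keep_one <- fem[which(geno[i, fem] == 1L)[1]]
    protected[i, keep_one] <- TRUE
  }
  for (i in classes$high_het) {
    geno[i, ] <- 0L
    geno[i, sample.int(n_base, round(cfg$high_het_rate * n_base))] <- 1L
  }
  for (i in classes$low_maf) {
    geno[i, ] <- 0L
    carrier <- pick_het_carrier()
    geno[i, carrier] <- 1L
    protected[i, carrier] <- TRUE
  }
  for (i in classes$low_call) {
    carrier <- pick_het_carrier()
    geno[i, carrier] <- 1L
    protected[i, carrier] <- TRUE
  }
  for (i in classes$imbalance) {
    # imbalance is only observable in hets; guarantee a heterogametic one
    carrier <- pick_het_carrier()
    geno[i, carrier] <- 1L
    protected[i, carrier] <- TRUE
  }

  # missingness: base rate everywhere, planted low-call loci heavier
  miss_p <- matrix(cfg$missing_rate, L, n_base)
  miss_p[classes$low_call, ] <- 1 - cfg$low_call_rate
  miss <- matrix(runif(L * n_base) < miss_p, L, n_base) & !protected
  geno[miss] <- NA_integer_

  # technical replicates: duplicate, then flip called genotypes
  rep_of <- sample(ids, cfg$n_replicate_pairs)
  n_flips <- 0L; n_comparable <- 0L
  rep_cols <- NULL
  is_sex_locus <- locus_class == "sex_linked"
  if (cfg$n_replicate_pairs > 0) {
    rep_cols <- matrix(NA_integer_, L, length(rep_of))
    for (k in seq_along(rep_of)) {
      base_col <- match(rep_of[k], ids)
      col <- geno[, base_col]
      called <- which(!is.na(col))
      n_comparable <- n_comparable + length(called)
      flip <- called[runif(length(called)) < cfg$flip_prob]
      n_flips <- n_flips + length(flip)
      if (length(flip)) {
        # hemizygous (heterogametic) individuals at sex-linked loci can
        # only be miscalled as the other homozygote, never heterozygous
        hemi <- is_sex_locus[flip] & !is_female[base_col]
        shift <- sample(c(1L, 2L), length(flip), replace = TRUE)
        col[flip] <- ifelse(hemi, 2L - col[flip],
                            (col[flip] + shift) %% 3L)
      }
      rep_cols[, k] <- col
    }
  }

  all_geno <- cbind(geno, rep_cols)
  all_ids <- c(ids, if (length(rep_of)) paste0(rep_of, "_rep"))
  base_row <- match(rep_of, ids)
  sheet <- sample_sheet(data.frame(
    sample = all_ids,
    population = c(pops, pops[base_row]),
    sex = c(sex, sex[base_row]),
    replicate_group = c(ifelse(ids %in% rep_of, ids, NA_character_),
                        rep_of),
    stringsAsFactors = FALSE))

  # depths from final states, class-dependent
  dp_ref <- dp_alt <- matrix(NA_integer_, L, ncol(all_geno))
  lambda <- ifelse(locus_class == "low_depth", cfg$low_depth_mean,
                   cfg$mean_depth)
  split <- ifelse(locus_class == "imbalance", cfg$imbalance_split, 0.5)
  for (j in seq_len(ncol(all_geno))) {
    called <- which(!is.na(all_geno[, j]))
    d <- sim_depths(all_geno[called, j], lambda[called], split[called],
                    cfg$deterministic_depth)
    dp_ref[called, j] <- d[, 1]; dp_alt[called, j] <- d[, 2]
  }

  loci <- data.frame(contig = "chr1",
                     pos = seq_len(L) * cfg$locus_spacing,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  m <- genotype_matrix(all_geno, loci, all_ids, dp_ref, dp_alt)

  truth <- list(
    seed = cfg$seed,
    n_loci = L, n_samples = ncol(all_geno),
    planted = lapply(classes, function(ix)
      sort(m$loci$locus_id[ix])),
    planted_counts = as.list(class_sizes),
    replicate_of = rep_of,
    realized = list(
      missing_fraction = mean(is.na(all_geno)),
      n_replicate_flips = n_flips,
      n_replicate_comparable = n_comparable,
      replicate_discordance = if (n_comparable > 0)
        n_flips / n_comparable else NA,
      q_ancestral = q_anc,
      q_population = q_pop),
    config = unclass(cfg))
  list(matrix = m, sheet = sheet, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `sim.vcf` (VCF 4.2), `samples.tsv` (sample sheet) and
#' `truth.json` (the ledger; frequency vectors included). Byte-stable
#' for a fixed configuration.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             sheet = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$matrix, paths["vcf"])
  write_sample_sheet(sim$sheet, paths["sheet"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Canonical hand-auditable fixtures
#'
#' Small deterministic datasets whose expected values are embedded
#' alongside them, used across the test-suite:
#' `covdiff` — three loci at coverage-difference 0\%, 600/7 \% (~85.7,
#' removed at the 80\% cut-off) and 400/7 \% (~57.1, retained);
#' `repro` — 20 replicate pairs with per-locus reproducibility 1.0,
#' 0.85 (removed by the strict > 0.85 rule) and 0.5;
#' `fst_worked` — a 2-population, 4+4-sample, 2-locus instance with
#' fully enumerated genotypes for checking the Weir-Cockerham
#' variance components against direct evaluation.
#'
#' @return named list of fixtures, each with `matrix`, optionally
#'   `sheet`/`pairs`, and an `expect` list of hand-derived values.
#' @export
fixture_suite <- function() {
  out <- list()

  # coverage-difference boundary loci: 2 samples, both het everywhere
  dp_r <- rbind(c(10L, 10L), c(5L, 5L), c(9L, 9L))
  dp_a <- rbind(c(10L, 10L), c(2L, 2L), c(5L, 5L))
  out$covdiff <- list(
    matrix = genotype_matrix(
      matrix(1L, 3, 2),
      data.frame(contig = "chr1", pos = c(100L, 200L, 300L),
                 ref = "A", alt = "G"),
      c("s1", "s2"), dp_r, dp_a),
    expect = list(coverage_diff = c(0, 600 / 7, 400 / 7),
                  removed_at_80 = "chr1:200"))

  # reproducibility boundary: 20 pairs, loci at 20/20, 17/20, 10/20
  n_pairs <- 20L
  orig <- sprintf("r%02d", seq_len(n_pairs))
  g_orig <- rbind(rep(0L, n_pairs), rep(0L, n_pairs), rep(0L, n_pairs))
  g_rep <- g_orig
  g_rep[2, 1:3] <- 1L     # 3 discordant  -> 17/20 = 0.85
  g_rep[3, 1:10] <- 1L    # 10 discordant -> 0.5
  sheet <- sample_sheet(data.frame(
    sample = c(orig, paste0(orig, "_rep")),
    population = "p1", sex = "unknown",
    replicate_group = c(orig, orig), stringsAsFactors = FALSE))
  out$repro <- list(
    matrix = genotype_matrix(
      cbind(g_orig, g_rep),
      data.frame(contig = "chr1", pos = c(100L, 200L, 300L),
                 ref = "A", alt = "G"),
      c(orig, paste0(orig, "_rep"))),
    sheet = sheet,
    expect = list(reproducibility = c(1, 0.85, 0.5),
                  removed_at_0.85 = c("chr1:200", "chr1:300")))

  # tiny worked F_ST instance (theta frozen from direct W&C evaluation)
  g <- rbind(c(0L, 0L, 1L, 1L, 2L, 2L, 1L, 2L),
             c(0L, 1L, 0L, 0L, 1L, 1L, 2L, 1L))
  samples <- c(paste0("a", 1:4), paste0("b", 1:4))
  out$fst_worked <- list(
    matrix = genotype_matrix(
      g, data.frame(contig = "chr1", pos = c(100L, 200L),
                    ref = "A", alt = "G"), samples),
    sheet = sample_sheet(data.frame(
      sample = samples, population = rep(c("pa", "pb"), each = 4),
      sex = "unknown", stringsAsFactors = FALSE)),
    expect = list(theta = 0.4471544715447155))
  out
}
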