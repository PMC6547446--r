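# Within-population diversity: per-locus observed/expected
# heterozygosity, per-individual multilocus heterozygosity, and
# genotype-ratio profiles. All frequencies are computed over called
# genotypes only.

#' Observed and expected heterozygosity
#'
#' Per locus: `H_O` = heterozygous fraction of called genotypes; `H_E` =
#' `2 p (1 - p)` with `p` the REF-allele frequency among called
#' genotypes (uncorrected by default; `corrected = TRUE` applies the
#' small-sample factor `2n / (2n - 1)`). Dataset-level means and SDs
#' are taken across loci; with `grouping`, statistics are additionally
#' recomputed within each population (allele frequencies re-estimated
#' from the subset).
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping optional character vector of population labels, one
#'   per sample (e.g. `sample_sheet$population` matched to the matrix).
#' @param corrected apply Nei's small-sample correction to `H_E`.
#' @return a `diversity_summary`: list with `per_locus` (data.frame
#'   `locus_id`, `h_obs`, `h_exp`, `n_called`), `mean_h_obs`,
#'   `sd_h_obs`, `mean_h_exp`, `sd_h_exp`, `mlh` (per-sample), and
#'   `by_population` (named list of summaries) when grouping is given.
#' @export
het_stats <- function(matrix, grouping = NULL, corrected = FALSE) {
  g <- matrix$geno
  called <- rowSums(!is.na(g))
  het <- rowSums(g == 1L, na.rm = TRUE)
  p_ref <- ifelse(called > 0, 1 - rowSums(g, na.rm = TRUE) / (2 * called), NA)
  h_obs <- ifelse(called > 0, het / called, NA)
  h_exp <- 2 * p_ref * (1 - p_ref)
  if (corrected)
    h_exp <- ifelse(called > 0, h_exp * 2 * called / (2 * called - 1), NA)
  out <- list(per_locus = data.frame(locus_id = matrix$loci$locus_id,
                                     h_obs = h_obs, h_exp = h_exp,
                                     n_called = called,
                                     stringsAsFactors = FALSE),
              mean_h_obs = mean(h_obs, na.rm = TRUE),
              sd_h_obs = sd(h_obs, na.rm = TRUE),
              mean_h_exp = mean(h_exp, na.rm = TRUE),
              sd_h_exp = sd(h_exp, na.rm = TRUE),
              mlh = mlh(matrix))
  if (!is.null(grouping)) {
    stopifnot(length(grouping) == n_samples(matrix))
    out$by_population <- lapply(
      split(seq_len(n_samples(matrix)), grouping),
      function(idx) het_stats(subset_samples(matrix, idx),
                              corrected = corrected))
  }
  class(out) <- "diversity_summary"
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("diversity_summary over %d loci\n", nrow(x$per_locus)))
  cat(sprintf("  H_O %.3f (SD %.3f)   H_E %.3f (SD %.3f)   MLH %.3f (SD %.3f)\n",
              x$mean_h_obs, x$sd_h_obs, x$mean_h_exp, x$sd_h_exp,
              mean(x$mlh, na.rm = TRUE), sd(x$mlh, na.rm = TRUE)))
  if (!is.null(x$by_population))
    cat("  populations:", paste(names(x$by_population), collapse = ", "), "\n")
  invisible(x)
}

#' Multilocus heterozygosity per individual
#'
#' Proportion of an individual's called loci that are heterozygous.
#' Samples with zero called loci are `NA` with a warning.
#'
#' @param matrix a `genotype_matrix`.
#' @return named numeric vector, one value per sample.
#' @export
mlh <- function(matrix) {
  g <- matrix$geno
  called <- colSums(!is.na(g))
  het <- colSums(g == 1L, na.rm = TRUE)
  if (any(called == 0L) && nrow(g) > 0L)
    warning("MLH undefined for sample(s) with no called loci: ",
            paste(matrix$samples[called == 0L], collapse = ", "))
  setNames(ifelse(called > 0L, het / called, NA_real_), matrix$samples)
}

#' Genotype-ratio profile
#'
#' Dataset-level proportions of called genotypes that are the major
#' homozygote, heterozygote, or minor homozygote. The major allele at
#' each locus is the more frequent called allele (ties resolved to
#' REF), so the classes are comparable across loci regardless of REF
#' polarity.
#'
#' @param matrix a `genotype_matrix`.
#' @return named numeric vector `c(hom_major, het, hom_minor)` summing
#'   to 1 (all zero for an empty matrix), with attribute `counts`.
#' @export
genotype_ratios <- function(matrix) {
  g <- matrix$geno
  called <- rowSums(!is.na(g))
  p_ref <- ifelse(called > 0, 1 - rowSums(g, na.rm = TRUE) / (2 * called), 1)
  ref_major <- p_ref >= 0.5           # ties -> REF is major
  hom_ref <- rowSums(g == 0L, na.rm = TRUE)
  hom_alt <- rowSums(g == 2L, na.rm = TRUE)
  het <- rowSums(g == 1L, na.rm = TRUE)
  counts <- c(hom_major = sum(ifelse(ref_major, hom_ref, hom_alt)),
              het = sum(het),
              hom_minor = sum(ifelse(ref_major, hom_alt, hom_ref)))
  total <- sum(counts)
  props <- if (total > 0) counts / total else counts * 0
  attr(props, "counts") <- counts
  props
}

#' Dataset summary table
#'
#' One row of headline statistics in the conventional reporting shape:
#' total loci, mean (min; max) called loci per individual, percent
#' missing, replicate error rate (when pairs are supplied), and
#' mean +/- SD of H_O, H_E and MLH.
#'
#' @param matrix a `genotype_matrix`.
#' @param pairs optional [replicate_pairs()] table for the error-rate
#'   column (`NA` otherwise).
#' @return one-row data.frame.
#' @export
diversity_table <- function(matrix, pairs = NULL) {
  hs <- het_stats(matrix)
  called_per_sample <- colSums(!is.na(matrix$geno))
  err <- if (!is.null(pairs) && nrow(pairs)) error_rate(matrix, pairs) else NA
  data.frame(
    total_loci = n_loci(matrix),
    mean_loci = mean(called_per_sample),
    min_loci = min(called_per_sample),
    max_loci = max(called_per_sample),
    pct_missing = 100 * missing_fraction(matrix)$dataset,
    error_rate_pct = 100 * err,
    h_obs = hs$mean_h_obs, h_obs_sd = hs$sd_h_obs,
    h_exp = hs$mean_h_exp, h_exp_sd = hs$sd_h_exp,
    mlh = mean(hs$mlh, na.rm = TRUE), mlh_sd = sd(hs$mlh, na.rm = TRUE))
}
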