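# Technical-replicate reproducibility, error rate, and deduplication.
# A "comparable" pair-call is one where both replicates are non-missing;
# identity means the same genotype state (depths are never compared).

#' Enumerate technical-replicate pairs from a sample sheet
#'
#' Replicate groups of size g contribute all g(g-1)/2 pairs. Only
#' samples present in the matrix are considered.
#'
#' @param sheet a `sample_sheet` with a `replicate_group` column.
#' @param matrix a `genotype_matrix` (restricts pairs to its samples).
#' @return data.frame with columns `sample_a`, `sample_b`, `group`.
#' @export
replicate_pairs <- function(sheet, matrix) {
  sheet <- sheet[sheet$sample %in% matrix$samples &
                   !is.na(sheet$replicate_group), , drop = FALSE]
  out <- list()
  for (grp in unique(sheet$replicate_group)) {
    ids <- sort(sheet$sample[sheet$replicate_group == grp])
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2L)
    out[[grp]] <- data.frame(sample_a = cmb[1, ], sample_b = cmb[2, ],
                             group = grp, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_a = character(), sample_b = character(),
                      group = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-locus counts of comparable and identical replicate pair-calls
rep_pair_counts <- function(matrix, pairs) {
  if (nrow(pairs) == 0L) stop("empty replicate pair set")
  ia <- match(pairs$sample_a, matrix$samples)
  ib <- match(pairs$sample_b, matrix$samples)
  if (anyNA(ia) || anyNA(ib))
    stop("replicate pair member(s) absent from matrix: ",
         paste(unique(c(pairs$sample_a[is.na(ia)],
                        pairs$sample_b[is.na(ib)])), collapse = ", "))
  g <- matrix$geno
  comp <- integer(n_loci(matrix))
  ident <- integer(n_loci(matrix))
  for (k in seq_along(ia)) {
    a <- g[, ia[k]]; b <- g[, ib[k]]
    both <- !is.na(a) & !is.na(b)
    comp <- comp + both
    ident <- ident + (both & a == b)
  }
  list(comparable = comp, identical = ident)
}

#' Per-locus replicate reproducibility
#'
#' For each locus, the fraction of replicate pairs with identical
#' genotype calls among pairs where both calls are non-missing. Loci
#' with no comparable pair are `NA` (undefined), never silently 1.
#'
#' @param matrix a `genotype_matrix`.
#' @param pairs pair table from [replicate_pairs()].
#' @return named numeric vector, one value per locus.
#' @export
locus_reproducibility <- function(matrix, pairs) {
  ct <- rep_pair_counts(matrix, pairs)
  r <- ifelse(ct$comparable > 0L, ct$identical / ct$comparable, NA_real_)
  setNames(r, matrix$loci$locus_id)
}

#' Filter loci on replicate reproducibility
#'
#' Loci are retained only when reproducibility is strictly greater than
#' `threshold` (so exactly 0.85 is removed at the default 0.85). Loci
#' with undefined reproducibility (no comparable pair) are retained —
#' absence of evidence is not failure — and their count is noted in the
#' report entry.
#'
#' @inheritParams locus_reproducibility
#' @param threshold reproducibility threshold (strict `>`).
#' @return `list(matrix, entry)`.
#' @export
filter_reproducibility <- function(matrix, pairs, threshold = 0.85) {
  stopifnot(threshold >= 0, threshold <= 1)
  r <- locus_reproducibility(matrix, pairs)
  drop <- !is.na(r) & r <= threshold
  n_undef <- sum(is.na(r))
  filter_result(matrix, "reproducibility", threshold, drop,
                note = if (n_undef)
                  paste0(n_undef, " loci undefined (retained)") else "")
}

#' Dataset-level replicate error rate
#'
#' Pooled (micro-averaged) over loci: discordant comparable pair-calls
#' divided by all comparable pair-calls. With `average = "macro"`, the
#' unweighted mean of per-locus discordance instead. The pooled rate
#' satisfies `error_rate = 1 - weighted mean locus reproducibility`
#' (weights = comparable pair-calls per locus).
#'
#' @inheritParams locus_reproducibility
#' @param average `"pooled"` (default) or `"macro"`.
#' @return a fraction in [0, 1].
#' @export
error_rate <- function(matrix, pairs, average = c("pooled", "macro")) {
  average <- match.arg(average)
  ct <- rep_pair_counts(matrix, pairs)
  if (sum(ct$comparable) == 0L)
    stop("error rate undefined: no comparable replicate pair-calls")
  if (average == "pooled") {
    sum(ct$comparable - ct$identical) / sum(ct$comparable)
  } else {
    mean((ct$comparable - ct$identical)[ct$comparable > 0L] /
           ct$comparable[ct$comparable > 0L])
  }
}

#' Collapse technical replicates to one sample per individual
#'
#' Keeps, per replicate group, the sample with the least missing data
#' (ties broken by lexical sample id, so the result is deterministic).
#' An explicit `keep` list of sample ids overrides the ranking — useful
#' to carry one callset's selection over to the others so the same
#' physical sample is retained everywhere.
#'
#' @param matrix a `genotype_matrix`.
#' @param sheet a `sample_sheet` defining replicate groups.
#' @param keep optional character vector of sample ids to retain in
#'   place of the least-missing ranking (one per replicate group).
#' @return a `genotype_matrix` with one sample per individual.
#' @export
deduplicate_replicates <- function(matrix, sheet, keep = NULL) {
  sheet <- match_sheet(matrix, sheet)
  n_miss <- colSums(is.na(matrix$geno))
  drop <- logical(n_samples(matrix))
  for (grp in unique(stats::na.omit(sheet$replicate_group))) {
    idx <- which(!is.na(sheet$replicate_group) &
                   sheet$replicate_group == grp)
    if (length(idx) < 2L) next
    if (!is.null(keep) && any(matrix$samples[idx] %in% keep)) {
      chosen <- idx[matrix$samples[idx] %in% keep][1L]
    } else {
      ord <- idx[order(n_miss[idx], matrix$samples[idx])]
      chosen <- ord[1L]
    }
    drop[setdiff(idx, chosen)] <- TRUE
  }
  subset_samples(matrix, !drop)
}
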