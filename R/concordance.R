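# Cross-callset comparison. Callsets aligned to the same reference are
# merged by genomic position (contig:pos); REF/ALT swaps between
# callers are reconciled by flipping genotype polarity, and loci whose
# allele pairs cannot be reconciled are excluded and logged.

# Reconcile one callset's alleles against reference alleles for shared
# locus ids. Returns per-locus: "same", "swap" or "mismatch".
allele_relation <- function(ref_a, alt_a, ref_b, alt_b) {
  ifelse(ref_a == ref_b & alt_a == alt_b, "same",
         ifelse(ref_a == alt_b & alt_a == ref_b, "swap", "mismatch"))
}

#' Partition loci across callsets by membership
#'
#' Loci are matched on (contig, position). For loci present in several
#' callsets, alleles are cross-checked against the first callset that
#' carries the locus: REF/ALT swaps are tolerated (genotype polarity is
#' flipped downstream), while irreconcilable allele pairs are excluded
#' from the shared sets and logged.
#'
#' @param matrices named list of two or more `genotype_matrix` objects
#'   from the same reference coordinate system.
#' @return list with `membership` (logical data.frame, union loci x
#'   callsets), `partition` (table of counts per membership pattern,
#'   e.g. `"stacks+gatk"`), `mismatched` (excluded locus ids) and
#'   `n_union`.
#' @export
shared_loci <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("callset", seq_along(matrices))
  ids <- lapply(matrices, function(m) m$loci$locus_id)
  union_ids <- Reduce(union, ids)
  membership <- vapply(ids, function(x) union_ids %in% x,
                       logical(length(union_ids)))
  membership <- as.data.frame(membership, row.names = union_ids)
  # allele reconciliation against the first callset carrying each locus
  mismatched <- character()
  allele_of <- lapply(matrices, function(m)
    setNames(paste0(m$loci$ref, "/", m$loci$alt), m$loci$locus_id))
  for (id in union_ids[rowSums(membership) >= 2]) {
    present <- which(unlist(membership[id, ]))
    first <- allele_of[[present[1]]][[id]]
    fa <- strsplit(first, "/", fixed = TRUE)[[1]]
    for (j in present[-1]) {
      oa <- strsplit(allele_of[[j]][[id]], "/", fixed = TRUE)[[1]]
      if (allele_relation(fa[1], fa[2], oa[1], oa[2]) == "mismatch") {
        mismatched <- c(mismatched, id)
        break
      }
    }
  }
  membership[rownames(membership) %in% mismatched, ] <- FALSE
  pattern <- apply(membership, 1, function(r)
    paste(names(matrices)[r], collapse = "+"))
  pattern <- pattern[pattern != ""]
  list(membership = membership,
       partition = table(pattern),
       mismatched = unique(mismatched),
       n_union = length(union_ids))
}

#' Genotype concordance between two callsets
#'
#' Compares genotype states cell by cell over loci shared by position
#' (REF/ALT swaps flipped to a common polarity; irreconcilable loci
#' dropped) and samples shared by id. A comparable cell has a
#' non-missing call in both callsets. Discordant cells are classified
#' directionally (a -> b): `hom_hom` (opposite homozygotes), `hom_het`
#' (homozygous in a, heterozygous in b) and `het_hom`. Rates are
#' percentages of the chosen denominator.
#'
#' @param matrix_a,matrix_b `genotype_matrix` objects on one reference.
#' @param shared optional character vector of locus ids to restrict to
#'   (default: all reconcilable position-shared loci).
#' @param denominator `"comparable"` (both-called cells; default) or
#'   `"all_shared"` (every shared sample x locus cell).
#' @return one-row data.frame: `n_shared_loci`, `n_samples`,
#'   `n_comparable`, `concordance_pct`, `hom_hom_pct`, `hom_het_pct`,
#'   `het_hom_pct`, `denominator`.
#' @export
genotype_concordance <- function(matrix_a, matrix_b, shared = NULL,
                                 denominator = c("comparable",
                                                 "all_shared")) {
  denominator <- match.arg(denominator)
  ids <- intersect(matrix_a$loci$locus_id, matrix_b$loci$locus_id)
  if (!is.null(shared)) ids <- intersect(ids, shared)
  ia <- match(ids, matrix_a$loci$locus_id)
  ib <- match(ids, matrix_b$loci$locus_id)
  rel <- allele_relation(matrix_a$loci$ref[ia], matrix_a$loci$alt[ia],
                         matrix_b$loci$ref[ib], matrix_b$loci$alt[ib])
  keep <- rel != "mismatch"
  ia <- ia[keep]; ib <- ib[keep]; rel <- rel[keep]
  samples <- intersect(matrix_a$samples, matrix_b$samples)
  ga <- matrix_a$geno[ia, match(samples, matrix_a$samples), drop = FALSE]
  gb <- matrix_b$geno[ib, match(samples, matrix_b$samples), drop = FALSE]
  gb[rel == "swap", ] <- 2L - gb[rel == "swap", , drop = FALSE]
  comp <- !is.na(ga) & !is.na(gb)
  n_comp <- sum(comp)
  if (n_comp == 0L)
    stop("no comparable cells: concordance undefined (",
         length(ia), " shared loci, ", length(samples), " shared samples)")
  concordant <- comp & ga == gb
  hom_a <- ga != 1L; hom_b <- gb != 1L
  hom_hom <- comp & !concordant & hom_a & hom_b
  hom_het <- comp & hom_a & !hom_b
  het_hom <- comp & !hom_a & hom_b
  denom <- if (denominator == "comparable") n_comp
           else length(ia) * length(samples)
  data.frame(n_shared_loci = length(ia), n_samples = length(samples),
             n_comparable = n_comp,
             concordance_pct = 100 * sum(concordant) / denom,
             hom_hom_pct = 100 * sum(hom_hom) / denom,
             hom_het_pct = 100 * sum(hom_het) / denom,
             het_hom_pct = 100 * sum(het_hom) / denom,
             denominator = denominator, stringsAsFactors = FALSE)
}

#' Concordance table over all callset pairs
#'
#' @param matrices named list of `genotype_matrix` objects.
#' @param restrict_to_common restrict to loci present in all callsets
#'   (the conventional shared-loci comparison) rather than each pair's
#'   own intersection.
#' @inheritParams genotype_concordance
#' @return data.frame, one row per unordered callset pair, with
#'   `callset_a`/`callset_b` columns prepended.
#' @export
concordance_table <- function(matrices, restrict_to_common = TRUE,
                              denominator = c("comparable", "all_shared")) {
  stopifnot(length(matrices) >= 2)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("callset", seq_along(matrices))
  common <- NULL
  if (restrict_to_common) {
    sl <- shared_loci(matrices)
    common <- rownames(sl$membership)[rowSums(sl$membership) ==
                                        length(matrices)]
  }
  pairs <- utils::combn(names(matrices), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cbind(data.frame(callset_a = a, callset_b = b,
                     stringsAsFactors = FALSE),
          genotype_concordance(matrices[[a]], matrices[[b]],
                               shared = common,
                               denominator = denominator))
  })
  do.call(rbind, rows)
}
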