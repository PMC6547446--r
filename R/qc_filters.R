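# Per-locus QC filters. Every filter is pure: it returns the filtered
# matrix plus a one-row report entry, never mutates calls, and is
# idempotent at a fixed threshold.

#' Filter configuration
#'
#' Thresholds for the full per-locus filter suite. Defaults are the
#' protocol values used throughout this package's reference workflow:
#' 70\% minimum call rate, MAF >= 0.01, observed heterozygosity <= 0.70,
#' mean allelic depth >= 2.5x for each allele, coverage difference
#' <= 80\%, replicate reproducibility strictly > 0.85, and a 77 bp
#' thinning window (a typical RRS read length, so SNPs on one read-locus
#' collapse to one).
#'
#' @param call_rate_min minimum fraction of samples called at a locus.
#' @param maf_min minimum minor allele frequency (over called genotypes).
#' @param max_obs_het maximum observed heterozygosity.
#' @param min_mean_allele_depth minimum mean read depth required for the
#'   REF allele and for the ALT allele (each among its carriers).
#' @param max_coverage_diff maximum symmetric percentage difference
#'   between mean REF and ALT depth over heterozygous calls, in [0, 200].
#' @param coverage_diff_mode `"het_mean"` (default; depths averaged over
#'   heterozygous calls, where imbalance is observable) or `"all_sum"`
#'   (depths summed over all called genotypes).
#' @param min_reproducibility replicate-pair reproducibility threshold;
#'   loci are kept only if strictly above it.
#' @param locus_thinning_window bp window for one-SNP-per-locus thinning.
#' @param sex_system `"XY"` (heterogametic males) or `"ZW"`
#'   (heterogametic females).
#' @param rng_seed seed used by the stochastic thinning step.
#' @return a `filter_config` list.
#' @export
filter_config <- function(call_rate_min = 0.70, maf_min = 0.01,
                          max_obs_het = 0.70, min_mean_allele_depth = 2.5,
                          max_coverage_diff = 80,
                          coverage_diff_mode = c("het_mean", "all_sum"),
                          min_reproducibility = 0.85,
                          locus_thinning_window = 77L,
                          sex_system = c("XY", "ZW"), rng_seed = 1L) {
  cfg <- list(call_rate_min = call_rate_min, maf_min = maf_min,
              max_obs_het = max_obs_het,
              min_mean_allele_depth = min_mean_allele_depth,
              max_coverage_diff = max_coverage_diff,
              coverage_diff_mode = match.arg(coverage_diff_mode),
              min_reproducibility = min_reproducibility,
              locus_thinning_window = as.integer(locus_thinning_window),
              sex_system = match.arg(sex_system),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$call_rate_min >= 0, cfg$call_rate_min <= 1,
            cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$max_obs_het >= 0, cfg$max_obs_het <= 1,
            cfg$min_reproducibility >= 0, cfg$min_reproducibility <= 1,
            cfg$max_coverage_diff >= 0, cfg$max_coverage_diff <= 200,
            cfg$locus_thinning_window >= 1)
  class(cfg) <- "filter_config"
  cfg
}

#' Read a filter configuration from a key=value file
#' @param path text file with one `key = value` pair per line; `#`
#'   comments allowed; keys are `filter_config()` argument names.
#' @return a `filter_config`.
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- lapply(kv, function(x) {
    v <- x[2]
    if (grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
  })
  names(args) <- vapply(kv, `[[`, "", 1)
  unknown <- setdiff(names(args), names(formals(filter_config)))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(filter_config, args)
}

filter_entry <- function(name, threshold, m_before, drop, note = "") {
  removed <- m_before$loci$locus_id[drop]
  entry <- data.frame(filter = name, threshold = as.character(threshold),
                      loci_before = n_loci(m_before),
                      loci_removed = length(removed),
                      loci_after = n_loci(m_before) - length(removed),
                      note = note, stringsAsFactors = FALSE)
  entry$removed_ids <- I(list(removed))
  entry
}

filter_result <- function(m, name, threshold, drop, note = "",
                          flagged = NULL) {
  out <- list(matrix = subset_loci(m, !drop),
              entry = filter_entry(name, threshold, m, drop, note))
  if (!is.null(flagged)) out$flagged <- flagged
  out
}

## ---- per-locus metrics ---------------------------------------------------

#' Per-locus QC metrics
#'
#' Vectorised per-locus summaries that the filters threshold on.
#' `locus_call_rate`: fraction of samples called. `locus_maf`: minor
#' allele frequency among called genotypes (0 for monomorphic or
#' uncalled loci). `locus_obs_het`: heterozygous fraction of called
#' genotypes. `locus_mean_allele_depth`: mean REF and ALT depth, each
#' over called genotypes carrying at least one copy of that allele
#' (`NaN` when an allele has no carriers). `locus_coverage_diff`:
#' symmetric percentage difference `100 |R - A| / ((R + A) / 2)` between
#' mean REF depth R and mean ALT depth A over heterozygous calls (`NA`
#' when the locus has no heterozygous calls).
#'
#' @param matrix a `genotype_matrix`.
#' @param mode see `coverage_diff_mode` in [filter_config()].
#' @return numeric vector (or two-column matrix for depths), one entry
#'   per locus.
#' @export
locus_call_rate <- function(matrix) {
  rowMeans(!is.na(matrix$geno))
}

#' @rdname locus_call_rate
#' @export
locus_maf <- function(matrix) {
  g <- matrix$geno
  called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), 0)
  pmin(p, 1 - p)
}

#' @rdname locus_call_rate
#' @export
locus_obs_het <- function(matrix) {
  g <- matrix$geno
  called <- rowSums(!is.na(g))
  het <- rowSums(g == 1L, na.rm = TRUE)
  ifelse(called > 0, het / called, 0)
}

#' @rdname locus_call_rate
#' @export
locus_mean_allele_depth <- function(matrix) {
  require_depth(matrix, "locus_mean_allele_depth")
  g <- matrix$geno
  ref_carrier <- !is.na(g) & g <= 1L
  alt_carrier <- !is.na(g) & g >= 1L
  dpr <- matrix$dp_ref; dpa <- matrix$dp_alt
  sum_where <- function(dp, w) rowSums(ifelse(w & !is.na(dp), dp, 0))
  n_where <- function(dp, w) rowSums(w & !is.na(dp))
  mr <- sum_where(dpr, ref_carrier) / n_where(dpr, ref_carrier)
  ma <- sum_where(dpa, alt_carrier) / n_where(dpa, alt_carrier)
  cbind(mean_ref = mr, mean_alt = ma)
}

#' @rdname locus_call_rate
#' @export
locus_coverage_diff <- function(matrix, mode = c("het_mean", "all_sum")) {
  require_depth(matrix, "locus_coverage_diff")
  mode <- match.arg(mode)
  g <- matrix$geno
  if (mode == "het_mean") {
    w <- !is.na(g) & g == 1L
  } else {
    w <- !is.na(g)
  }
  R <- rowSums(ifelse(w & !is.na(matrix$dp_ref), matrix$dp_ref, 0))
  A <- rowSums(ifelse(w & !is.na(matrix$dp_alt), matrix$dp_alt, 0))
  any_cell <- rowSums(w) > 0
  d <- ifelse(R + A > 0, 100 * abs(R - A) / ((R + A) / 2), 0)
  d[!any_cell] <- NA_real_
  d
}

## ---- filters -------------------------------------------------------------

#' Per-locus QC filters
#'
#' Each filter returns `list(matrix, entry)`: the matrix restricted to
#' retained loci and a report entry recording the threshold and removed
#' locus ids. Boundary semantics follow the reference protocol: call
#' rate and MAF are inclusive (`>=`), observed heterozygosity and
#' coverage difference are inclusive (`<=`), reproducibility (see
#' [filter_reproducibility()]) is strict (`>`).
#'
#' @param matrix a `genotype_matrix`.
#' @param threshold filter threshold (see [filter_config()] defaults).
#' @return `list(matrix = genotype_matrix, entry = data.frame)`;
#'   `filter_sex_linked` additionally returns `flagged`, the flagged
#'   locus ids.
#' @export
filter_call_rate <- function(matrix, threshold = 0.70) {
  stopifnot(threshold >= 0, threshold <= 1)
  filter_result(matrix, "call_rate", threshold,
                locus_call_rate(matrix) < threshold)
}

#' @rdname filter_call_rate
#' @export
filter_maf <- function(matrix, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  filter_result(matrix, "maf", threshold, locus_maf(matrix) < threshold)
}

#' @rdname filter_call_rate
#' @export
filter_max_het <- function(matrix, threshold = 0.70) {
  stopifnot(threshold >= 0, threshold <= 1)
  filter_result(matrix, "max_het", threshold,
                locus_obs_het(matrix) > threshold)
}

#' @rdname filter_call_rate
#' @param min_mean_depth minimum mean depth required for each allele.
#' @export
filter_allele_depth <- function(matrix, min_mean_depth = 2.5) {
  require_depth(matrix, "filter_allele_depth")
  md <- locus_mean_allele_depth(matrix)
  # NaN means (no carriers, or no depth among carriers) fail the criterion
  ok <- !is.nan(md[, 1]) & !is.nan(md[, 2]) &
    md[, 1] >= min_mean_depth & md[, 2] >= min_mean_depth
  filter_result(matrix, "allele_depth", min_mean_depth, !ok)
}

#' @rdname filter_call_rate
#' @param max_percent maximum coverage difference, percent in [0, 200].
#' @param mode see `coverage_diff_mode` in [filter_config()].
#' @export
filter_coverage_diff <- function(matrix, max_percent = 80,
                                 mode = c("het_mean", "all_sum")) {
  require_depth(matrix, "filter_coverage_diff")
  d <- locus_coverage_diff(matrix, mode)
  # NA = no heterozygous call: no evidence of imbalance, locus passes
  filter_result(matrix, "coverage_diff", max_percent,
                !is.na(d) & d > max_percent)
}

#' Flag and remove candidate sex-linked loci
#'
#' A locus is flagged when, among called genotypes, the heterogametic
#' sex (XY males, ZW females) shows zero heterozygotes while the
#' homogametic sex shows at least one, and both sexes have at least one
#' called genotype. Samples of unknown sex are excluded from both
#' tallies. This captures X-linked (or Z-linked) SNPs typed as diploid:
#' hemizygous individuals can never be truly heterozygous.
#'
#' @param matrix a `genotype_matrix`.
#' @param sheet a `sample_sheet` covering all samples.
#' @param system `"XY"` or `"ZW"`.
#' @return `list(matrix, entry, flagged)`.
#' @export
filter_sex_linked <- function(matrix, sheet, system = c("XY", "ZW")) {
  system <- match.arg(system)
  sheet <- match_sheet(matrix, sheet)
  hetero_sex <- if (system == "XY") "male" else "female"
  homo_sex <- if (system == "XY") "female" else "male"
  in_hetero <- sheet$sex == hetero_sex
  in_homo <- sheet$sex == homo_sex
  if (!any(in_hetero) || !any(in_homo))
    stop("sex-linkage filter needs called samples of both sexes ",
         "(found ", sum(in_hetero), " ", hetero_sex, ", ",
         sum(in_homo), " ", homo_sex, ")")
  g <- matrix$geno
  het_hetero <- rowSums(g[, in_hetero, drop = FALSE] == 1L, na.rm = TRUE)
  het_homo <- rowSums(g[, in_homo, drop = FALSE] == 1L, na.rm = TRUE)
  called_hetero <- rowSums(!is.na(g[, in_hetero, drop = FALSE]))
  called_homo <- rowSums(!is.na(g[, in_homo, drop = FALSE]))
  flagged <- het_hetero == 0L & het_homo >= 1L &
    called_hetero >= 1L & called_homo >= 1L
  filter_result(matrix, "sex_linked", system, flagged,
                flagged = matrix$loci$locus_id[flagged])
}

#' Thin to one SNP per RAD locus
#'
#' SNPs on the same contig are chained into clusters by single linkage
#' (consecutive SNPs no more than `window` bp apart share a cluster,
#' emulating one sequencing locus of that read length); one SNP per
#' cluster is kept, chosen uniformly at random. Deterministic for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param matrix a `genotype_matrix`.
#' @param window linkage window in bp (default 77).
#' @param seed integer RNG seed.
#' @return `list(matrix, entry)`.
#' @export
thin_one_snp_per_locus <- function(matrix, window = 77L, seed = 1L) {
  stopifnot(window >= 1)
  pos <- matrix$loci$pos
  contig <- matrix$loci$contig
  new_cluster <- c(TRUE, contig[-1] != contig[-length(contig)] |
                     diff(pos) > window)
  if (!n_loci(matrix)) new_cluster <- logical(0)
  cluster <- cumsum(new_cluster)
  keep_idx <- with_seed(seed, {
    vapply(split(seq_along(cluster), cluster), function(idx) {
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }, integer(1))
  })
  drop <- !(seq_len(n_loci(matrix)) %in% keep_idx)
  filter_result(matrix, "thin", paste0(window, "bp"), drop)
}

## ---- chain ---------------------------------------------------------------

default_filter_order <- c("allele_depth", "coverage_diff", "reproducibility",
                          "sex_linked", "max_het", "call_rate", "maf", "thin")

#' Run an ordered chain of filters
#'
#' Applies the requested filters in order, accumulating a filter report
#' whose entries chain exactly (each stage's `loci_before` equals the
#' previous stage's `loci_after`). The default order applies per-call
#' evidence filters (depth, coverage difference, reproducibility,
#' sex-linkage) before the population-level filters (observed
#' heterozygosity, call rate, MAF) and thins last.
#'
#' Filters whose prerequisites are unavailable (depth filters on a
#' depth-free matrix, reproducibility without replicate groups,
#' sex-linkage without sexed samples) are skipped with a zero-removal
#' report entry when `skip_unavailable = TRUE`, and raise an error
#' naming the stage otherwise.
#'
#' @param matrix a `genotype_matrix`.
#' @param sheet a `sample_sheet`, required by the reproducibility and
#'   sex-linkage stages (may be `NULL` if neither is requested).
#' @param config a [filter_config()].
#' @param order character vector of stage names, a subset of
#'   `"allele_depth"`, `"coverage_diff"`, `"reproducibility"`,
#'   `"sex_linked"`, `"max_het"`, `"call_rate"`, `"maf"`, `"thin"`.
#' @param skip_unavailable skip stages lacking prerequisites instead of
#'   erroring.
#' @return `list(matrix, report)` where `report` is the chained
#'   data.frame of entries (class `filter_report`).
#' @export
run_filter_chain <- function(matrix, sheet = NULL, config = filter_config(),
                             order = default_filter_order,
                             skip_unavailable = TRUE) {
  stopifnot(all(order %in% default_filter_order))
  m <- matrix
  entries <- list()
  skip_entry <- function(name, why) {
    e <- filter_entry(name, "skipped", m, rep(FALSE, n_loci(m)), note = why)
    entries[[length(entries) + 1L]] <<- e
  }
  for (stage in order) {
    res <- switch(stage,
      allele_depth = ,
      coverage_diff = {
        if (!has_depth(m)) {
          if (skip_unavailable) { skip_entry(stage, "depth-free matrix"); next }
          stop("stage ", stage, ": matrix is depth-free")
        }
        if (stage == "allele_depth")
          filter_allele_depth(m, config$min_mean_allele_depth)
        else
          filter_coverage_diff(m, config$max_coverage_diff,
                               config$coverage_diff_mode)
      },
      reproducibility = {
        pairs <- if (!is.null(sheet)) replicate_pairs(sheet, m) else NULL
        if (is.null(pairs) || nrow(pairs) == 0L) {
          if (skip_unavailable) {
            skip_entry(stage, "no replicate pairs"); next
          }
          stop("stage reproducibility: no replicate pairs in sample sheet")
        }
        filter_reproducibility(m, pairs, config$min_reproducibility)
      },
      sex_linked = {
        known <- !is.null(sheet) &&
          any(sheet$sex == "male") && any(sheet$sex == "female")
        if (!known) {
          if (skip_unavailable) { skip_entry(stage, "no sexed samples"); next }
          stop("stage sex_linked: sample sheet lacks sexed samples")
        }
        filter_sex_linked(m, sheet, config$sex_system)
      },
      max_het = filter_max_het(m, config$max_obs_het),
      call_rate = filter_call_rate(m, config$call_rate_min),
      maf = filter_maf(m, config$maf_min),
      thin = thin_one_snp_per_locus(m, config$locus_thinning_window,
                                    config$rng_seed))
    m <- res$matrix
    entries[[length(entries) + 1L]] <- res$entry
  }
  report <- do.call(rbind, entries)
  if (is.null(report))
    report <- filter_entry("none", NA, m, logical(n_loci(m)))[0, ]
  class(report) <- c("filter_report", "data.frame")
  list(matrix = m, report = report)
}

#' Write a filter report
#' @param report a `filter_report` from [run_filter_chain()].
#' @param path output path.
#' @param format `"tsv"` (removed ids comma-collapsed) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "tsv") {
    df$removed_ids <- vapply(df$removed_ids, paste, "", collapse = ",")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
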