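#' @importFrom stats rbeta rbinom rpois runif quantile sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Genotype states are stored as ALT-allele dose: 0 = hom ref, 1 = het,
# 2 = hom alt, NA = missing. Depth matrices are NULL on depth-free input.

#' Construct a genotype matrix
#'
#' The core container of the package: an ordered set of biallelic SNP loci
#' by an ordered set of samples, with each call stored as the ALT-allele
#' dose (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing) and, when available, per-call read depths
#' supporting the REF and ALT alleles.
#'
#' @param geno integer matrix, loci x samples, values in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns `contig`, `pos`, `ref`, `alt`.
#'   Loci must be sorted by (contig, pos); `locus_id` is derived as
#'   `"contig:pos"` and must be unique.
#' @param samples character vector of sample ids (column names of `geno`).
#' @param dp_ref,dp_alt integer matrices of per-call read depth for the
#'   REF and ALT allele, same shape as `geno`, or both `NULL` for a
#'   depth-free matrix (depth-based filters then refuse to run).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci, samples, dp_ref = NULL, dp_alt = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(loci)))
  loci$contig <- as.character(loci$contig)
  loci$pos <- as.integer(loci$pos)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  loci$locus_id <- if (nrow(loci)) paste0(loci$contig, ":", loci$pos)
                   else character(0)
  rownames(loci) <- NULL
  samples <- as.character(samples)
  dimnames(geno) <- list(loci$locus_id, samples)
  if (!is.null(dp_ref) != !is.null(dp_alt))
    stop("dp_ref and dp_alt must be supplied together or not at all")
  if (!is.null(dp_ref)) {
    dp_ref <- as.matrix(dp_ref); dp_alt <- as.matrix(dp_alt)
    storage.mode(dp_ref) <- "integer"; storage.mode(dp_alt) <- "integer"
    dimnames(dp_ref) <- dimnames(dp_alt) <- dimnames(geno)
  }
  obj <- structure(
    list(geno = geno, loci = loci, samples = samples,
         dp_ref = dp_ref, dp_alt = dp_alt),
    class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

validate_genotype_matrix <- function(x) {
  g <- x$geno
  if (nrow(g) != nrow(x$loci))
    stop("genotype grid has ", nrow(g), " rows but ", nrow(x$loci), " loci")
  if (ncol(g) != length(x$samples))
    stop("genotype grid has ", ncol(g), " columns but ", length(x$samples),
         " samples")
  if (length(x$samples) != length(unique(x$samples)))
    stop("duplicate sample ids")
  bad <- !(g %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  if (anyDuplicated(x$loci$locus_id))
    stop("duplicate locus_id: ",
         x$loci$locus_id[anyDuplicated(x$loci$locus_id)])
  if (nrow(x$loci)) {
    if (any(x$loci$pos < 1L)) stop("positions must be >= 1")
    single <- x$loci$ref %in% c("A", "C", "G", "T") &
      x$loci$alt %in% c("A", "C", "G", "T")
    if (!all(single)) stop("only single-base REF/ALT SNPs are allowed")
    if (any(x$loci$ref == x$loci$alt)) stop("REF and ALT alleles must differ")
    o <- order(x$loci$contig, x$loci$pos)
    if (!identical(o, seq_len(nrow(x$loci))) &&
        !identical(x$loci$locus_id, x$loci$locus_id[o]))
      stop("loci must be sorted by (contig, position)")
  }
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  mf <- missing_fraction(x)
  cat(sprintf(
    "genotype_matrix: %d loci x %d samples (%s; %.1f%% missing)\n",
    n_loci(x), n_samples(x),
    if (has_depth(x)) "with allelic depths" else "depth-free",
    100 * mf$dataset))
  invisible(x)
}

#' Number of loci / samples in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_loci <- function(x) nrow(x$geno)

#' @rdname n_loci
#' @export
n_samples <- function(x) ncol(x$geno)

#' Does the matrix carry per-allele read depths?
#' @param x a `genotype_matrix`.
#' @return logical; `FALSE` for matrices ingested without an AD field.
#' @export
has_depth <- function(x) !is.null(x$dp_ref)

require_depth <- function(x, what) {
  if (!has_depth(x))
    stop(what, " requires per-allele read depths, but this matrix is ",
         "depth-free (no AD field at ingestion)", call. = FALSE)
  invisible(x)
}

#' Subset a genotype matrix by locus or sample index
#'
#' Filters only change locus membership, never the calls themselves, so
#' subsetting is the primitive every filter is built on.
#'
#' @param x a `genotype_matrix`.
#' @param keep integer or logical index of loci (`subset_loci`) or samples
#'   (`subset_samples`) to retain, in matrix order.
#' @return a `genotype_matrix`.
#' @export
subset_loci <- function(x, keep) {
  genotype_matrix(x$geno[keep, , drop = FALSE], x$loci[keep, , drop = FALSE],
                  x$samples,
                  if (has_depth(x)) x$dp_ref[keep, , drop = FALSE],
                  if (has_depth(x)) x$dp_alt[keep, , drop = FALSE])
}

#' @rdname subset_loci
#' @export
subset_samples <- function(x, keep) {
  genotype_matrix(x$geno[, keep, drop = FALSE], x$loci,
                  x$samples[keep],
                  if (has_depth(x)) x$dp_ref[, keep, drop = FALSE],
                  if (has_depth(x)) x$dp_alt[, keep, drop = FALSE])
}

#' Missing-data fraction of a genotype matrix
#'
#' @param matrix a `genotype_matrix`.
#' @return list with `dataset` (missing cells / total cells), `per_sample`
#'   and `per_locus` named fractions.
#' @export
missing_fraction <- function(matrix) {
  g <- matrix$geno
  miss <- is.na(g)
  list(dataset = if (length(g)) mean(miss) else 0,
       per_sample = if (length(g)) colMeans(miss) else
         setNames(numeric(length(matrix$samples)), matrix$samples),
       per_locus = rowMeans(miss))
}

## ---- VCF ingestion -------------------------------------------------------

parse_gt_dose <- function(gt) {
  # diploid GT string -> dose; phase separators equal "/"; any allele "."
  # (half-calls included) or non-diploid form -> missing
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- rep(NA_integer_, length(gt))
  dose[gt == "0/0"] <- 0L
  dose[gt == "0/1" | gt == "1/0"] <- 1L
  dose[gt == "1/1"] <- 2L
  dose
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Ingests a VCF v4.x file (any short-variant caller) keeping only
#' biallelic single-nucleotide variants. Multi-allelic sites, indels/other
#' non-SNP records and duplicate positions are excluded and counted in the
#' ingestion log (`attr(x, "ingest_log")`), never silently dropped.
#' Half-called genotypes (e.g. `0/.`) and non-diploid calls map to
#' missing; phased separators are accepted and phase discarded. Per-allele
#' depths are taken from the `AD` FORMAT field; if `AD` is absent the
#' matrix is depth-free and depth-based filters later refuse to run.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param min_sample_overlap drop loci called in fewer than this fraction
#'   of samples at ingestion (default 0: keep everything).
#' @return a `genotype_matrix` with attribute `ingest_log`, a data.frame
#'   of exclusion reasons and counts.
#' @export
read_vcf <- function(path, min_sample_overlap = 0) {
  stopifnot(file.exists(path), min_sample_overlap >= 0,
            min_sample_overlap <= 1)
  v <- VariantAnnotation::readVcf(path)
  if (!("GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(v)))))
    stop("VCF has no GT FORMAT field: ", path)
  rr <- SummarizedExperiment::rowRanges(v)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  # sortedness check on raw records: contigs must form contiguous blocks
  # with non-decreasing positions
  if (length(contig) > 1) {
    blocks <- rle(contig)$values
    if (anyDuplicated(blocks)) {
      first_bad <- which(contig != contig[c(1, seq_len(length(contig) - 1))] &
                           contig %in% contig[duplicated(blocks)])
      stop("unsorted VCF: contig blocks interleaved near record ",
           contig[first_bad[1]], ":", pos[first_bad[1]])
    }
    same <- contig[-1] == contig[-length(contig)]
    bad <- which(same & pos[-1] < pos[-length(pos)])
    if (length(bad))
      stop("unsorted VCF: record ", contig[bad[1] + 1], ":", pos[bad[1] + 1],
           " follows position ", pos[bad[1]])
  }
  refc <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  n_alt <- S4Vectors::elementNROWS(altl)
  altc <- rep(NA_character_, length(n_alt))
  altc[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))

  multi <- n_alt != 1
  non_snp <- !multi & !(nchar(refc) == 1 & !is.na(altc) & nchar(altc) == 1 &
                          refc %in% c("A", "C", "G", "T") &
                          altc %in% c("A", "C", "G", "T"))
  keep <- !multi & !non_snp
  dup <- rep(FALSE, length(keep))
  kept_idx <- which(keep)
  dup[kept_idx[duplicated(paste0(contig, ":", pos)[kept_idx])]] <- TRUE
  keep <- keep & !dup

  gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]
  geno <- matrix(parse_gt_dose(gt), nrow = nrow(gt), ncol = ncol(gt))
  samples <- colnames(gt)

  dp_ref <- dp_alt <- NULL
  if ("AD" %in% names(VariantAnnotation::geno(v))) {
    ad <- VariantAnnotation::geno(v)$AD[keep, , drop = FALSE]
    pick <- function(i) {
      matrix(vapply(ad, function(x)
        if (length(x) >= i) as.integer(x[i]) else NA_integer_,
        integer(1)), nrow = nrow(ad), ncol = ncol(ad))
    }
    dp_ref <- pick(1L); dp_alt <- pick(2L)
    dp_ref[is.na(geno)] <- NA_integer_
    dp_alt[is.na(geno)] <- NA_integer_
  }

  m <- genotype_matrix(geno,
                       data.frame(contig = contig[keep], pos = pos[keep],
                                  ref = refc[keep], alt = altc[keep],
                                  stringsAsFactors = FALSE),
                       samples, dp_ref, dp_alt)
  log <- data.frame(
    reason = c("multiallelic", "non_snp", "duplicate_position",
               "below_min_sample_overlap"),
    count = c(sum(multi), sum(non_snp), sum(dup), 0L),
    stringsAsFactors = FALSE)
  if (min_sample_overlap > 0) {
    cr <- rowMeans(!is.na(m$geno))
    drop <- cr < min_sample_overlap
    log$count[log$reason == "below_min_sample_overlap"] <- sum(drop)
    m <- subset_loci(m, !drop)
  }
  attr(m, "ingest_log") <- log
  attr(m, "n_input_records") <- length(contig)
  m
}

#' Write a genotype matrix as VCF 4.2
#'
#' Plain-text, deterministic output: writing the same matrix twice yields
#' byte-identical files, and `read_vcf(write_vcf(m))` reproduces states,
#' depths, loci and sample order exactly.
#'
#' @param matrix a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(matrix, path) {
  m <- matrix
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("##fileformat=VCFv4.2")
  wl("##source=snpsieve")
  for (ctg in unique(m$loci$contig))
    wl(sprintf("##contig=<ID=%s>", ctg))
  wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_depth(m))
    wl('##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">')
  wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", m$samples), collapse = "\t"))
  if (n_loci(m)) {
    gt_str <- matrix("./.", n_loci(m), n_samples(m))
    gt_str[!is.na(m$geno) & m$geno == 0L] <- "0/0"
    gt_str[!is.na(m$geno) & m$geno == 1L] <- "0/1"
    gt_str[!is.na(m$geno) & m$geno == 2L] <- "1/1"
    if (has_depth(m)) {
      ad_str <- matrix(".", n_loci(m), n_samples(m))
      called <- !is.na(m$geno)
      ad_str[called] <- paste0(
        ifelse(is.na(m$dp_ref[called]), ".", m$dp_ref[called]), ",",
        ifelse(is.na(m$dp_alt[called]), ".", m$dp_alt[called]))
      cells <- matrix(paste0(gt_str, ":", ad_str), nrow = n_loci(m))
      fmt <- "GT:AD"
    } else {
      cells <- gt_str
      fmt <- "GT"
    }
    lines <- paste(m$loci$contig, m$loci$pos, ".", m$loci$ref, m$loci$alt,
                   ".", "PASS", ".", fmt,
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    wl(lines)
  }
  invisible(path)
}

## ---- sample sheet --------------------------------------------------------

#' Read a sample sheet
#'
#' Headered delimited text (tab or comma) with columns `sample`,
#' `population`, `sex` (`female`/`male`/`unknown`; empty = unknown) and
#' optionally `replicate_group` (samples sharing a non-empty group id are
#' technical replicates of one individual).
#'
#' @param path file path.
#' @return data.frame with those four columns (`replicate_group` is `NA`
#'   where absent), class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' Construct/validate a sample sheet from a data.frame
#' @param df data.frame with columns `sample`, `population`, `sex`,
#'   optionally `replicate_group`.
#' @return validated `sample_sheet` data.frame.
#' @export
sample_sheet <- function(df) {
  stopifnot(all(c("sample", "population") %in% names(df)))
  if (is.null(df$sex)) df$sex <- "unknown"
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  if (!all(df$sex %in% c("female", "male", "unknown")))
    stop("sex must be one of female, male, unknown")
  if (is.null(df$replicate_group)) df$replicate_group <- NA_character_
  df$replicate_group[df$replicate_group %in% ""] <- NA_character_
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in sample sheet: ",
         df$sample[anyDuplicated(df$sample)])
  df <- df[, c("sample", "population", "sex", "replicate_group")]
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet as tab-delimited text
#' @param sheet a `sample_sheet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

match_sheet <- function(matrix, sheet) {
  i <- match(matrix$samples, sheet$sample)
  if (anyNA(i))
    stop("samples missing from sample sheet: ",
         paste(matrix$samples[is.na(i)], collapse = ", "))
  sheet[i, , drop = FALSE]
}
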