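# Between-population divergence: principal coordinates analysis of
# individuals and pairwise Weir & Cockerham (1984) F_ST with bootstrap
# confidence intervals over loci.

#' Principal coordinates analysis of a genotype matrix
#'
#' Individuals are coded as ALT-allele dose (0/1/2); missing cells are
#' imputed with the locus mean (loci with no called genotype are
#' dropped with a warning). Classical PCoA is then applied to the
#' pairwise Euclidean distances between individuals, i.e. the squared
#' distances are Gower double-centred and eigendecomposed. Axes are
#' returned for positive eigenvalues only; negative eigenvalues (none
#' arise for this Euclidean embedding beyond numerical noise) are
#' reported. Each axis is deterministically oriented so that its
#' largest-magnitude coordinate is positive.
#'
#' @param matrix a `genotype_matrix`.
#' @param k number of axes to return (default all positive-eigenvalue
#'   axes).
#' @return a `pcoa_result`: list with `coordinates` (samples x axes),
#'   `eigenvalues` (descending, full spectrum), `percent_variance`
#'   (per returned axis, of the positive-eigenvalue total) and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(matrix, k = NULL) {
  stopifnot(n_samples(matrix) >= 2, n_loci(matrix) >= 1)
  g <- matrix$geno
  all_missing <- rowSums(!is.na(g)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing loci dropped before PCoA")
    g <- g[!all_missing, , drop = FALSE]
  }
  x <- t(g)                                   # samples x loci, doses
  mu <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- mu[nas[, 2]]
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2           # squared Euclidean
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J                  # Gower double-centring
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  eps <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > eps)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  axes <- pos[seq_len(k)]
  coords <- e$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(e$values[axes]), nrow = length(axes))
  # orient each axis: largest |coordinate| positive
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(matrix$samples,
                           paste0("Axis", seq_len(ncol(coords))))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    percent_variance = 100 * e$values[axes] / sum(e$values[pos]),
    negative_eigenvalues = e$values[e$values < -eps]),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes (axis 1: %.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$percent_variance[1]))
  invisible(x)
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for a
# set of populations. Inputs are per-locus-per-population counts:
# n (called genotypes), p (ALT frequency), h (observed het fraction),
# as loci x pops matrices. Loci with any n < min_n get NA components.
wc_components <- function(n, p, h, min_n = 2L) {
  r <- ncol(n)
  ok <- rowSums(n >= min_n) == r
  nbar <- rowMeans(n)
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c[!ok] <- NA_real_
  data.frame(a = a, b = b, c = c)
}

pop_counts <- function(matrix, pop) {
  g <- matrix$geno
  pops <- sort(unique(pop))
  n <- p <- h <- base::matrix(0, n_loci(matrix), length(pops),
                              dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    gj <- g[, pop == pops[j], drop = FALSE]
    nj <- rowSums(!is.na(gj))
    n[, j] <- nj
    p[, j] <- ifelse(nj > 0, rowSums(gj, na.rm = TRUE) / (2 * nj), 0)
    h[, j] <- ifelse(nj > 0, rowSums(gj == 1L, na.rm = TRUE) / nj, 0)
  }
  list(n = n, p = p, h = h, pops = pops)
}

#' Weir-Cockerham F_ST (theta) for one population grouping
#'
#' Multilocus theta combines per-locus variance components as a ratio
#' of sums, `sum(a) / sum(a + b + c)`. Loci with fewer than two called
#' genotypes in any population are skipped.
#'
#' @param matrix a `genotype_matrix`.
#' @param pop character vector of population labels, one per sample.
#' @return list with `theta`, per-locus `components`, and `n_loci_used`.
#' @export
wc_fst <- function(matrix, pop) {
  stopifnot(length(pop) == n_samples(matrix))
  pc <- pop_counts(matrix, pop)
  zero <- colSums(pc$n) == 0
  if (any(zero))
    stop("population(s) with zero called genotypes at all loci: ",
         paste(pc$pops[zero], collapse = ", "))
  comp <- wc_components(pc$n, pc$p, pc$h)
  used <- !is.na(comp$a)
  theta <- sum(comp$a[used]) / sum(comp$a[used] + comp$b[used] +
                                     comp$c[used])
  list(theta = theta, components = comp, n_loci_used = sum(used))
}

#' Pairwise F_ST with bootstrap confidence intervals
#'
#' For every unordered pair of populations, the Weir & Cockerham
#' (1984) theta estimate and a percentile bootstrap confidence
#' interval obtained by resampling loci with replacement `n_boot`
#' times. Deterministic for a fixed `seed` (the caller's RNG state is
#' untouched); estimates are invariant to sample and locus order.
#'
#' @param matrix a `genotype_matrix`.
#' @param sheet a `sample_sheet` supplying population labels.
#' @param n_boot bootstrap replicates across loci (default 2000).
#' @param seed integer RNG seed for the bootstrap.
#' @param alpha two-sided CI level (default 0.05 for a 95\% CI).
#' @return an `fst_result` data.frame: `pop_a`, `pop_b`, `fst`,
#'   `ci_lower`, `ci_upper`, `n_boot`, `n_loci_used`.
#' @export
pairwise_fst <- function(matrix, sheet, n_boot = 2000L, seed = 1L,
                         alpha = 0.05) {
  sheet <- match_sheet(matrix, sheet)
  pops <- sort(unique(sheet$population))
  stopifnot(length(pops) >= 2)
  pairs <- utils::combn(pops, 2)
  rows <- with_seed(seed, {
    lapply(seq_len(ncol(pairs)), function(k) {
      pa <- pairs[1, k]; pb <- pairs[2, k]
      keep <- sheet$population %in% c(pa, pb)
      sub <- subset_samples(matrix, keep)
      res <- wc_fst(sub, sheet$population[keep])
      comp <- res$components[!is.na(res$components$a), , drop = FALSE]
      L <- nrow(comp)
      boot <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(L, L, replace = TRUE)
        sum(comp$a[idx]) / sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
      }, numeric(1))
      ci <- quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                     names = FALSE)
      data.frame(pop_a = pa, pop_b = pb, fst = res$theta,
                 ci_lower = ci[1], ci_upper = ci[2],
                 n_boot = n_boot, n_loci_used = L,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fst_result", "data.frame")
  out
}
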