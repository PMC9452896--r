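#' Counts per million
#'
#' Scales column `j` by `1e6 / (lib_size_j * factor_j)`. Without
#' normalization factors each CPM column sums to exactly one million.
#'
#' @param x `mir_counts` or numeric count matrix.
#' @param factors optional `norm_factors` object (from [tmm_factors()] or
#'   [median_of_ratios_factors()]); `NULL` means unit factors.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(x, factors = NULL) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  lib <- colSums(m)
  f <- rep(1, ncol(m))
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "norm_factors"))
    f <- factors$factors[colnames(m)]
    lib <- factors$lib_sizes[colnames(m)]
  }
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "))
  }
  sweep(m, 2, 1e6 / (lib * f), `*`)
}

#' Remove low-expressed miRs by a CPM threshold
#'
#' A miR is retained iff its CPM (computed without normalization factors,
#' since filtering precedes factor estimation) reaches `cpm_threshold` in at
#' least `min_samples` samples. The dropped ids are returned alongside the
#' kept matrix: the preferential-expression stage inspects them for
#' informative missingness.
#'
#' @param x `mir_counts` object.
#' @param cpm_threshold CPM cutoff (default 0.5).
#' @param min_samples minimum number of samples reaching the cutoff
#'   (default 2, the strict reading of "more than one sample").
#' @return list with `kept` (`mir_counts`) and `dropped` (character vector).
#' @export
filter_low_expressors <- function(x, cpm_threshold = 0.5, min_samples = 2) {
  stopifnot(inherits(x, "mir_counts"), cpm_threshold >= 0)
  if (min_samples > ncol(x$counts)) {
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(x$counts), ")")
  }
  cm <- cpm(x)
  keep <- rowSums(cm >= cpm_threshold) >= min_samples
  list(
    kept = mir_counts(x$counts[keep, , drop = FALSE], x$samples),
    dropped = rownames(x$counts)[!keep]
  )
}

new_norm_factors <- function(method, factors, lib_sizes) {
  structure(list(method = method, factors = factors, lib_sizes = lib_sizes),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("norm_factors (", x$method, "):\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference, gene-wise
#' log2 ratios of library-size-scaled proportions (M) and mean log2
#' abundances (A) are computed over genes positive in both samples, doubly
#' trimmed (`trim_m` on each tail of M, `trim_a` on each tail of A), and the
#' factor is `2^` the weighted mean of the surviving M values with inverse
#' asymptotic (delta-method binomial) variance weights. Factors are rescaled
#' so their geometric mean is 1. The reference defaults to the sample whose
#' upper quartile of scaled counts is closest to the mean upper quartile.
#'
#' @param x `mir_counts` or count matrix (>= 2 samples).
#' @param reference sample id or column index; `NULL` = automatic choice.
#' @param trim_m two-sided trim fraction on M (default 0.3).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return `norm_factors` object (`method = "tmm"`).
#' @export
tmm_factors <- function(x, reference = NULL, trim_m = 0.3, trim_a = 0.05) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("zero library size")
  if (is.null(reference)) {
    uq <- apply(m, 2, function(y) stats::quantile(y / sum(y), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(reference)) match(reference, colnames(m)) else reference
    if (is.na(ref) || ref < 1 || ref > ncol(m)) stop("invalid reference sample")
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, ref], lib[j], lib[ref], trim_m, trim_a,
                    sample_label = colnames(m)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  names(lib) <- colnames(m)
  new_norm_factors("tmm", f, lib)
}

# One sample-vs-reference trimmed weighted mean of M values.
tmm_pair_factor <- function(y, yr, n, nr, trim_m, trim_a, sample_label = "") {
  both <- y > 0 & yr > 0
  if (!any(both)) {
    stop("sample ", sample_label,
         " shares no positively expressed gene with the TMM reference")
  }
  p <- y[both] / n
  pr <- yr[both] / nr
  M <- log2(p / pr)
  A <- 0.5 * log2(p * pr)
  v <- (n - y[both]) / (n * y[both]) + (nr - yr[both]) / (nr * yr[both])
  k <- length(M)
  loM <- floor(k * trim_m) + 1
  hiM <- k - floor(k * trim_m)
  loA <- floor(k * trim_a) + 1
  hiA <- k - floor(k * trim_a)
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  w <- 1 / v[keep]
  2^(sum(w * M[keep]) / sum(w))
}

#' Median-of-ratios size factors (DESeq-style)
#'
#' For genes positive in every sample, each sample's factor is the median of
#' its counts divided by the gene-wise geometric means; factors are rescaled
#' to geometric mean 1.
#'
#' @param x `mir_counts` or count matrix.
#' @return `norm_factors` object (`method = "median_of_ratios"`).
#' @export
median_of_ratios_factors <- function(x) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("median-of-ratios undefined: no gene is positive in all samples")
  }
  sub <- m[pos, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  f <- apply(sub / gm, 2, stats::median)
  f <- f / exp(mean(log(f)))
  lib <- colSums(m)
  names(f) <- colnames(m)
  names(lib) <- colnames(m)
  new_norm_factors("median_of_ratios", f, lib)
}

#' Transcripts per million
#'
#' Standard TPM: counts are divided by feature length (nt), then each column
#' is scaled to sum to one million.
#'
#' @param x `mir_counts` or count matrix.
#' @param lengths named numeric vector of feature lengths in nt (e.g.
#'   `end - start + 1` from annotation); names must cover the rownames of
#'   the matrix.
#' @return numeric TPM matrix.
#' @export
tpm_normalize <- function(x, lengths) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  if (!is.null(names(lengths))) {
    lengths <- lengths[rownames(m)]
  }
  if (length(lengths) != nrow(m) || anyNA(lengths)) {
    stop("`lengths` must provide a length for every miR in the matrix")
  }
  if (any(lengths <= 0)) stop("zero or negative feature length")
  rate <- m / lengths
  sweep(rate, 2, 1e6 / colSums(rate), `*`)
}

#' Log effective-library-size offsets for the NB GLM
#'
#' @param factors `norm_factors` object.
#' @return named numeric vector `log(lib_size * factor)` per sample.
#' @export
norm_offsets <- function(factors) {
  stopifnot(inherits(factors, "norm_factors"))
  log(factors$lib_sizes * factors$factors)
}

#' Unit normalization factors (library size only)
#'
#' @param x `mir_counts` or count matrix.
#' @return `norm_factors` with all factors 1 (`method = "none"`).
#' @export
unit_factors <- function(x) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  lib <- colSums(m)
  f <- rep(1, ncol(m))
  names(f) <- colnames(m)
  names(lib) <- colnames(m)
  new_norm_factors("none", f, lib)
}
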