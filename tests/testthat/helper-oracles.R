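# Independent oracles used to cross-check the package's implementations.
# These deliberately use plain loops / direct formula evaluation, never the
# package's own code paths.

# Brute-force quantifier: evaluate every (record, locus) pair against the
# retention, strand, 5'-anchor and 3'-tolerance rules, then count distinct
# (mir, chrom, strand, start, end, umi) tuples.
oracle_quantify <- function(records, loci, max_hits = 13, max_3p_var = 2) {
  counts <- integer(nrow(loci))
  names(counts) <- loci$mir_id
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$n_hits > max_hits) next
    for (k in seq_len(nrow(loci))) {
      l <- loci[k, ]
      if (r$chrom != l$chrom) next
      if (r$strand != l$strand) next
      r5 <- if (l$strand == "+") r$start else r$end
      l5 <- if (l$strand == "+") l$start else l$end
      if (r5 != l5) next
      r3 <- if (l$strand == "+") r$end else r$start
      l3 <- if (l$strand == "+") l$end else l$start
      if (abs(r3 - l3) > max_3p_var) next
      tup <- paste(l$mir_id, r$chrom, r$strand, r$start, r$end, r$umi)
      if (tup %in% seen) next
      seen <- c(seen, tup)
      counts[l$mir_id] <- counts[l$mir_id] + 1L
    }
  }
  counts
}

# Direct evaluation of the doubly-trimmed, variance-weighted mean of M
# values (per-sample factor vs a given reference), rescaled to geometric
# mean 1. Trimming is done by sorting positions rather than rank filtering.
oracle_tmm <- function(m, ref = NULL, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(m)
  if (is.null(ref)) {
    uq <- sapply(seq_len(ncol(m)), function(j) {
      quantile(m[, j] / lib[j], 0.75)
    })
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- sapply(seq_len(ncol(m)), function(j) {
    ok <- which(m[, j] > 0 & m[, ref] > 0)
    y <- m[ok, j]; yr <- m[ok, ref]
    M <- log2((y / lib[j]) / (yr / lib[ref]))
    A <- 0.5 * log2((y / lib[j]) * (yr / lib[ref]))
    v <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - yr) / (lib[ref] * yr)
    k <- length(M)
    oM <- order(M)
    selM <- oM[(floor(k * trim_m) + 1):(k - floor(k * trim_m))]
    oA <- order(A)
    selA <- oA[(floor(k * trim_a) + 1):(k - floor(k * trim_a))]
    sel <- intersect(selM, selA)
    if (length(sel) == 0) return(1)
    2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
  })
  f / exp(mean(log(f)))
}

# Exhaustive hypergeometric upper tail: enumerate every draw of n ids from
# the universe and count draws overlapping the pathway by >= obs.
oracle_hyper_enum <- function(universe, pathway, n, obs) {
  draws <- combn(universe, n)
  hits <- apply(draws, 2, function(d) sum(d %in% pathway))
  mean(hits >= obs)
}

# Spreadsheet-style TPM for a single column.
oracle_tpm_col <- function(counts, lengths) {
  r <- counts / lengths
  r / sum(r) * 1e6
}

# Convenience: a small deterministic study-shaped sample sheet.
toy_sheet <- function(n_subjects = 3, treatments = c("CTL", "CLFS", "IHFS"),
                      compartments = c("MB", "EV")) {
  g <- expand.grid(subject = paste0("S", seq_len(n_subjects)),
                   compartment = compartments, treatment = treatments,
                   stringsAsFactors = FALSE)
  g$sample_id <- paste(g$subject, g$compartment, g$treatment, sep = "_")
  g[, c("sample_id", "subject", "compartment", "treatment")]
}
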