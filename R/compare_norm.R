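#' Compare TMM, median-of-ratios and TPM normalization through one DE engine
#'
#' Runs the same paired quasi-NB engine on one treatment contrast within one
#' compartment three times, differing only in normalization: (1) TMM factors
#' as offsets; (2) median-of-ratios size factors as offsets; (3) TPM values
#' rescaled to each sample's original depth and rounded to integer
#' pseudo-counts, tested with library-size offsets only. Reports the
#' differentially expressed set per method at each p threshold plus all
#' Venn overlap regions.
#'
#' @param x `mir_counts` object.
#' @param compartment compartment to analyse (default `"MB"`).
#' @param treatments length-2 treatment pair, reference first (default
#'   `c("CTL", "CLFS")`).
#' @param thresholds p-value stringencies (default 0.05 and 0.01).
#' @param lengths named miR lengths in nt for TPM; default 22 nt for every
#'   miR (mature miRs are nearly length-uniform, making TPM's length term a
#'   near-constant).
#' @param cpm_threshold,min_samples low-expressor filter parameters
#'   (applied once, to the raw compartment matrix, so all three arms test
#'   the same miR set).
#' @param prior_df QL prior df.
#' @return list with `tables` (per-method DE tables), `sets` (per
#'   threshold, per method: significant miR ids), `overlaps` (per
#'   threshold: Venn regions of the three sets), and `sizes` (per
#'   threshold: per-method set sizes).
#' @export
compare_normalizations <- function(x, compartment = "MB",
                                   treatments = c("CTL", "CLFS"),
                                   thresholds = c(0.05, 0.01),
                                   lengths = NULL,
                                   cpm_threshold = 0.5, min_samples = 2,
                                   prior_df = 10) {
  stopifnot(inherits(x, "mir_counts"), length(treatments) == 2)
  sub <- subset_mir_counts(
    x, sample_ids = x$samples$sample_id[x$samples$compartment == compartment])
  flt <- filter_low_expressors(sub, cpm_threshold, min_samples)
  y <- flt$kept
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(22, nrow(y$counts)), rownames(y$counts))
  }

  run_arm <- function(counts_obj, factors) {
    run_one_contrast(counts_obj, factors,
                     "between_treatment_within_population",
                     compartment = compartment, treatments = treatments,
                     prior_df = prior_df)
  }
  tables <- list()
  tables$tmm <- run_arm(y, tmm_factors(y))
  tables$median_of_ratios <- run_arm(y, median_of_ratios_factors(y))
  # TPM arm: length-normalized abundances put back on each sample's depth
  # so the count-based engine applies; rounding makes them valid counts.
  depth <- colSums(y$counts)
  tpm <- tpm_normalize(y, lengths)
  pseudo <- round(sweep(tpm, 2, depth / 1e6, `*`))
  ytpm <- mir_counts(pseudo, y$samples)
  tables$tpm <- run_arm(ytpm, unit_factors(ytpm))

  sets <- list()
  overlaps <- list()
  sizes <- list()
  for (th in thresholds) {
    key <- paste0("p", th)
    s <- lapply(tables, function(tab) {
      tab$mir_id[!is.na(tab$p_value) & tab$p_value < th]
    })
    sets[[key]] <- s
    sizes[[key]] <- vapply(s, length, integer(1))
    overlaps[[key]] <- overlap_sets(s)
  }
  list(tables = tables, sets = sets, overlaps = overlaps, sizes = sizes,
       filtered_ids = rownames(y$counts))
}
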