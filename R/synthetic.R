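#' Configuration for the NB count-matrix simulator
#'
#' Defaults mirror the study design: 3 subjects, each contributing one
#' myobundle (MB) and one EV sample per treatment (CTL, CLFS, IHFS), 991
#' mature miRs (the size of the raw pre-filter set), sequencing depth around
#' 16 million, and moderate NB dispersion. Baseline per-miR abundances are
#' log-normal; subject effects are shared between a subject's MB and EV
#' samples, inducing cross-compartment correlation of magnitude
#' `planted_corr`; planted fold changes multiply flagged miRs by
#' `2^planted_log2fc` in the target group; compartment-exclusive miRs are
#' zeroed in the other compartment.
#'
#' @param seed integer seed; fully determines the simulated dataset.
#' @param n_subjects number of subjects (default 3).
#' @param treatments treatment labels (default CTL, CLFS, IHFS).
#' @param compartments compartment labels (default MB and EV).
#' @param n_mirs number of miRs (default 991).
#' @param mean_log_expression `c(meanlog, sdlog)` of the log-normal baseline
#'   relative abundances.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param lib_size_range integer pair; library sizes drawn uniformly.
#' @param frac_de fraction of miRs with a planted fold change.
#' @param planted_log2fc planted log2 fold change.
#' @param de_target `"treatment"` (effects in non-reference treatments of
#'   `de_compartment`) or `"compartment"` (effects in `de_compartment`
#'   across all treatments).
#' @param de_compartment compartment carrying planted effects.
#' @param frac_mb_exclusive,frac_ev_exclusive fractions of miRs expressed
#'   exclusively in MB / EV.
#' @param exclusive_leak mean fraction leaking into the "absent"
#'   compartment (0 = absolute zeroing, the default).
#' @param planted_corr target MB-EV correlation induced via shared subject
#'   effects, in [-1, 1].
#' @param subject_sd log-scale SD of subject effects.
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_subjects = 3,
                       treatments = c("CTL", "CLFS", "IHFS"),
                       compartments = c("MB", "EV"),
                       n_mirs = 991,
                       mean_log_expression = c(0, 2),
                       dispersion = 0.1,
                       lib_size_range = c(12e6, 20e6),
                       frac_de = 0.1, planted_log2fc = 2,
                       de_target = c("treatment", "compartment"),
                       de_compartment = "MB",
                       frac_mb_exclusive = 0.02, frac_ev_exclusive = 0.02,
                       exclusive_leak = 0,
                       planted_corr = 0.7, subject_sd = 0.4) {
  de_target <- match.arg(de_target)
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              treatments = treatments, compartments = compartments,
              n_mirs = n_mirs, mean_log_expression = mean_log_expression,
              dispersion = dispersion, lib_size_range = lib_size_range,
              frac_de = frac_de, planted_log2fc = planted_log2fc,
              de_target = de_target, de_compartment = de_compartment,
              frac_mb_exclusive = frac_mb_exclusive,
              frac_ev_exclusive = frac_ev_exclusive,
              exclusive_leak = exclusive_leak,
              planted_corr = planted_corr, subject_sd = subject_sd)
  if (cfg$frac_de + cfg$frac_mb_exclusive + cfg$frac_ev_exclusive > 1) {
    stop("frac_de + frac_mb_exclusive + frac_ev_exclusive must be <= 1")
  }
  if (abs(cfg$planted_corr) > 1) stop("planted_corr must be in [-1, 1]")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a miR count matrix with planted truth
#'
#' Samples are all subject x compartment x treatment combinations. Counts
#' are drawn NB(mean, dispersion) (Poisson when dispersion = 0) around
#' per-sample expected abundances built from: log-normal baseline, shared
#' subject effects (correlation), planted fold changes, and
#' compartment-exclusive zeroing. Reproducible: the same config (including
#' seed) always yields the same dataset.
#'
#' @param config `sim_config` object.
#' @return list with `counts` ([mir_counts()]), `truth` (per-miR planted
#'   parameters: `de_flag`, `true_log2fc`, `exclusivity`, `corr_group`) and
#'   `config`.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- expand.grid(
    subject = paste0("S", seq_len(config$n_subjects)),
    compartment = config$compartments,
    treatment = config$treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  samples$sample_id <- paste(samples$subject, samples$compartment,
                             samples$treatment, sep = "_")
  samples <- samples[, c("sample_id", "subject", "compartment", "treatment")]
  G <- config$n_mirs
  mir_ids <- sprintf("sim-miR-%04d", seq_len(G))

  base <- stats::rlnorm(G, meanlog = config$mean_log_expression[1],
                        sdlog = config$mean_log_expression[2])

  # disjoint planted sets: DE, MB-exclusive, EV-exclusive
  n_de <- round(config$frac_de * G)
  n_mb <- round(config$frac_mb_exclusive * G)
  n_ev <- round(config$frac_ev_exclusive * G)
  pool <- sample.int(G, n_de + n_mb + n_ev)
  de_idx <- pool[seq_len(n_de)]
  mb_idx <- pool[n_de + seq_len(n_mb)]
  ev_idx <- pool[n_de + n_mb + seq_len(n_ev)]

  exclusivity <- rep("none", G)
  exclusivity[mb_idx] <- "MB"
  exclusivity[ev_idx] <- "EV"
  de_flag <- logical(G)
  de_flag[de_idx] <- TRUE
  true_lfc <- ifelse(de_flag, config$planted_log2fc, 0)

  rho <- config$planted_corr
  a_sh <- sqrt(abs(rho))
  a_id <- sqrt(1 - abs(rho))
  z_shared <- matrix(stats::rnorm(G * config$n_subjects), G)
  lib_lo <- config$lib_size_range[1]
  lib_hi <- config$lib_size_range[2]
  n_s <- nrow(samples)
  lib <- round(stats::runif(n_s, lib_lo, lib_hi))
  # per-compartment independent component (shared across treatments so the
  # subject effect is a property of the subject, not of the well)
  z_comp <- array(stats::rnorm(G * config$n_subjects * 2),
                  dim = c(G, config$n_subjects, 2))
  counts <- matrix(0L, G, n_s, dimnames = list(mir_ids, samples$sample_id))
  for (j in seq_len(n_s)) {
    si <- match(samples$subject[j], unique(samples$subject))
    ci <- match(samples$compartment[j], config$compartments)
    sgn <- if (rho < 0 && samples$compartment[j] == "EV") -1 else 1
    subj_eff <- config$subject_sd *
      (sgn * a_sh * z_shared[, si] + a_id * z_comp[, si, ci])
    mu <- base * exp(subj_eff)
    if (config$de_target == "compartment") {
      if (samples$compartment[j] == config$de_compartment) {
        mu[de_idx] <- mu[de_idx] * 2^config$planted_log2fc
      }
    } else if (samples$treatment[j] != config$treatments[1] &&
               samples$compartment[j] == config$de_compartment) {
      mu[de_idx] <- mu[de_idx] * 2^config$planted_log2fc
    }
    off <- if (samples$compartment[j] == "MB") ev_idx else mb_idx
    mu[off] <- mu[off] * config$exclusive_leak
    mu <- mu / sum(mu) * lib[j]
    counts[, j] <- if (config$dispersion <= 0) {
      stats::rpois(G, mu)
    } else {
      stats::rnbinom(G, size = 1 / config$dispersion, mu = mu)
    }
  }
  truth <- data.frame(mir_id = mir_ids, de_flag = de_flag,
                      true_log2fc = true_lfc, exclusivity = exclusivity,
                      corr_group = rho != 0, stringsAsFactors = FALSE)
  list(counts = mir_counts(counts, samples), truth = truth, config = config)
}

# Random UMI of length `len` (A/C/G/T).
random_umi <- function(n, len = 6) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a toy SAM + GFF3 fixture with known true counts
#'
#' Generates `n_loci` mature-miR loci on a toy chromosome (alternating
#' strands) and `n_reads` reads over them, corrupting each read
#' independently: multimapping (NH set above/below the retention cutoff,
#' with a decoy alignment record), 3'-end shifts of 1-4 nt, 5'-end shifts of
#' 1-2 nt (seed violations), and duplicate UMIs (PCR copies of an earlier
#' read). A few unmapped records are included. The bundled `truth` is
#' computed by a direct, independent application of the counting rules
#' (retention cutoff 13, exact 5' anchor, 3' tolerance 2, coordinate+UMI
#' deduplication) over the emitted records.
#'
#' @param n_loci number of mature-miR loci (default 10).
#' @param n_reads number of reads (default 200).
#' @param p_multimap,p_shift3,p_shift5,p_dup_umi corruption probabilities.
#' @param seed integer seed.
#' @param dir directory for the SAM/GFF3 files (default `tempdir()`).
#' @return list with `sam` and `gff` file paths, `truth` (named integer
#'   vector of true molecule counts per locus) and `loci` (annotation
#'   data.frame).
#' @export
simulate_alignments <- function(n_loci = 10, n_reads = 200,
                                p_multimap = 0.1, p_shift3 = 0.1,
                                p_shift5 = 0.05, p_dup_umi = 0.1,
                                seed = 1, dir = tempdir()) {
  stopifnot(n_loci >= 1, n_reads >= 1)
  for (p in c(p_multimap, p_shift3, p_shift5, p_dup_umi)) {
    if (p < 0 || p > 1) stop("corruption rates must be in [0, 1]")
  }
  set.seed(seed)
  chrom <- "chrS"
  len <- sample(20:24, n_loci, replace = TRUE)
  start <- 1000 + (seq_len(n_loci) - 1) * 1000
  loci <- data.frame(
    mir_id = sprintf("sim-miR-%03d", seq_len(n_loci)),
    chrom = chrom,
    strand = rep(c("+", "-"), length.out = n_loci),
    start = start,
    end = start + len - 1,
    stringsAsFactors = FALSE
  )
  plus <- loci$strand == "+"
  loci$seed_start <- ifelse(plus, loci$start + 1L, loci$end - 7L)
  loci$seed_end <- ifelse(plus, loci$start + 7L, loci$end - 1L)

  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    if (i > 1 && stats::runif(1) < p_dup_umi) {
      prev <- reads[[sample.int(i - 1, 1)]]
      r <- prev
      r$read_id <- sprintf("R%06d_%s", i, prev$umi)
      reads[[i]] <- r
      next
    }
    li <- sample.int(n_loci, 1)
    lc <- loci[li, ]
    s <- lc$start
    e <- lc$end
    if (stats::runif(1) < p_shift5) {
      d5 <- sample(c(-2L, -1L, 1L, 2L), 1)
      if (lc$strand == "+") s <- s + d5 else e <- e + d5
    }
    if (stats::runif(1) < p_shift3) {
      d3 <- sample(c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L), 1)
      if (lc$strand == "+") e <- e + d3 else s <- s + d3
    }
    if (e - s + 1 < 12) e <- s + 11  # keep spans sane
    nh <- if (stats::runif(1) < p_multimap) sample(c(5L, 14L, 20L), 1) else 1L
    umi <- random_umi(1)
    reads[[i]] <- list(read_id = sprintf("R%06d_%s", i, umi), umi = umi,
                       chrom = chrom, strand = lc$strand, start = s, end = e,
                       n_hits = nh)
  }
  reads <- do.call(rbind, lapply(reads, as.data.frame,
                                 stringsAsFactors = FALSE))

  # SAM emission: one record at the read span, plus one decoy record at a
  # shifted position for multimappers (same NH), plus a couple of unmapped
  # records to exercise the reader.
  sam <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:100000", chrom))
  fmt_rec <- function(r, s, e) {
    flag <- if (r$strand == "-") 16L else 0L
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
            r$read_id, flag, r$chrom, s, e - s + 1L, r$n_hits)
  }
  recs <- character(0)
  extra <- list()
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    recs <- c(recs, fmt_rec(r, r$start, r$end))
    if (r$n_hits > 1) {
      ds <- r$start + 137L
      recs <- c(recs, fmt_rec(r, ds, ds + (r$end - r$start)))
      extra[[length(extra) + 1]] <- data.frame(
        read_id = r$read_id, umi = r$umi, chrom = r$chrom,
        strand = r$strand, start = ds, end = ds + (r$end - r$start),
        n_hits = r$n_hits, stringsAsFactors = FALSE)
    }
  }
  unmapped <- sprintf("U%03d_%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
                      1:2, random_umi(2))
  sam <- c(sam, recs, unmapped)

  sam_path <- file.path(dir, sprintf("sim_reads_seed%d.sam", seed))
  gff_path <- file.path(dir, sprintf("sim_mirs_seed%d.gff3", seed))
  writeLines(sam, sam_path)
  gff <- c("##gff-version 3",
           sprintf("%s\tsim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   loci$chrom, loci$start, loci$end, loci$strand,
                   loci$mir_id, loci$mir_id))
  writeLines(gff, gff_path)

  all_recs <- rbind(reads, do.call(rbind, extra))
  truth <- brute_force_truth(all_recs, loci, max_hits = 13, max_3p_var = 2)
  list(sam = sam_path, gff = gff_path, truth = truth, loci = loci,
       records = all_recs)
}

# Independent brute-force application of the counting rules: plain loops
# over every (record, locus) pair, then set-based deduplication. Kept free
# of the vectorized/indexed code paths in quantify_sample() on purpose.
brute_force_truth <- function(records, loci, max_hits = 13, max_3p_var = 2) {
  tuples <- character(0)
  mirs <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$n_hits > max_hits) next
    for (k in seq_len(nrow(loci))) {
      l <- loci[k, ]
      if (r$chrom != l$chrom || r$strand != l$strand) next
      if (l$strand == "+") {
        if (r$start != l$start) next
        if (abs(r$end - l$end) > max_3p_var) next
      } else {
        if (r$end != l$end) next
        if (abs(r$start - l$start) > max_3p_var) next
      }
      tuples <- c(tuples, paste(l$mir_id, r$chrom, r$strand, r$start,
                                r$end, r$umi))
      mirs <- c(mirs, l$mir_id)
    }
  }
  keep <- !duplicated(tuples)
  out <- integer(nrow(loci))
  names(out) <- loci$mir_id
  if (any(keep)) {
    tab <- table(mirs[keep])
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Run a calibration experiment on the DE or correlation machinery
#'
#' * `type1`: simulate a null dataset (`frac_de = 0`) with `n_reps` miRs and
#'   a 2-compartment paired design, run the full filter/TMM/QL pipeline on
#'   the compartment contrast, and report the fraction of miRs with
#'   p < 0.05.
#' * `power`: plant `frac_de` compartment fold changes and report the
#'   detection rate among planted miRs.
#' * `fc_recovery`: as `power`, reporting the median estimated log2FC error
#'   among planted miRs.
#' * `corr_recovery`: `n_reps` paired Gaussian vectors at the planted
#'   correlation; reports the mean Pearson estimate.
#'
#' @param kind experiment type.
#' @param config `sim_config`; for `type1`/`power`/`fc_recovery` the
#'   replicates are the miRs (config `n_mirs` is overridden by `n_reps`).
#' @param n_reps number of replicates (>= 100 for type1/power).
#' @param n_pairs vector length for `corr_recovery` (default 50).
#' @param alpha significance threshold (default 0.05).
#' @return list of summary statistics incl. a Monte-Carlo standard error.
#' @export
calibration_experiment <- function(kind = c("type1", "power", "fc_recovery",
                                            "corr_recovery"),
                                   config = sim_config(), n_reps = 500,
                                   n_pairs = 50, alpha = 0.05) {
  kind <- match.arg(kind)
  if (kind %in% c("type1", "power") && n_reps < 100) {
    stop("type1/power experiments need n_reps >= 100")
  }
  if (kind == "corr_recovery") {
    set.seed(config$seed)
    rho <- config$planted_corr
    r_hat <- vapply(seq_len(n_reps), function(i) {
      z1 <- stats::rnorm(n_pairs)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_pairs)
      stats::cor(z1, z2)
    }, numeric(1))
    return(list(kind = kind, mean_r = mean(r_hat),
                bias = mean(r_hat) - rho,
                mc_se = stats::sd(r_hat) / sqrt(n_reps), n = n_reps))
  }
  # DE calibration isolates the NB sampling layer: pure NB counts at the
  # configured dispersion, no subject random effects (those are a distinct,
  # non-NB variance component exercised by the correlation experiments).
  cfg <- config
  cfg$n_mirs <- n_reps
  cfg$treatments <- cfg$treatments[1]
  cfg$de_target <- "compartment"
  cfg$frac_mb_exclusive <- 0
  cfg$frac_ev_exclusive <- 0
  cfg$subject_sd <- 0
  cfg$planted_corr <- 0
  if (kind == "type1") cfg$frac_de <- 0
  class(cfg) <- "sim_config"
  sim <- simulate_counts(cfg)
  flt <- filter_low_expressors(sim$counts)
  nf <- tmm_factors(flt$kept)
  tab <- run_one_contrast(flt$kept, nf,
                          "within_treatment_between_population",
                          treatment = cfg$treatments[1])
  tab <- merge(tab, sim$truth, by = "mir_id")
  if (kind == "type1") {
    pv <- tab$p_value[!tab$de_flag & !is.na(tab$p_value)]
    rate <- mean(pv < alpha)
    return(list(kind = kind, rate = rate,
                mc_se = sqrt(rate * (1 - rate) / length(pv)),
                p_values = pv, n = length(pv)))
  }
  planted <- tab[tab$de_flag & !is.na(tab$p_value), ]
  rate <- mean(planted$p_value < alpha)
  err <- planted$log2_fc - planted$true_log2fc
  list(kind = kind, rate = rate,
       mc_se = sqrt(rate * (1 - rate) / nrow(planted)),
       median_error = stats::median(err), n = nrow(planted))
}
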