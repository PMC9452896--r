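#' Myobundle-EV Pearson correlation per miR within one treatment
#'
#' Pairs each subject's MB and EV samples within the treatment and computes
#' the Pearson correlation of normalized counts per miR, with a two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df. With the
#' study's n = 3 pairs this test has a single degree of freedom and |r| = 1
#' gives an infinite t; such boundary cases are reported with the smallest
#' representable positive p and flagged `"boundary"`. Zero variance in
#' either compartment is flagged `"undefined"` rather than returning silent
#' NaN.
#'
#' @param norm_counts numeric matrix of normalized counts (e.g. TMM-CPM),
#'   columns named by sample id.
#' @param samples sample sheet covering those columns.
#' @param treatment treatment condition to pair within.
#' @param mir_subset optional miR ids to restrict to (e.g. the significant
#'   set from the matching DE contrast); default all rows.
#' @return data.frame: `mir_id`, `treatment`, `r`, `r_squared`, `p_value`,
#'   `n_pairs`, `flag` (`"ok"`, `"boundary"` or `"undefined"`).
#' @export
compartment_correlation <- function(norm_counts, samples, treatment,
                                    mir_subset = NULL) {
  samples <- validate_sample_sheet(samples)
  sub <- samples[samples$treatment == treatment, , drop = FALSE]
  subj <- sort(intersect(sub$subject[sub$compartment == "MB"],
                         sub$subject[sub$compartment == "EV"]))
  if (length(subj) < 3) {
    stop("need >= 3 subjects with paired MB and EV samples in treatment ",
         treatment)
  }
  mb_ids <- vapply(subj, function(s) {
    sub$sample_id[sub$subject == s & sub$compartment == "MB"]
  }, character(1))
  ev_ids <- vapply(subj, function(s) {
    sub$sample_id[sub$subject == s & sub$compartment == "EV"]
  }, character(1))
  if (!all(c(mb_ids, ev_ids) %in% colnames(norm_counts))) {
    stop("normalized matrix is missing paired sample columns")
  }
  mirs <- if (is.null(mir_subset)) rownames(norm_counts) else mir_subset
  n <- length(subj)
  res <- lapply(mirs, function(mid) {
    xv <- norm_counts[mid, mb_ids]
    yv <- norm_counts[mid, ev_ids]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      return(data.frame(mir_id = mid, treatment = treatment, r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n_pairs = n, flag = "undefined",
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(xv, yv)
    if (abs(r) >= 1 - 1e-12) {
      return(data.frame(mir_id = mid, treatment = treatment,
                        r = sign(r), r_squared = 1,
                        p_value = .Machine$double.xmin, n_pairs = n,
                        flag = "boundary", stringsAsFactors = FALSE))
    }
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(mir_id = mid, treatment = treatment, r = r,
               r_squared = r^2, p_value = max(p, .Machine$double.xmin),
               n_pairs = n, flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Partition 2-4 named id sets into Venn regions
#'
#' Returns every non-empty-membership region (2^k - 1 of them) as a named
#' list; region names join the member set names with `"&"`. The regions
#' partition the union of the sets.
#'
#' @param sets named list of 2-4 character vectors.
#' @return named list mapping region -> ids exclusive to that region.
#' @export
overlap_sets <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) {
    stop("overlap_sets supports 2-4 sets (got ", k, ")")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    region <- paste(names(sets)[inset], collapse = "&")
    sel <- apply(member, 1, function(row) all(row == inset))
    out[[region]] <- ids[sel]
  }
  out
}

# Paired t-test returning the statistic and two-sided p; sd(d) == 0 is
# reported as undefined (NA) rather than an error.
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (n < 2 || is.na(s) || s == 0) {
    return(list(t = NA_real_, p = NA_real_, defined = FALSE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), defined = TRUE)
}

#' Detect miRs preferentially expressed in one compartment
#'
#' Informative missingness: a miR that passes the low-expressor filter in
#' the MB-only matrix but not in the EV-only matrix (or vice versa) is
#' flagged as preferentially expressed in that compartment. Each flagged
#' miR is then tested on raw counts with a repeated-measures comparison of
#' compartments across all subject x treatment units -- with two
#' compartment levels this is exactly a paired t-test on those units
#' (RM-ANOVA-equivalent) -- and, where that test reaches `alpha`, by paired
#' t-tests MB vs EV within each treatment.
#'
#' @param filtered_joint ids passing the filter on the joint matrix.
#' @param filtered_mb ids passing the filter on the MB-only matrix.
#' @param filtered_ev ids passing the filter on the EV-only matrix.
#' @param raw `mir_counts` with the raw (unfiltered) counts.
#' @param alpha significance gate for the follow-up per-treatment tests
#'   (default 0.05).
#' @return list with one element per compartment (`MB`, `EV`), each a list
#'   of `mir_ids` and a results data.frame (`mir_id`, `anova_t`, `anova_p`,
#'   then `t_<treatment>_p` columns). The two id sets are disjoint by
#'   construction.
#' @export
preferential_expression <- function(filtered_joint, filtered_mb, filtered_ev,
                                    raw, alpha = 0.05) {
  stopifnot(inherits(raw, "mir_counts"))
  flags <- list(MB = setdiff(filtered_mb, filtered_ev),
                EV = setdiff(filtered_ev, filtered_mb))
  samples <- raw$samples
  trts <- treatment_levels(samples$treatment)
  units <- unique(samples[, c("subject", "treatment")])
  units <- units[order(units$subject, match(units$treatment, trts)), ,
                 drop = FALSE]
  pair_ids <- function(comp) {
    vapply(seq_len(nrow(units)), function(i) {
      sid <- samples$sample_id[samples$subject == units$subject[i] &
                                 samples$treatment == units$treatment[i] &
                                 samples$compartment == comp]
      if (length(sid) != 1) NA_character_ else sid
    }, character(1))
  }
  mb_ids <- pair_ids("MB")
  ev_ids <- pair_ids("EV")
  ok_units <- !is.na(mb_ids) & !is.na(ev_ids)
  if (sum(ok_units) < 2) {
    stop("preferential-expression test needs >= 2 paired subject-treatment units")
  }
  mb_ids <- mb_ids[ok_units]
  ev_ids <- ev_ids[ok_units]
  unit_trt <- units$treatment[ok_units]
  test_one <- function(mid) {
    mb <- raw$counts[mid, mb_ids]
    ev <- raw$counts[mid, ev_ids]
    omni <- paired_t(mb, ev)
    row <- data.frame(mir_id = mid, anova_t = omni$t, anova_p = omni$p,
                      stringsAsFactors = FALSE)
    for (trt in trts) {
      col <- paste0("t_", trt, "_p")
      if (omni$defined && !is.na(omni$p) && omni$p < alpha) {
        sel <- unit_trt == trt
        tt <- paired_t(mb[sel], ev[sel])
        row[[col]] <- tt$p
      } else {
        row[[col]] <- NA_real_
      }
    }
    row
  }
  out <- lapply(names(flags), function(comp) {
    mirs <- sort(intersect(flags[[comp]], rownames(raw$counts)))
    tab <- if (length(mirs)) {
      do.call(rbind, lapply(mirs, test_one))
    } else {
      data.frame(mir_id = character(), anova_t = numeric(),
                 anova_p = numeric(), stringsAsFactors = FALSE)
    }
    rownames(tab) <- NULL
    list(compartment = comp, mir_ids = mirs, table = tab)
  })
  names(out) <- names(flags)
  out
}
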