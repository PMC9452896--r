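#' Drop reads mapping to too many genomic locations
#'
#' Reads are retained only if they map to at most `max_hits` genomic
#' locations (boundary inclusive: `n_hits == max_hits` is kept). Input order
#' is preserved.
#'
#' @param reads data.frame from [read_alignments()].
#' @param max_hits maximum number of genomic locations (default 13).
#' @export
filter_multimappers <- function(reads, max_hits = 13) {
  stopifnot(is.numeric(max_hits), max_hits >= 1)
  reads[reads$n_hits <= max_hits, , drop = FALSE]
}

#' Decide whether one aligned read supports one mature miR
#'
#' A read is accepted when (a) it lies on the annotated strand, (b) its 5'
#' genomic terminus coincides exactly with the mature miR's 5' terminus --
#' which pins read positions 2-8 onto the annotated seed interval -- and
#' (c) its 3' terminus differs from the annotated 3' terminus by at most
#' `max_3p_var` nucleotides (trimming or extension). On the minus strand the
#' 5'/3' termini are the `end`/`start` coordinates respectively.
#'
#' `seed_mode = "cover"` relaxes (b) to "the read span contains the seed
#' interval" (the looser reading of seed matching); the 3' rule still
#' applies.
#'
#' @param read one-row data.frame or list with `chrom`, `strand`, `start`,
#'   `end`.
#' @param mir one-row data.frame or list with `chrom`, `strand`, `start`,
#'   `end`, `seed_start`, `seed_end`.
#' @param max_3p_var maximum 3'-terminus deviation in nt (default 2).
#' @param seed_mode `"anchor"` (exact 5'-terminus equality, default) or
#'   `"cover"`.
#' @return list with `accepted` (logical) and `reason` (one of `ok`,
#'   `strand_mismatch`, `no_overlap`, `seed_mismatch`, `three_prime_excess`).
#' @export
assign_read <- function(read, mir, max_3p_var = 2,
                        seed_mode = c("anchor", "cover")) {
  seed_mode <- match.arg(seed_mode)
  decision <- function(reason) {
    list(accepted = identical(reason, "ok"), reason = reason)
  }
  if (!identical(as.character(read$chrom), as.character(mir$chrom))) {
    return(decision("no_overlap"))
  }
  if (!identical(as.character(read$strand), as.character(mir$strand))) {
    return(decision("strand_mismatch"))
  }
  if (read$end < mir$start || read$start > mir$end) {
    return(decision("no_overlap"))
  }
  plus <- identical(as.character(mir$strand), "+")
  read5 <- if (plus) read$start else read$end
  mir5 <- if (plus) mir$start else mir$end
  seed_ok <- if (seed_mode == "anchor") {
    read5 == mir5
  } else {
    read$start <= mir$seed_start && read$end >= mir$seed_end
  }
  if (!seed_ok) return(decision("seed_mismatch"))
  read3 <- if (plus) read$end else read$start
  mir3 <- if (plus) mir$end else mir$start
  if (abs(read3 - mir3) > max_3p_var) return(decision("three_prime_excess"))
  decision("ok")
}

#' Collapse assigned reads to molecule counts by (coordinate, UMI) identity
#'
#' The molecule count of a miR is the number of distinct
#' `(chrom, strand, start, end, umi)` tuples among its assigned reads; reads
#' sharing all five fields are PCR duplicates of one molecule. Exact-match
#' deduplication (no UMI edit-distance clustering). Idempotent.
#'
#' @param assigned data.frame with columns `mir_id`, `chrom`, `strand`,
#'   `start`, `end`, `umi` (one row per accepted read-miR assignment).
#' @param mir_ids optional character vector fixing the output order; miRs
#'   without assignments get count 0.
#' @return named integer vector of molecule counts.
#' @export
deduplicate <- function(assigned, mir_ids = NULL) {
  if (nrow(assigned) == 0) {
    out <- integer(0)
  } else {
    key <- paste(assigned$mir_id, assigned$chrom, assigned$strand,
                 assigned$start, assigned$end, assigned$umi, sep = "\r")
    uniq <- assigned[!duplicated(key), , drop = FALSE]
    tab <- table(uniq$mir_id)
    out <- as.integer(tab)
    names(out) <- names(tab)
  }
  if (!is.null(mir_ids)) {
    full <- integer(length(mir_ids))
    names(full) <- mir_ids
    full[names(out)] <- out
    out <- full
  }
  out
}

# All accepted (read, miR) assignments for one sample; vectorized over reads.
# Anchor mode uses a (chrom, strand, 5'-terminus) key join; cover mode uses
# interval overlap of the annotated seed within the read span.
assignments_for_sample <- function(reads, annotations, max_3p_var = 2,
                                   seed_mode = c("anchor", "cover")) {
  seed_mode <- match.arg(seed_mode)
  empty <- data.frame(mir_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), umi = character(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0 || nrow(annotations) == 0) return(empty)
  plus_r <- reads$strand == "+"
  if (seed_mode == "anchor") {
    read5 <- ifelse(plus_r, reads$start, reads$end)
    mir5 <- ifelse(annotations$strand == "+", annotations$start,
                   annotations$end)
    rkey <- paste(reads$chrom, reads$strand, read5)
    akey <- paste(annotations$chrom, annotations$strand, mir5)
    lut <- split(seq_len(nrow(annotations)), akey)
    hit_list <- lut[rkey]
    nhit <- vapply(hit_list, function(h) if (is.null(h)) 0L else length(h),
                   integer(1))
    ri <- rep(seq_len(nrow(reads)), nhit)
    ai <- unlist(hit_list[nhit > 0], use.names = FALSE)
  } else {
    rgr <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(reads$start, reads$end),
                                  strand = reads$strand)
    sgr <- GenomicRanges::GRanges(annotations$chrom,
                                  IRanges::IRanges(annotations$seed_start,
                                                   annotations$seed_end),
                                  strand = annotations$strand)
    ov <- GenomicRanges::findOverlaps(sgr, rgr, type = "within",
                                      ignore.strand = FALSE)
    ai <- S4Vectors::queryHits(ov)
    ri <- S4Vectors::subjectHits(ov)
  }
  if (length(ri) == 0) return(empty)
  plus_a <- annotations$strand[ai] == "+"
  read3 <- ifelse(plus_a, reads$end[ri], reads$start[ri])
  mir3 <- ifelse(plus_a, annotations$end[ai], annotations$start[ai])
  ok <- abs(read3 - mir3) <= max_3p_var
  ri <- ri[ok]
  ai <- ai[ok]
  data.frame(
    mir_id = annotations$mir_id[ai],
    chrom = reads$chrom[ri],
    strand = reads$strand[ri],
    start = reads$start[ri],
    end = reads$end[ri],
    umi = reads$umi[ri],
    stringsAsFactors = FALSE
  )
}

#' Quantify one sample's alignments against mature-miR annotation
#'
#' Pipeline composition: multimap filter, candidate lookup by (chrom,
#' strand), per-read seed/3' acceptance, then (coordinate, UMI)
#' deduplication. A read contributes to every mature record its alignment
#' records satisfy.
#'
#' @param reads data.frame from [read_alignments()].
#' @param annotations data.frame from [read_mirbase_gff()].
#' @inheritParams filter_multimappers
#' @inheritParams assign_read
#' @return named integer vector of molecule counts (one per annotation
#'   record, annotation order), with a `stats` attribute recording per-stage
#'   retention: `input`, `multimap_dropped`, `assigned`, `post_dedup`.
#' @export
quantify_sample <- function(reads, annotations, max_hits = 13,
                            max_3p_var = 2,
                            seed_mode = c("anchor", "cover")) {
  seed_mode <- match.arg(seed_mode)
  n_in <- nrow(reads)
  kept <- filter_multimappers(reads, max_hits = max_hits)
  assigned <- assignments_for_sample(kept, annotations,
                                     max_3p_var = max_3p_var,
                                     seed_mode = seed_mode)
  counts <- deduplicate(assigned, mir_ids = annotations$mir_id)
  attr(counts, "stats") <- list(
    input = n_in,
    multimap_dropped = n_in - nrow(kept),
    assigned = nrow(assigned),
    post_dedup = sum(counts)
  )
  counts
}

#' Quantify a set of per-sample SAM files into a miR count matrix
#'
#' @param sam_files named character vector of SAM paths; names are sample
#'   ids. Every sample in `samples` must have an entry.
#' @param annotations data.frame from [read_mirbase_gff()].
#' @param samples sample sheet (data.frame).
#' @param umi_pattern passed to [read_alignments()].
#' @inheritParams quantify_sample
#' @param verbose log per-sample retention statistics via `message()`.
#' @return [mir_counts()] object, columns ordered per the sample sheet.
#' @export
quantify_dataset <- function(sam_files, annotations, samples,
                             max_hits = 13, max_3p_var = 2,
                             seed_mode = c("anchor", "cover"),
                             umi_pattern = "_([^_]+)$", verbose = FALSE) {
  seed_mode <- match.arg(seed_mode)
  samples <- validate_sample_sheet(samples)
  missing <- setdiff(samples$sample_id, names(sam_files))
  if (length(missing)) {
    stop("no alignment file for sample(s): ",
         paste(missing, collapse = ", "))
  }
  cols <- lapply(samples$sample_id, function(sid) {
    reads <- read_alignments(sam_files[[sid]], umi_pattern = umi_pattern)
    v <- quantify_sample(reads, annotations, max_hits = max_hits,
                         max_3p_var = max_3p_var, seed_mode = seed_mode)
    if (verbose) {
      s <- attr(v, "stats")
      message(sprintf(
        "%s: %d reads in, %d multimap-dropped, %d assigned, %d after dedup",
        sid, s$input, s$multimap_dropped, s$assigned, s$post_dedup))
    }
    v
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(annotations$mir_id, samples$sample_id)
  mir_counts(m, samples)
}
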