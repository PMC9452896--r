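#' Read mature miRNA records from a miRBase-style GFF3 file
#'
#' Selects features of the mature-miR type, derives genomic seed coordinates
#' (mature positions 2-8 from the 5' end) and returns one row per record in
#' file order. On the + strand the seed spans `start+1 .. start+7`; on the -
#' strand it spans `end-7 .. end-1` (the 5' end of a minus-strand mature miR
#' is its larger genomic coordinate).
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"miRNA"`, the mature records;
#'   `"miRNA_primary_transcript"` rows are ignored).
#' @param name_attr GFF3 attribute carrying the miR name (default `"Name"`).
#' @return data.frame with columns `mir_id`, `chrom`, `strand`, `start`,
#'   `end`, `seed_start`, `seed_end` (all coordinates 1-based inclusive).
#' @export
read_mirbase_gff <- function(path, feature = "miRNA", name_attr = "Name") {
  if (!file.exists(path)) stop("cannot read GFF3 file: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1]]
    stop("malformed GFF3 record at line ", bad, " of ", path,
         " (expected 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  if (length(gr) == 0) {
    return(data.frame(mir_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), seed_start = integer(),
                      seed_end = integer(), stringsAsFactors = FALSE))
  }
  nm <- S4Vectors::mcols(gr)[[name_attr]]
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  nm <- as.character(nm)
  if (anyNA(nm) || any(!nzchar(nm))) {
    i <- which(is.na(nm) | !nzchar(nm))[1]
    stop("mature miRNA record ", i, " (",
         as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i], ") lacks attribute '", name_attr, "'")
  }
  rec <- data.frame(
    mir_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(!rec$strand %in% c("+", "-"))) {
    stop("mature miRNA records must be stranded (+ or -)")
  }
  len <- rec$end - rec$start + 1
  if (any(len < 15 | len > 30)) {
    stop("mature miR length outside 15-30 nt for: ",
         paste(rec$mir_id[len < 15 | len > 30], collapse = ", "))
  }
  plus <- rec$strand == "+"
  rec$seed_start <- ifelse(plus, rec$start + 1L, rec$end - 7L)
  rec$seed_end <- ifelse(plus, rec$start + 7L, rec$end - 1L)
  rec
}

#' Read mapped small-RNA alignments from a SAM file
#'
#' Converts the SAM to BAM internally (via Rsamtools) and returns one row per
#' mapped alignment record with its UMI (extracted from the read name), the
#' aligned reference span, strand, and number of genomic hits. `n_hits` is
#' taken from the `NH` tag when present; otherwise it falls back to the
#' multiplicity of the read id within the file.
#'
#' @param path SAM file with a valid header.
#' @param umi_pattern regex with one capture group extracting the UMI from the
#'   read name. Default: the last `_`-delimited token.
#' @return data.frame with columns `read_id`, `umi`, `chrom`, `strand`,
#'   `start`, `end`, `n_hits` (coordinates 1-based inclusive).
#' @export
read_alignments <- function(path, umi_pattern = "_([^_]+)$") {
  if (!file.exists(path)) stop("cannot read SAM file: ", path)
  dest <- tempfile(fileext = "")
  bam <- tryCatch(
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE),
    error = function(e) stop("failed to read SAM file '", path, "': ",
                             conditionMessage(e))
  )
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(what = "qname", tag = "NH")
  gal <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam),
                                            param = param)
  qname <- S4Vectors::mcols(gal)$qname
  nh <- S4Vectors::mcols(gal)$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(gal))
  if (anyNA(nh)) {
    mult <- table(qname)
    nh[is.na(nh)] <- as.integer(mult[qname[is.na(nh)]])
  }
  m <- regexec(umi_pattern, qname)
  umi <- vapply(regmatches(qname, m), function(g) {
    if (length(g) >= 2) g[2] else NA_character_
  }, character(1))
  if (anyNA(umi) || any(!nzchar(umi))) {
    bad <- qname[is.na(umi) | !nzchar(umi)][1]
    stop("cannot extract UMI from read name '", bad,
         "' with pattern '", umi_pattern, "'")
  }
  data.frame(
    read_id = qname,
    umi = umi,
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    strand = as.character(GenomicAlignments::strand(gal)),
    start = GenomicAlignments::start(gal),
    end = GenomicAlignments::end(gal),
    n_hits = as.integer(nh),
    stringsAsFactors = FALSE
  )
}

#' Read / write a miR x sample count matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first column is
#' `mir_id`; remaining columns are samples. Integer values round-trip
#' exactly.
#'
#' @param path TSV file.
#' @return `read_count_matrix`: integer matrix with miR rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "mir_id") {
    stop("count matrix must have 'mir_id' as its first column")
  }
  if (anyDuplicated(df$mir_id)) {
    stop("duplicate miR ids in ", path, ": ",
         paste(unique(df$mir_id[duplicated(df$mir_id)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mir_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_count_matrix
#' @param x matrix (or `mir_counts`, whose counts are written).
#' @export
write_count_matrix <- function(x, path) {
  if (inherits(x, "mir_counts")) x <- x$counts
  df <- data.frame(mir_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' TSV with columns `sample_id`, `subject`, `compartment` (MB/EV),
#' `treatment`.
#'
#' @param path TSV file.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  samples <- validate_sample_sheet(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pathway -> miR sets from a GMT-like TSV
#'
#' Each line: pathway name, description, then one miR id per field.
#' Duplicate ids within a set are collapsed; empty sets are an error.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    stop("empty pathway set(s): ", paste(names(sets)[empty], collapse = ", "))
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate pathway names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets
}

#' Write a results table as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_results_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
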