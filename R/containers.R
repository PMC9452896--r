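#' miR count matrix with sample metadata
#'
#' Container pairing a non-negative integer matrix of deduplicated molecule
#' counts (rows = mature miRs, columns = samples) with its sample sheet.
#' This is the object every downstream stage (filtering, normalization,
#' differential expression, correlation) consumes.
#'
#' @param counts numeric matrix of non-negative integers with unique rownames
#'   (miR identifiers). Column names, if present, must equal
#'   `samples$sample_id`.
#' @param samples data.frame with columns `sample_id`, `subject`,
#'   `compartment` (`"MB"` or `"EV"`) and `treatment`; one row per column of
#'   `counts`, in column order.
#' @return An object of class `"mir_counts"`: a list with elements `counts`
#'   and `samples`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), 2, 2,
#'             dimnames = list(c("miR-1", "miR-2"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), subject = c("A", "A"),
#'                     compartment = c("MB", "EV"), treatment = "CTL")
#' mir_counts(m, sheet)
#' @export
mir_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  samples <- validate_sample_sheet(samples)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) {
      stop("`counts` must have miR identifiers as rownames")
    }
    rownames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate miR ids in count matrix: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (ncol(counts) != nrow(samples)) {
    stop("count matrix has ", ncol(counts), " columns but sample sheet has ",
         nrow(samples), " rows")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- samples$sample_id
  } else if (!identical(colnames(counts), samples$sample_id)) {
    bad <- union(setdiff(colnames(counts), samples$sample_id),
                 setdiff(samples$sample_id, colnames(counts)))
    stop("count matrix columns and sample sheet disagree: ",
         paste(bad, collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be finite non-negative integers")
  }
  counts <- round(counts)
  structure(list(counts = counts, samples = samples), class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts: ", nrow(x$counts), " miRs x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("compartments:", paste(sort(unique(x$samples$compartment)),
                             collapse = ", "), "\n")
  cat("treatments:  ", paste(levels(factor(x$samples$treatment)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mir_counts <- function(x) dim(x$counts)

# Subset a mir_counts by miR ids and/or sample ids (internal).
subset_mir_counts <- function(x, mirs = NULL, sample_ids = NULL) {
  counts <- x$counts
  samples <- x$samples
  if (!is.null(mirs)) counts <- counts[mirs, , drop = FALSE]
  if (!is.null(sample_ids)) {
    keep <- match(sample_ids, samples$sample_id)
    if (anyNA(keep)) {
      stop("unknown sample ids: ",
           paste(sample_ids[is.na(keep)], collapse = ", "))
    }
    counts <- counts[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    rownames(samples) <- NULL
  }
  mir_counts(counts, samples)
}

# Shared sample-sheet validation used by mir_counts() and read_sample_sheet().
validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject", "compartment", "treatment")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  samples <- samples[, need]
  for (col in need) samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(samples$compartment), c("MB", "EV"))
  if (length(bad)) {
    stop("compartment must be 'MB' or 'EV'; found: ",
         paste(bad, collapse = ", "))
  }
  key <- paste(samples$subject, samples$compartment, samples$treatment)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, compartment, treatment) combination: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(samples) <- NULL
  samples
}

# Order treatment levels with CTL first when present (reference condition).
treatment_levels <- function(treatment) {
  canon <- c("CTL", "CLFS", "IHFS")
  u <- unique(treatment)
  c(intersect(canon, u), sort(setdiff(u, canon)))
}
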