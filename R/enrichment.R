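#' Hypergeometric over-representation analysis of a miR hit set
#'
#' For each pathway set (intersected with the universe first), reports the
#' observed overlap with the hits, the expected overlap
#' `|hits| * |pathway| / |universe|`, and the upper-tail hypergeometric
#' probability `P(X >= observed)`. The universe is the pre-filter reference
#' set (every miR identified in the raw data), so filtering does not bias
#' the background. Rows are sorted by observed count (descending), ties
#' broken by ascending p. Unadjusted p-values by default.
#'
#' @param hits character vector of significant miR ids (must be a subset of
#'   `universe`).
#' @param universe character vector of reference miR ids.
#' @param pathways named list of miR id sets (from [read_gmt()]).
#' @param add_fdr append a Benjamini-Hochberg `fdr` column.
#' @return data.frame: `pathway`, `pathway_size` (within universe),
#'   `observed`, `expected`, `p_value`.
#' @examples
#' ora_hypergeometric(paste0("m", 1:5), paste0("m", 1:10),
#'                    list(pathA = paste0("m", 1:4)))
#' @export
ora_hypergeometric <- function(hits, universe, pathways, add_fdr = FALSE) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    stop("hit id(s) not in the universe: ", paste(outside, collapse = ", "))
  }
  if (!is.list(pathways) || is.null(names(pathways))) {
    stop("`pathways` must be a named list of id sets")
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(pathways), function(pw) {
    K <- length(intersect(pathways[[pw]], universe))
    obs <- length(intersect(hits, intersect(pathways[[pw]], universe)))
    p <- stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, pathway_size = K, observed = obs,
               expected = n * K / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$observed, out$p_value, out$pathway), , drop = FALSE]
  if (add_fdr) out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
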