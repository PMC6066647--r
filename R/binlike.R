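# BIN-style clustering surrogate.
#
# The Barcode Index Number (RESL) algorithm behind BOLD is not published in
# implementable detail; this surrogate follows the BIN literature's
# single-linkage seed threshold of 2.2% and refines each cluster by a
# gap scan, and is documented as a stand-in, not a reimplementation.

#' BIN-style partition (single linkage + gap refinement)
#'
#' Stage 1 forms single-linkage clusters at the seed threshold (default
#' 2.2%). Stage 2 re-runs the ranked-distance gap scan within each cluster;
#' when a significant gap at least as wide as the seed threshold splits a
#' cluster, the cluster is split and the refinement recurses. Deterministic
#' and invariant to specimen order.
#'
#' @param matrix a `motu_dist` (p-distance or K2P) or symmetric matrix with
#'   dimnames.
#' @param threshold seed clustering threshold (substitutions/site).
#' @param relative_gap_width gap-width multiplier X for the refinement scan.
#' @param window sliding window size for the gap scan.
#' @return a `motu_partition` with method `"BINlike"`.
#' @export
binlike_partition <- function(matrix, threshold = 0.022,
                              relative_gap_width = 1.0, window = 10L) {
  d <- if (inherits(matrix, "motu_dist")) matrix$values else as.matrix(matrix)
  ids <- rownames(d)
  n <- nrow(d)
  if (n == 0L) stop("empty distance matrix")
  refine <- function(idx) {
    if (length(idx) <= 2L) return(list(idx))
    sub <- d[idx, idx, drop = FALSE]
    dsort <- sort(sub[upper.tri(sub)])
    # only gaps at least as wide as the seed threshold are honored
    thr <- find_gap_threshold(dsort, P = 0, X = relative_gap_width,
                              W = window, min_gap = threshold)
    if (is.na(thr)) return(list(idx))
    comp <- linkage_components(sub, thr)
    if (length(unique(comp)) == 1L) return(list(idx))
    unlist(lapply(sort(unique(comp)),
                  function(g) refine(idx[comp == g])), recursive = FALSE)
  }
  comp <- linkage_components(d, threshold)
  groups <- unlist(lapply(sort(unique(comp)),
                          function(g) refine(which(comp == g))),
                   recursive = FALSE)
  assign <- integer(n)
  for (k in seq_along(groups)) assign[groups[[k]]] <- k
  names(assign) <- ids
  motu_partition(assign, method = "BINlike",
                 parameters = list(threshold = threshold,
                                   X = relative_gap_width))
}
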