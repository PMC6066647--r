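# Neighbor-joining (Saitou & Nei) with deterministic tie-breaking and
# non-negative branch lengths.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration on the Q-criterion. Ties in the Q matrix are
#' broken deterministically by the lexicographically smallest (sorted) pair
#' of member ids. Negative branch-length estimates are clamped to zero with
#' the deficit transferred to the sibling edge, so the path length between
#' the joined pair is preserved.
#'
#' @param matrix a `motu_dist`, or a symmetric numeric matrix with
#'   dimnames.
#' @return an unrooted `phylo` tree (ape) with branch lengths in
#'   substitutions/site.
#' @export
neighbor_joining <- function(matrix) {
  d <- if (inherits(matrix, "motu_dist")) matrix$values else as.matrix(matrix)
  if (is.null(rownames(d))) stop("distance matrix must have ids as dimnames")
  if (any(is.na(d))) stop("distance matrix contains NA (saturated?) entries")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  ids <- rownames(d)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 specimens for neighbor joining")
  # active clusters: newick fragments + the id used for tie-breaking
  frag <- ids
  minid <- ids
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3L) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(minid[ij[1L]], minid[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    newmin <- min(minid[i], minid[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    minid <- c(minid[keep], newmin)
    n <- n - 1L
  }
  # connect the last three by the three-point formulas
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb), ",",
                frag[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Clade exclusivity (monophyly) per morphospecies
#'
#' A species is exclusive when some edge bipartition of the (unrooted) tree
#' isolates exactly its specimens; singletons count as exclusive. Invariant
#' to re-rooting.
#'
#' @param tree a `phylo` whose tip labels are specimen ids (a subset of the
#'   library's ids).
#' @param library the `barcode_library` supplying morphospecies labels.
#' @return list with `per_species` (named logical) and `fraction`.
#' @export
clade_exclusivity <- function(tree, library) {
  stopifnot(inherits(tree, "phylo"))
  rec <- library$records
  if (!all(tree$tip.label %in% rec$specimen_id))
    stop("tree tips must be a subset of library specimen ids")
  labels <- rec$morphospecies[match(tree$tip.label, rec$specimen_id)]
  species <- unique(labels)
  per <- vapply(species, function(sp) {
    tips <- tree$tip.label[labels == sp]
    if (length(tips) <= 1L) return(TRUE)
    other <- setdiff(tree$tip.label, tips)
    if (length(other) == 0L) return(TRUE)
    ape::is.monophyletic(tree, tips) || ape::is.monophyletic(tree, other)
  }, logical(1L))
  list(per_species = per, fraction = mean(per))
}

#' Write a tree as Newick with 6 significant digits
#' @param tree a `phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
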