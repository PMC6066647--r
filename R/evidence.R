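# Assemble species evidence from pipeline outputs (library, distances,
# tree, partitions) for the congruence layer.

# number of maximal species-pure clades covering a species' tips
count_pure_clades <- function(tree, tips) {
  if (length(tips) <= 1L) return(length(tips))
  labels <- tree$tip.label
  ntip <- length(labels)
  in_sp <- labels %in% tips
  po <- ape::reorder.phylo(tree, "postorder")$edge
  nnode <- ntip + tree$Nnode
  pure <- c(in_sp, rep(TRUE, tree$Nnode))
  has <- c(in_sp, rep(FALSE, tree$Nnode))
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]; v <- po[k, 2L]
    pure[p] <- pure[p] && pure[v]
    has[p] <- has[p] || has[v]
  }
  # maximal pure nodes: pure, containing >=1 focal tip, parent impure
  parent <- rep(NA_integer_, nnode)
  parent[po[, 2L]] <- po[, 1L]
  maximal <- which(pure & has &
                   (is.na(parent) | !pure[ifelse(is.na(parent), 1L, parent)]))
  length(maximal)
}

#' Build species evidence from a full pipeline run
#'
#' Combines the distance summaries, the guide tree and the three method
#' partitions into one [species_evidence()] row per morphospecies, ready for
#' [flag_species()]. Cluster sharing and exclusivity are read from the
#' BIN-like partition (the reference clustering, mirroring BIN-centric
#' survey workflows); cluster counts come from each method separately.
#'
#' @param library a `barcode_library`.
#' @param matrix the model `motu_dist` for the library.
#' @param tree optional guide tree (`phylo`) for the clade count column.
#' @param bin_partition,abgd_partition,bptp_partition `motu_partition`
#'   objects from the three delimitation methods.
#' @param min_n_intra minimum specimens for intraspecific estimates.
#' @return data frame of evidence rows.
#' @export
build_evidence <- function(library, matrix, tree = NULL,
                           bin_partition, abgd_partition, bptp_partition,
                           min_n_intra = 3L) {
  rec <- library$records
  summ <- species_summaries(matrix, library, min_n_intra = min_n_intra)
  status <- rec$nomenclature_status[match(summ$morphospecies,
                                          rec$morphospecies)]
  parts <- list(bin = bin_partition, abgd = abgd_partition,
                bptp = bptp_partition)
  described_of <- function(labels)
    labels[rec$nomenclature_status[match(labels, rec$morphospecies)] ==
             "described"]
  rows <- lapply(seq_len(nrow(summ)), function(i) {
    sp <- summ$morphospecies[i]
    ids <- rec$specimen_id[rec$morphospecies == sp]
    counts <- vapply(parts, function(p)
      length(unique(p$assignment[ids])), integer(1L))
    # cluster composition under the reference (BIN-like) partition
    ref <- parts$bin
    cl_ids <- unique(ref$assignment[ids])
    shares_nominal <- FALSE; shares_any <- FALSE; n_excl <- 0L
    for (cid in cl_ids) {
      members <- names(ref$assignment)[ref$assignment == cid]
      other_labels <- setdiff(
        unique(rec$morphospecies[match(members, rec$specimen_id)]), sp)
      if (length(other_labels)) shares_any <- TRUE
      if (length(described_of(other_labels))) shares_nominal <- TRUE
      else n_excl <- n_excl + 1L
    }
    species_evidence(
      morphospecies = sp, nomenclature_status = status[i],
      max_intra = summ$max_intra[i], mean_intra = summ$mean_intra[i],
      n_clades = if (!is.null(tree)) count_pure_clades(
        tree, rec$specimen_id[rec$morphospecies == sp]) else NA_integer_,
      n_bin = counts[["bin"]], n_abgd = counts[["abgd"]],
      n_bptp = counts[["bptp"]],
      shares_cluster_with_nominal = shares_nominal,
      n_exclusive = n_excl, shares_any = shares_any,
      nn_species = summ$nn_species[i], nn_distance = summ$nn_distance[i],
      max_similarity = summ$max_similarity[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
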