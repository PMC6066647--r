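# Concordance of clusters with morphology.

#' Classify clusters as concordant, discordant or singleton
#'
#' A cluster is a singleton when it holds one specimen, concordant when it
#' holds two or more specimens of a single morphospecies, and discordant
#' when it mixes two or more morphospecies.
#'
#' @param partition a `motu_partition` covering the library.
#' @param library the `barcode_library`.
#' @return list with `labels` (data frame: cluster_id, label, n_specimens,
#'   n_species, member_species) and `counts` (named vector concordant /
#'   discordant / singleton).
#' @export
classify_concordance <- function(partition, library) {
  rec <- library$records
  ids <- names(partition$assignment)
  if (!setequal(ids, rec$specimen_id))
    stop("partition does not cover the library")
  sp <- rec$morphospecies[match(ids, rec$specimen_id)]
  cl <- split(sp, partition$assignment)
  rows <- lapply(names(cl), function(cid) {
    members <- sort(unique(cl[[cid]]))
    n <- length(cl[[cid]])
    label <- if (n == 1L) "singleton"
             else if (length(members) == 1L) "concordant" else "discordant"
    data.frame(cluster_id = cid, label = label, n_specimens = n,
               n_species = length(members),
               member_species = paste(members, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  counts <- c(concordant = sum(labels$label == "concordant"),
              discordant = sum(labels$label == "discordant"),
              singleton = sum(labels$label == "singleton"))
  list(labels = labels, counts = counts)
}
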