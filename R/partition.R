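# MOTU partitions: assignment of specimens to clusters, tagged by method.

#' Construct a MOTU partition
#'
#' Cluster ids are canonicalized to the lexicographically smallest specimen
#' id in each cluster, which makes partitions invariant to specimen order.
#'
#' @param assignment named vector mapping specimen id to cluster.
#' @param method producing method label.
#' @param parameters list of parameters used.
#' @return a `motu_partition`.
#' @export
motu_partition <- function(assignment, method = "truth", parameters = list()) {
  stopifnot(!is.null(names(assignment)), !anyDuplicated(names(assignment)))
  ids <- names(assignment)
  canon <- ave(ids, as.character(assignment), FUN = min)
  names(canon) <- ids
  structure(list(method = method, assignment = canon, parameters = parameters),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("motu_partition [", x$method, "]: ", length(x$assignment),
      " specimens in ", n_clusters(x), " clusters\n", sep = "")
  invisible(x)
}

#' Number of clusters in a partition
#' @param partition a `motu_partition`.
#' @export
n_clusters <- function(partition) length(unique(partition$assignment))

#' Clusters as a list of specimen-id vectors
#' @param partition a `motu_partition`.
#' @export
clusters <- function(partition) {
  out <- split(names(partition$assignment), partition$assignment)
  lapply(out, sort)
}

#' Do two partitions induce the same clustering?
#' @param a,b `motu_partition` objects over the same specimens.
#' @export
same_partition <- function(a, b) {
  ia <- a$assignment[sort(names(a$assignment))]
  ib <- b$assignment[sort(names(b$assignment))]
  identical(names(ia), names(ib)) && identical(unname(ia), unname(ib))
}

#' Rand index between two partitions
#'
#' Fraction of specimen pairs on which the two partitions agree
#' (co-clustered in both or separated in both).
#'
#' @param a,b `motu_partition` objects over the same specimens.
#' @export
rand_index <- function(a, b) {
  ids <- sort(names(a$assignment))
  stopifnot(setequal(ids, names(b$assignment)))
  ca <- a$assignment[ids]; cb <- b$assignment[ids]
  n <- length(ids)
  if (n < 2L) return(1)
  agree <- 0L; total <- 0L
  for (i in 1:(n - 1L)) {
    sa <- ca[i] == ca[(i + 1L):n]
    sb <- cb[i] == cb[(i + 1L):n]
    agree <- agree + sum(sa == sb)
    total <- total + (n - i)
  }
  agree / total
}

#' Export partitions as a long TSV
#' @param partitions list of `motu_partition` objects.
#' @param path output path.
#' @export
write_partitions <- function(partitions, path) {
  rows <- lapply(partitions, function(p)
    data.frame(specimen_id = names(p$assignment), method = p$method,
               cluster_id = unname(p$assignment), stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# single-linkage components of the graph linking pairs with d <= threshold
linkage_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(d[i, ] <= threshold)
      m <- min(comp[nb], comp[i])
      if (any(comp[c(i, nb)] != m)) {
        comp[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}
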