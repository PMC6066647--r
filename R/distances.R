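# Pairwise evolutionary distances with pairwise deletion.
#
# Sequences are compared site by site; a site enters a pair's comparison only
# when both sequences carry an unambiguous A/C/G/T there (gaps and IUPAC
# ambiguity codes are deleted pairwise, the BOLD/MEGA default).

BASE4 <- c(A = 1L, C = 2L, G = 3L, T = 4L)
# transition partner: A<->G, C<->T
TS_PARTNER <- c(3L, 4L, 1L, 2L)

encode_seq <- function(s) {
  chars <- strsplit(toupper(s), "")[[1L]]
  m <- BASE4[chars]
  unname(m) # NA for gaps/ambiguities
}

pair_counts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) return(c(n = 0L, ts = 0L, tv = 0L))
  aa <- a[ok]; bb <- b[ok]
  diff <- aa != bb
  ts <- sum(diff & (TS_PARTNER[aa] == bb))
  c(n = n, ts = ts, tv = sum(diff) - ts)
}

k2p_from_pq <- function(P, Q) {
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (arg <= 0) return(c(d = NA_real_, saturated = 1))
  c(d = -0.5 * log(arg), saturated = 0)
}

jc69_from_p <- function(p) {
  arg <- 1 - 4 * p / 3
  if (arg <= 0) return(c(d = NA_real_, saturated = 1))
  c(d = -0.75 * log(arg), saturated = 0)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K2P distance `d = -1/2 log[(1 - 2P - Q) sqrt(1 - 2Q)]`, where
#' `P` and `Q` are the transition and transversion proportions over the
#' pairwise-deleted sites. When the logarithm's argument is non-positive the
#' distance is saturated and reported as `NA` with `saturated = TRUE`.
#'
#' @param seq_a,seq_b aligned IUPAC DNA strings of equal length.
#' @return list with `distance`, `stats` (a data frame holding `P`, `Q`,
#'   `n_sites`) and `saturated`.
#' @examples
#' a <- strrep("A", 100)
#' b <- paste0(strrep("G", 10), strrep("A", 90)) # 10 transitions
#' pairwise_k2p(a, b)$distance  # -0.5 * log(0.8)
#' @export
pairwise_k2p <- function(seq_a, seq_b) {
  a <- encode_seq(seq_a); b <- encode_seq(seq_b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ct <- pair_counts(a, b)
  if (ct["n"] == 0L) stop("no comparable sites after pairwise deletion")
  P <- ct[["ts"]] / ct[["n"]]; Q <- ct[["tv"]] / ct[["n"]]
  k <- k2p_from_pq(P, Q)
  list(distance = unname(k["d"]),
       stats = data.frame(P = P, Q = Q, n_sites = ct[["n"]]),
       saturated = k[["saturated"]] == 1)
}

#' Jukes-Cantor (JC69) distance between two aligned sequences
#'
#' `d = -3/4 log(1 - 4p/3)` with `p` the mismatch proportion over
#' pairwise-deleted sites; saturated (NA) when `p >= 3/4`.
#'
#' @inheritParams pairwise_k2p
#' @return list with `distance`, `p`, `n_sites`, `saturated`.
#' @export
pairwise_jc69 <- function(seq_a, seq_b) {
  a <- encode_seq(seq_a); b <- encode_seq(seq_b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ct <- pair_counts(a, b)
  if (ct["n"] == 0L) stop("no comparable sites after pairwise deletion")
  p <- (ct[["ts"]] + ct[["tv"]]) / ct[["n"]]
  j <- jc69_from_p(p)
  list(distance = unname(j["d"]), p = p, n_sites = ct[["n"]],
       saturated = j[["saturated"]] == 1)
}

#' Build a pairwise distance matrix for a library
#'
#' @param library a `barcode_library`.
#' @param model `"K2P"`, `"JC69"` or `"p"` (raw mismatch proportion).
#' @return a `motu_dist` object: list with `ids`, `model`, `values`
#'   (symmetric distance matrix, `NA` where saturated), `site_counts`,
#'   `saturated` (logical matrix).
#' @export
build_matrix <- function(library, model = c("K2P", "JC69", "p")) {
  stopifnot(inherits(library, "barcode_library"))
  model <- match.arg(model)
  ids <- names(library$sequences)
  n <- length(ids)
  if (n == 0L) stop("empty library")
  enc <- lapply(library$sequences, encode_seq)
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ct <- pair_counts(enc[[i]], enc[[j]])
    if (ct["n"] == 0L)
      stop("no comparable sites between ", ids[i], " and ", ids[j])
    P <- ct[["ts"]] / ct[["n"]]; Q <- ct[["tv"]] / ct[["n"]]
    res <- switch(model,
                  K2P = k2p_from_pq(P, Q),
                  JC69 = jc69_from_p(P + Q),
                  p = c(d = P + Q, saturated = 0))
    values[i, j] <- values[j, i] <- res[["d"]]
    sites[i, j] <- sites[j, i] <- ct[["n"]]
    sat[i, j] <- sat[j, i] <- res[["saturated"]] == 1
  }
  diag(sites) <- vapply(enc, function(e) sum(!is.na(e)), integer(1L))
  structure(list(ids = ids, model = model, values = values,
                 site_counts = sites, saturated = sat),
            class = "motu_dist")
}

#' @export
print.motu_dist <- function(x, ...) {
  cat("motu_dist:", length(x$ids), "specimens, model", x$model, "\n")
  invisible(x)
}

# pooled pairwise distances for specimens sharing a label at a given rank
rank_pairs <- function(matrix, labels) {
  vals <- matrix$values
  n <- length(matrix$ids)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (!is.na(labels[i]) && !is.na(labels[j]) && labels[i] == labels[j])
      out <- c(out, vals[i, j])
  out
}

#' Distance summaries by taxonomic rank
#'
#' Pools all pairwise distances whose two specimens share a label at each
#' rank (species = morphospecies, genus, family) and reports min/mean/max as
#' percentages, mirroring the usual barcode-survey "distance summary" table.
#'
#' @param matrix a `motu_dist`.
#' @param library the `barcode_library` the matrix was built from.
#' @param digits decimal places for the percentage columns.
#' @return data frame with columns `rank`, `n_pairs`, `min`, `mean`, `max`.
#' @export
summarize_ranks <- function(matrix, library, digits = 2L) {
  stopifnot(inherits(matrix, "motu_dist"), inherits(library, "barcode_library"))
  rec <- library$records[match(matrix$ids, library$records$specimen_id), ]
  ranks <- list(species = rec$morphospecies, genus = rec$genus,
                family = rec$family)
  rows <- lapply(names(ranks), function(rk) {
    d <- rank_pairs(matrix, ranks[[rk]])
    d <- d[!is.na(d)]
    if (length(d) == 0L) {
      warning("no comparable pair at rank ", rk, "; summary omitted")
      return(NULL)
    }
    data.frame(rank = rk, n_pairs = length(d),
               min = round(100 * min(d), digits),
               mean = round(100 * mean(d), digits),
               max = round(100 * max(d), digits))
  })
  do.call(rbind, rows)
}

#' Histogram of per-taxon maximum divergence
#'
#' Bins the maximum within-taxon divergence (per morphospecies or per genus)
#' and reports bin counts plus the cumulative fraction of taxa below 1% and
#' 2% — the classic barcode-gap histogram.
#'
#' @param matrix a `motu_dist`.
#' @param library the corresponding `barcode_library`.
#' @param rank `"species"` or `"genus"`.
#' @param bin_width bin width in percent.
#' @return list with `table` (bin_low, bin_high, count), `fraction_below_1`,
#'   `fraction_below_2`, `n_taxa`.
#' @export
divergence_histogram <- function(matrix, library, rank = c("species", "genus"),
                                 bin_width = 1) {
  rank <- match.arg(rank)
  rec <- library$records[match(matrix$ids, library$records$specimen_id), ]
  labels <- if (rank == "species") rec$morphospecies else rec$genus
  taxa <- unique(labels[!is.na(labels)])
  maxd <- vapply(taxa, function(t) {
    idx <- which(labels == t)
    if (length(idx) < 2L) return(0)
    sub <- matrix$values[idx, idx]
    m <- suppressWarnings(max(sub[upper.tri(sub)], na.rm = TRUE))
    if (!is.finite(m)) 0 else 100 * m
  }, numeric(1L))
  top <- max(maxd, bin_width)
  breaks <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  counts <- as.integer(table(cut(maxd, breaks, include.lowest = TRUE,
                                 right = FALSE)))
  # cut() with right=FALSE drops values equal to the last break; guard
  counts[length(counts)] <- counts[length(counts)] + sum(maxd == breaks[length(breaks)])
  list(table = data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1L], count = counts),
       fraction_below_1 = mean(maxd < 1),
       fraction_below_2 = mean(maxd < 2),
       n_taxa = length(taxa))
}

#' Per-morphospecies summaries: intraspecific divergence, nearest neighbor,
#' barcode gap
#'
#' For each morphospecies reports the maximum and mean intraspecific
#' distance (undefined for species with fewer than `min_n_intra` specimens),
#' the nearest-neighbor (heterospecific) species and distance, the barcode
#' gap indicator (`nn_distance - max_intra`), and the maximum similarity
#' `100 * (1 - min p-distance to any heterospecific)`.
#'
#' @param matrix a `motu_dist` (model distances used for NND).
#' @param library the corresponding `barcode_library`.
#' @param min_n_intra minimum specimens for intraspecific summaries
#'   (species with fewer get `NA`, mirroring survey practice of excluding
#'   1-2 specimen species).
#' @param p_matrix optional precomputed `motu_dist` with `model = "p"` used
#'   for the similarity column; built from the library when `NULL`.
#' @return data frame, one row per morphospecies.
#' @export
species_summaries <- function(matrix, library, min_n_intra = 3L,
                              p_matrix = NULL) {
  rec <- library$records[match(matrix$ids, library$records$specimen_id), ]
  labels <- rec$morphospecies
  species <- unique(labels)
  if (length(species) < 2L) stop("need at least two morphospecies")
  if (is.null(p_matrix)) p_matrix <- build_matrix(library, "p")
  pv <- p_matrix$values[matrix$ids, matrix$ids]
  vals <- matrix$values
  rows <- lapply(species, function(sp) {
    idx <- which(labels == sp); oth <- which(labels != sp)
    n <- length(idx)
    if (n >= min_n_intra) {
      sub <- vals[idx, idx][upper.tri(matrix(0, n, n))]
      max_intra <- 100 * max(sub, na.rm = TRUE)
      mean_intra <- 100 * mean(sub, na.rm = TRUE)
    } else max_intra <- mean_intra <- NA_real_
    cross <- vals[idx, oth, drop = FALSE]
    j <- which(cross == min(cross, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    nn_distance <- 100 * cross[j[1L], j[2L]]
    nn_species <- labels[oth[j[2L]]]
    max_similarity <- 100 * (1 - min(pv[idx, oth], na.rm = TRUE))
    data.frame(morphospecies = sp, n_specimens = n, max_intra = max_intra,
               mean_intra = mean_intra, nn_species = nn_species,
               nn_distance = nn_distance,
               barcode_gap = nn_distance - max_intra,
               max_similarity = max_similarity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a distance matrix
#'
#' @param matrix a `motu_dist`.
#' @param path output file.
#' @param format `"phylip"` (square matrix) or `"long"` (TSV columns
#'   id_a, id_b, model, distance, n_sites).
#' @return invisibly, `path`.
#' @export
write_matrix <- function(matrix, path, format = c("phylip", "long")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(matrix$ids)), con)
    for (i in seq_along(matrix$ids))
      writeLines(paste(c(sprintf("%-10s", matrix$ids[i]),
                         sprintf("%.8f", matrix$values[i, ])),
                       collapse = " "), con)
  } else {
    n <- length(matrix$ids)
    iu <- which(upper.tri(matrix$values), arr.ind = TRUE)
    df <- data.frame(id_a = matrix$ids[iu[, 1L]], id_b = matrix$ids[iu[, 2L]],
                     model = matrix$model,
                     distance = matrix$values[iu],
                     n_sites = matrix$site_counts[iu])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
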