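# Automatic Barcode Gap Discovery (recursive gap partitioning of a distance
# matrix beyond a prior intraspecific limit P).

#' ABGD configuration
#'
#' @param p_min,p_max bounds of the prior maximal intraspecific distance
#'   sweep.
#' @param n_steps number of log-spaced priors between `p_min` and `p_max`.
#' @param relative_gap_width the gap-width multiplier X: a gap in the ranked
#'   distances is significant when it exceeds X times the mean gap width in
#'   the preceding window.
#' @param window number of preceding ranked gaps in the sliding window.
#' @param model distance model label recorded with the output.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, n_steps = 20L,
                        relative_gap_width = 1.0, window = 10L,
                        model = "K2P") {
  stopifnot(p_min > 0, p_min < p_max, p_max < 1, relative_gap_width > 0,
            n_steps >= 1L, window >= 1L)
  list(p_min = p_min, p_max = p_max, n_steps = n_steps,
       relative_gap_width = relative_gap_width, window = window,
       model = model)
}

# Find the first significant gap in sorted distances above prior P.
# Returns the midpoint threshold, or NA when no gap is found.
# Gaps are scanned between consecutive ranked distances whose upper member
# exceeds P; the window of preceding gaps may dip below P (that is what lets
# the first supra-prior jump register against the intra-prior gap scale).
find_gap_threshold <- function(dsort, P, X, W, min_window = 3L,
                               min_gap = 0) {
  m <- length(dsort)
  if (m < 2L) return(NA_real_)
  gaps <- diff(dsort)
  for (i in seq_len(m - 1L)) {
    if (dsort[i + 1L] <= P) next
    lo <- max(1L, i - W)
    if (i - lo < min_window) next
    prev <- gaps[lo:(i - 1L)]
    if (gaps[i] > X * mean(prev) && gaps[i] > 0 && gaps[i] >= min_gap)
      return((dsort[i] + dsort[i + 1L]) / 2)
  }
  NA_real_
}

abgd_split <- function(d, P, X, W) {
  n <- nrow(d)
  if (n <= 2L) return(rep(1L, n))
  dsort <- sort(d[upper.tri(d)])
  thr <- find_gap_threshold(dsort, P, X, W)
  if (is.na(thr)) return(rep(1L, n))
  comp <- linkage_components(d, thr)
  if (length(unique(comp)) == 1L) return(comp)
  # recurse within each group
  out <- integer(n)
  next_id <- 0L
  for (g in sort(unique(comp))) {
    idx <- which(comp == g)
    sub <- abgd_split(d[idx, idx, drop = FALSE], P, X, W)
    out[idx] <- next_id + sub
    next_id <- next_id + max(sub)
  }
  out
}

#' ABGD partition sweep
#'
#' For each prior maximal intraspecific distance P in a log-spaced sweep:
#' ranks all pairwise distances, scans for the first significant gap above
#' the prior region (gap width > X times the mean gap width in the sliding
#' window of the preceding `window` ranked distances), thresholds at the gap
#' midpoint, forms single-linkage groups, and recurses within each group
#' until no further gap is found. Deterministic.
#'
#' @param matrix a `motu_dist` or symmetric matrix with dimnames.
#' @param config an [abgd_config()].
#' @return data frame-like list: one element per prior with fields `prior`,
#'   `partition` (a `motu_partition`), `n_groups`. Class `abgd_sweep`.
#' @export
abgd_partition <- function(matrix, config = abgd_config()) {
  d <- if (inherits(matrix, "motu_dist")) matrix$values else as.matrix(matrix)
  if (nrow(d) == 0L) stop("empty distance matrix")
  if (nrow(d) < 2L) stop("need at least 2 specimens")
  if (any(is.na(d))) stop("distance matrix contains NA entries")
  ids <- rownames(d)
  priors <- exp(seq(log(config$p_min), log(config$p_max),
                    length.out = config$n_steps))
  out <- lapply(priors, function(P) {
    grp <- abgd_split(d, P, config$relative_gap_width, config$window)
    names(grp) <- ids
    part <- motu_partition(grp, method = "ABGD",
                           parameters = list(prior = P,
                                             X = config$relative_gap_width))
    list(prior = P, partition = part, n_groups = n_clusters(part))
  })
  structure(out, class = "abgd_sweep")
}

#' @export
print.abgd_sweep <- function(x, ...) {
  cat("ABGD sweep:", length(x), "priors, group counts",
      paste(range(vapply(x, `[[`, 0L, "n_groups")), collapse = "-"), "\n")
  invisible(x)
}

#' Select the ABGD partition most consistent with a companion partition
#'
#' Mirrors the survey practice of retaining, from the ABGD prior sweep, the
#' partition that best agrees with an independent clustering (e.g. the
#' BIN-style partition), by maximum Rand index; ties go to the smaller
#' prior P.
#'
#' @param abgd_output an `abgd_sweep` from [abgd_partition()].
#' @param companion a `motu_partition` over the same specimens.
#' @return the selected `motu_partition` (with the prior in `parameters`).
#' @export
select_partition <- function(abgd_output, companion) {
  stopifnot(length(abgd_output) >= 1L)
  scores <- vapply(abgd_output, function(el)
    rand_index(el$partition, companion), numeric(1L))
  best <- which(scores >= max(scores) - 1e-12)[1L]
  abgd_output[[best]]$partition
}
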