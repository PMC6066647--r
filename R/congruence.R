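# The decision layer: combine distance summaries, nearest-neighbor evidence
# and the three delimitation methods into per-morphospecies verdicts.
#
# Described species (Rule D): a described morphospecies is a cryptic-species
# candidate when its intraspecific divergence exceeds the threshold, the
# delimitation methods agree on two or more clusters, and none of its
# specimens sits in a cluster with another nominal species. Deep divergence
# plus cluster sharing points instead at misidentification or hybridization
# (indistinguishable from COI alone); method disagreement leaves the species
# unresolved.
#
# Open-nomenclature taxa (Rule U): a taxon identified only at genus or
# family level is a new MOTU when at least one of its clusters is exclusive
# (not assignable to a nominal species at >= 98% similarity); when every
# cluster assigns, the taxon is referred to its nearest nominal neighbor.
# Exclusive clusters beyond the label's own nominal MOTU count as cryptic
# when the label shows deep intraspecific divergence (structural fallback
# when no divergence estimate is recorded: two or more exclusive clusters).

#' Congruence configuration
#'
#' @param intra_threshold maximum intraspecific divergence (%) above which a
#'   species is examined for hidden diversity.
#' @param inter_low_threshold interspecific divergence (%) below which a
#'   nearest-neighbor distance counts as a barcode-gap violation.
#' @param similarity_assign_threshold similarity (%) at or above which a
#'   cluster sharing with / matching a nominal species is assigned to it
#'   (98% corresponds to < 2% divergence from the nearest neighbor).
#' @param strictness `"strict"` requires all three methods (BIN-like, ABGD,
#'   PTP) to agree on the cluster count; `"majority"` accepts a count
#'   supported by two of three.
#' @export
congruence_config <- function(intra_threshold = 2.0,
                              inter_low_threshold = 1.0,
                              similarity_assign_threshold = 98.0,
                              strictness = c("strict", "majority")) {
  stopifnot(inter_low_threshold < intra_threshold)
  list(intra_threshold = intra_threshold,
       inter_low_threshold = inter_low_threshold,
       similarity_assign_threshold = similarity_assign_threshold,
       strictness = match.arg(strictness))
}

# consensus cluster count across the three methods under the strictness rule;
# NA when the methods do not agree. Missing (NA) method counts are ignored.
consensus_count <- function(n_bin, n_abgd, n_bptp, strictness) {
  counts <- c(n_bin, n_abgd, n_bptp)
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L) return(NA_integer_)
  if (strictness == "strict") {
    if (length(unique(counts)) == 1L) return(counts[1L])
    return(NA_integer_)
  }
  tab <- table(counts)
  if (length(counts) == 1L) return(counts[1L])
  top <- tab[tab >= 2L]
  if (length(top) == 0L) return(NA_integer_)
  as.integer(names(top)[1L])
}

#' Assemble a species-evidence row
#'
#' The unit of input to the congruence rules: everything the decision layer
#' knows about one morphospecies.
#'
#' @param morphospecies label.
#' @param nomenclature_status `"described"` or `"open"`.
#' @param max_intra,mean_intra intraspecific divergence (%), `NA` when not
#'   estimable.
#' @param n_clades clades in the guide tree (evidence only, not used by the
#'   rules).
#' @param n_bin,n_abgd,n_bptp cluster counts per method.
#' @param shares_cluster_with_nominal does any cluster holding this taxon's
#'   specimens also hold a nominal (described) species?
#' @param n_exclusive number of clusters exclusive to the taxon (open taxa).
#' @param shares_any does the label share any cluster with any other label?
#' @param n_taxa number of morphospecies labels pooled in this row (combined
#'   rows of survey tables).
#' @param nn_species,nn_distance,max_similarity nearest-neighbor evidence.
#' @return a one-row data frame of class `species_evidence`.
#' @export
species_evidence <- function(morphospecies, nomenclature_status,
                             max_intra = NA_real_, mean_intra = NA_real_,
                             n_clades = NA_integer_, n_bin = NA_integer_,
                             n_abgd = NA_integer_, n_bptp = NA_integer_,
                             shares_cluster_with_nominal = FALSE,
                             n_exclusive = NA_integer_, shares_any = NA,
                             n_taxa = 1L, nn_species = NA_character_,
                             nn_distance = NA_real_,
                             max_similarity = NA_real_) {
  out <- data.frame(morphospecies = morphospecies,
                    nomenclature_status = nomenclature_status,
                    max_intra = max_intra, mean_intra = mean_intra,
                    n_clades = as.integer(n_clades),
                    n_bin = as.integer(n_bin), n_abgd = as.integer(n_abgd),
                    n_bptp = as.integer(n_bptp),
                    shares_cluster_with_nominal = shares_cluster_with_nominal,
                    n_exclusive = as.integer(n_exclusive),
                    shares_any = shares_any, n_taxa = as.integer(n_taxa),
                    nn_species = nn_species, nn_distance = nn_distance,
                    max_similarity = max_similarity,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_evidence", class(out))
  out
}

decision_row <- function(evidence, verdict, n_new = 0L, n_cryptic = 0L,
                         rationale = "") {
  data.frame(morphospecies = evidence$morphospecies,
             nomenclature_status = evidence$nomenclature_status,
             verdict = verdict, n_new_motus = as.integer(n_new),
             n_cryptic_motus = as.integer(n_cryptic),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Flag a described species (Rule D)
#'
#' @param evidence a [species_evidence()] row with
#'   `nomenclature_status = "described"`.
#' @param config a [congruence_config()].
#' @return a one-row decision data frame (`verdict`, `n_new_motus`,
#'   `n_cryptic_motus`, `rationale`).
#' @export
flag_described <- function(evidence, config = congruence_config()) {
  stopifnot(evidence$nomenclature_status == "described")
  if (all(is.na(c(evidence$n_bin, evidence$n_abgd, evidence$n_bptp))))
    stop("missing cluster counts for ", evidence$morphospecies)
  if (is.na(evidence$max_intra) ||
      evidence$max_intra <= config$intra_threshold)
    return(decision_row(evidence, "assigned_to_nominal",
                        rationale = "intra<=thr"))
  if (isTRUE(evidence$shares_cluster_with_nominal))
    return(decision_row(evidence, "misid_or_hybrid_suspect",
                        rationale = "deep-intra+shares-nominal-cluster"))
  k <- consensus_count(evidence$n_bin, evidence$n_abgd, evidence$n_bptp,
                       config$strictness)
  if (is.na(k))
    return(decision_row(evidence, "unresolved",
                        rationale = "method-discordance"))
  if (k >= 2L) {
    extra <- max(k - evidence$n_taxa, 0L)
    return(decision_row(evidence, "cryptic_candidate", n_new = extra,
                        n_cryptic = extra,
                        rationale = sprintf("deep-intra+%d-congruent-clusters", k)))
  }
  decision_row(evidence, "assigned_to_nominal", rationale = "single-cluster")
}

#' Flag an open-nomenclature taxon (Rule U)
#'
#' @param evidence a [species_evidence()] row with
#'   `nomenclature_status = "open"`.
#' @param config a [congruence_config()].
#' @return a one-row decision data frame.
#' @export
flag_undescribed <- function(evidence, config = congruence_config()) {
  stopifnot(evidence$nomenclature_status == "open")
  counts <- c(evidence$n_bin, evidence$n_abgd, evidence$n_bptp)
  if (any(!is.na(counts))) {
    k <- consensus_count(evidence$n_bin, evidence$n_abgd, evidence$n_bptp,
                         config$strictness)
    if (is.na(k))
      return(decision_row(evidence, "unresolved",
                          rationale = "method-discordance"))
  }
  n_excl <- evidence$n_exclusive
  if (is.na(n_excl)) stop("missing n_exclusive for ", evidence$morphospecies)
  if (n_excl == 0L)
    return(decision_row(evidence, "assigned_to_nominal",
                        rationale = paste0("all-clusters-assign:",
                                           evidence$nn_species)))
  deep <- if (!is.na(evidence$max_intra))
    evidence$max_intra > config$intra_threshold else n_excl >= 2L
  own_motu <- if (isTRUE(evidence$shares_any)) 0L else 1L
  n_cryptic <- if (deep) max(n_excl - own_motu, 0L) else 0L
  decision_row(evidence, "new_motu", n_new = n_excl, n_cryptic = n_cryptic,
               rationale = sprintf("%d-exclusive-cluster%s%s", n_excl,
                                   if (n_excl > 1L) "s" else "",
                                   if (deep) "+deep-divergence" else ""))
}

#' Apply the congruence rules to a table of species evidence
#'
#' Routes each row to [flag_described()] or [flag_undescribed()] by its
#' nomenclature status.
#'
#' @param evidence data frame of [species_evidence()] rows.
#' @param config a [congruence_config()].
#' @return decision data frame, one row per morphospecies.
#' @export
flag_species <- function(evidence, config = congruence_config()) {
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    ev <- evidence[i, , drop = FALSE]
    if (ev$nomenclature_status == "described") flag_described(ev, config)
    else flag_undescribed(ev, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Incongruence typing per morphospecies
#'
#' `merge`: some method co-clusters the species with another morphospecies;
#' `split`: some method breaks it into two or more clusters;
#' `gap_violation`: deep intraspecific divergence (> `intra_threshold`)
#' combined with a nearest-neighbor distance below `inter_low_threshold`.
#'
#' @param partitions list of `motu_partition` objects (all covering the
#'   library).
#' @param library the `barcode_library`.
#' @param matrix the `motu_dist` used for the distance-based component.
#' @param config a [congruence_config()].
#' @return named list mapping morphospecies to a character vector drawn from
#'   `c("merge", "split", "gap_violation")`.
#' @export
incongruence_types <- function(partitions, library, matrix,
                               config = congruence_config()) {
  rec <- library$records
  summ <- species_summaries(matrix, library)
  species <- unique(rec$morphospecies)
  out <- lapply(species, function(sp) {
    ids <- rec$specimen_id[rec$morphospecies == sp]
    types <- character(0)
    for (p in partitions) {
      cl <- p$assignment[ids]
      if (length(unique(cl)) >= 2L) types <- c(types, "split")
      others <- p$assignment[setdiff(names(p$assignment), ids)]
      if (any(others %in% cl)) types <- c(types, "merge")
    }
    row <- summ[summ$morphospecies == sp, ]
    if (nrow(row) == 1L && !is.na(row$max_intra) &&
        row$max_intra > config$intra_threshold &&
        row$nn_distance < config$inter_low_threshold)
      types <- c(types, "gap_violation")
    sort(unique(types))
  })
  names(out) <- species
  out
}

#' Tally MOTU decisions
#'
#' @param decisions decision data frame from [flag_species()].
#' @return list of summary counts; `n_cryptic_motus` is the total number of
#'   putative cryptic-species MOTUs (extra MOTUs of flagged described
#'   species plus cryptic MOTUs within open-nomenclature taxa).
#' @export
motu_tally <- function(decisions) {
  stopifnot(!anyDuplicated(decisions$morphospecies))
  list(n_species = nrow(decisions),
       n_cryptic_candidates = sum(decisions$verdict == "cryptic_candidate"),
       n_cryptic_motus = sum(decisions$n_cryptic_motus),
       n_new_motu_taxa = sum(decisions$verdict == "new_motu"),
       n_new_motus_open = sum(decisions$n_new_motus[
         decisions$nomenclature_status == "open"]),
       n_assigned = sum(decisions$verdict == "assigned_to_nominal"),
       n_suspect = sum(decisions$verdict == "misid_or_hybrid_suspect"),
       n_unresolved = sum(decisions$verdict == "unresolved"))
}
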