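# Synthetic barcode libraries with known truth.
#
# Species-level structure: a random species tree whose inter-tip path
# lengths all exceed `min_inter`; within species, specimens sit on a star
# genealogy whose branch lengths give an expected pairwise divergence of
# `expected_intra`. Sequences evolve under the Kimura two-rate substitution
# process (transition:transversion rate ratio kappa; kappa = 1 reduces to
# JC69), codon-guarded so that no in-frame stop codon (vertebrate
# mitochondrial code) ever arises: a mutation that would create a stop is
# redirected to another target base at the same site, preserving the
# per-site substitution count.

#' Simulation configuration
#'
#' @param n_species number of species.
#' @param specimens_per_species specimens per species (the survey emulated
#'   averaged ~4.5 barcodes per species).
#' @param seq_length alignment length in bp.
#' @param kappa transition:transversion rate ratio (1 = JC69).
#' @param expected_intra expected within-species pairwise divergence
#'   (substitutions/site).
#' @param min_inter minimum between-species tree distance.
#' @param n_cryptic_injections species receiving an extra deep within-label
#'   split (cryptic lineages).
#' @param cryptic_depth divergence of the injected split.
#' @param n_label_swaps specimens relabeled to another species
#'   (misidentification mimic).
#' @param n_shared_haplotypes specimens whose sequence is replaced by a
#'   heterospecific haplotype (hybridization mimic).
#' @param seed RNG seed.
#' @export
sim_config <- function(n_species = 10L, specimens_per_species = 5L,
                       seq_length = 658L, kappa = 4,
                       expected_intra = 0.005, min_inter = 0.05,
                       n_cryptic_injections = 0L, cryptic_depth = 0.08,
                       n_label_swaps = 0L, n_shared_haplotypes = 0L,
                       seed = 42L) {
  if (min_inter <= expected_intra)
    stop("infeasible config: min_inter must exceed expected_intra")
  if (n_cryptic_injections > 0L && cryptic_depth <= expected_intra)
    stop("infeasible config: cryptic_depth must exceed expected_intra")
  stopifnot(n_species >= 2L, specimens_per_species >= 1L, seq_length >= 60L,
            kappa > 0, n_cryptic_injections >= 0L, n_label_swaps >= 0L,
            n_shared_haplotypes >= 0L)
  if (n_cryptic_injections + 2L * n_label_swaps + 2L * n_shared_haplotypes >
      n_species)
    stop("infeasible config: not enough species for disjoint injections")
  list(n_species = as.integer(n_species),
       specimens_per_species = as.integer(specimens_per_species),
       seq_length = as.integer(seq_length), kappa = kappa,
       expected_intra = expected_intra, min_inter = min_inter,
       n_cryptic_injections = as.integer(n_cryptic_injections),
       cryptic_depth = cryptic_depth,
       n_label_swaps = as.integer(n_label_swaps),
       n_shared_haplotypes = as.integer(n_shared_haplotypes),
       seed = as.integer(seed))
}

SIM_STOPS <- matrix(c(4L, 1L, 1L,   # TAA
                      4L, 1L, 3L,   # TAG
                      1L, 3L, 1L,   # AGA
                      1L, 3L, 3L),  # AGG
                    ncol = 3L, byrow = TRUE)

is_stop_codon <- function(cod)
  any(SIM_STOPS[, 1L] == cod[1L] & SIM_STOPS[, 2L] == cod[2L] &
      SIM_STOPS[, 3L] == cod[3L])

# random stop-free coding sequence (integer alphabet 1=A 2=C 3=G 4=T)
random_coding_seq <- function(len) {
  n_codons <- ceiling(len / 3)
  out <- integer(0)
  while (length(out) < 3L * n_codons) {
    cod <- sample.int(4L, 3L, replace = TRUE)
    if (!is_stop_codon(cod)) out <- c(out, cod)
  }
  out[seq_len(len)]
}

# K2P substitution probabilities for one branch of length d
k2p_probs <- function(d, kappa) {
  at <- d * kappa / (kappa + 2)
  bt <- d / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt) # each of the two transversion targets
  c(ts = p_ts, tv = p_tv)
}

TV1 <- c(2L, 1L, 2L, 1L) # first transversion target per base
TV2 <- c(4L, 3L, 4L, 3L) # second transversion target per base

# evolve an integer sequence along one branch, redirecting stop-creating
# mutations to a different target base at the same site
evolve_branch <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  L <- length(seq)
  pr <- k2p_probs(d, kappa)
  u <- stats::runif(L)
  child <- seq
  ts_hit <- u < pr["ts"]
  tv_hit <- !ts_hit & u < pr["ts"] + 2 * pr["tv"]
  child[ts_hit] <- TS_PARTNER[seq[ts_hit]]
  which_tv <- stats::runif(sum(tv_hit)) < 0.5
  child[tv_hit] <- ifelse(which_tv, TV1[seq[tv_hit]], TV2[seq[tv_hit]])
  # codon guard (reading frame 0)
  n_codons <- L %/% 3L
  changed <- which(child != seq)
  if (length(changed)) {
    for (ci in unique((changed[changed <= 3L * n_codons] - 1L) %/% 3L)) {
      pos <- ci * 3L + 1:3
      if (!is_stop_codon(child[pos])) next
      mut <- pos[child[pos] != seq[pos]]
      for (p in sample(rep(mut, 2L), length(mut))) {
        targets <- sample(setdiff(1:4, c(seq[p], child[p])))
        fixed <- FALSE
        for (tg in targets) {
          child[p] <- tg
          if (!is_stop_codon(child[pos])) { fixed <- TRUE; break }
        }
        if (!fixed) child[p] <- seq[p] # revert
        if (!is_stop_codon(child[pos])) break
      }
    }
  }
  child
}

int_to_seq <- function(x) paste0(c("A", "C", "G", "T")[x], collapse = "")

# random species tree with all inter-tip distances >= min_inter
random_species_tree <- function(n_species, min_inter) {
  tr <- ape::rtree(n_species, br = NULL)
  pendant <- tr$edge[, 2L] <= n_species
  tr$edge.length <- numeric(nrow(tr$edge))
  tr$edge.length[pendant] <- stats::runif(sum(pendant), min_inter / 2,
                                          min_inter)
  tr$edge.length[!pendant] <- stats::runif(sum(!pendant), 0.2 * min_inter,
                                           min_inter)
  tr$tip.label <- paste0("t", seq_len(n_species))
  tr
}

#' Simulate a barcode library with known truth
#'
#' @param config a [sim_config()].
#' @return list with `library` (a `barcode_library`), `truth` (a
#'   `motu_partition` of the true MOTUs), `events` (data frame logging the
#'   injected cryptic splits, label swaps and shared haplotypes) and
#'   `species_tree`.
#' @export
simulate_library <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))

  ns <- config$n_species
  sp_names <- sprintf("Genus%02d species%02d", 0L, seq_len(ns)) # placeholder
  tr <- random_species_tree(ns, config$min_inter)

  # taxonomy follows the species tree: genera/families = single-linkage
  # groups of species at increasing cophenetic thresholds
  coph <- ape::cophenetic.phylo(tr)
  ord <- match(paste0("t", seq_len(ns)), rownames(coph))
  coph <- coph[ord, ord]
  genus_grp <- linkage_components(coph, 2.5 * config$min_inter)
  family_grp <- linkage_components(coph, 5 * config$min_inter)
  genus <- sprintf("Genus%02d", genus_grp)
  family <- sprintf("Family%02d", family_grp)
  sp_names <- sprintf("%s species%02d", genus, seq_len(ns))

  # ancestral sequences: evolve a stop-free root down the species tree
  root_seq <- random_coding_seq(config$seq_length)
  nnode <- ns + tr$Nnode
  seqs_at <- vector("list", nnode)
  seqs_at[[ns + 1L]] <- root_seq
  pre <- ape::reorder.phylo(tr, "cladewise")$edge
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; v <- pre[k, 2L]
    seqs_at[[v]] <- evolve_branch(seqs_at[[p]],
                                  tr$edge.length[which(tr$edge[, 1L] == p &
                                                       tr$edge[, 2L] == v)],
                                  config$kappa)
  }
  anc <- lapply(seq_len(ns), function(i)
    seqs_at[[match(paste0("t", i), tr$tip.label)]])

  # choose disjoint species for the injected events
  n_needed <- config$n_cryptic_injections + 2L * config$n_label_swaps +
    2L * config$n_shared_haplotypes
  pool <- if (n_needed > 0L) sample.int(ns, n_needed) else integer(0)
  cryptic_sp <- utils::head(pool, config$n_cryptic_injections)
  rest <- utils::tail(pool, -config$n_cryptic_injections)
  swap_pairs <- if (config$n_label_swaps > 0L)
    matrix(utils::head(rest, 2L * config$n_label_swaps), ncol = 2L,
           byrow = TRUE) else matrix(integer(0), ncol = 2L)
  rest <- utils::tail(rest, -2L * config$n_label_swaps)
  share_pairs <- if (config$n_shared_haplotypes > 0L)
    matrix(rest, ncol = 2L, byrow = TRUE) else matrix(integer(0), ncol = 2L)

  nper <- config$specimens_per_species
  half_intra <- config$expected_intra / 2
  records <- list(); seqs <- character(0); truth <- character(0)
  events <- list()
  spec_ids <- sprintf("SP%04d", seq_len(ns * nper))
  idx <- 0L
  for (i in seq_len(ns)) {
    cryptic <- i %in% cryptic_sp
    sub_anc <- NULL
    sub_members <- integer(0)
    if (cryptic) {
      sub_anc <- evolve_branch(anc[[i]], config$cryptic_depth, config$kappa)
      sub_members <- utils::tail(seq_len(nper), nper %/% 2L)
      events[[length(events) + 1L]] <-
        data.frame(type = "cryptic_injection", species = sp_names[i],
                   detail = sprintf("%d specimens on lineage at depth %g",
                                    length(sub_members),
                                    config$cryptic_depth))
    }
    for (j in seq_len(nper)) {
      idx <- idx + 1L
      base <- if (cryptic && j %in% sub_members) sub_anc else anc[[i]]
      s <- evolve_branch(base, half_intra, config$kappa)
      seqs <- c(seqs, int_to_seq(s))
      names(seqs)[idx] <- spec_ids[idx]
      truth[spec_ids[idx]] <- if (cryptic && j %in% sub_members)
        paste0(sp_names[i], "_cryptic") else sp_names[i]
      records[[idx]] <- data.frame(
        specimen_id = spec_ids[idx], morphospecies = sp_names[i],
        genus = genus[i], family = family[i],
        site_id = sprintf("site%02d", 1L + (idx %% 5L)), basin = "SimBasin",
        native_status = "native", voucher = paste0("V", spec_ids[idx]),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, records)

  # label swaps: one specimen of the donor species relabeled as the receiver
  if (nrow(swap_pairs)) for (k in seq_len(nrow(swap_pairs))) {
    donor <- swap_pairs[k, 1L]; receiver <- swap_pairs[k, 2L]
    victim <- meta$specimen_id[meta$morphospecies == sp_names[donor]][1L]
    meta[meta$specimen_id == victim,
         c("morphospecies", "genus", "family")] <-
      list(sp_names[receiver], genus[receiver], family[receiver])
    events[[length(events) + 1L]] <-
      data.frame(type = "label_swap", species = sp_names[receiver],
                 detail = sprintf("%s is truly %s", victim, sp_names[donor]))
  }

  # shared haplotypes: one receiver specimen gets a donor sequence
  if (nrow(share_pairs)) for (k in seq_len(nrow(share_pairs))) {
    donor <- share_pairs[k, 1L]; receiver <- share_pairs[k, 2L]
    src <- meta$specimen_id[meta$morphospecies == sp_names[donor]][1L]
    dst <- meta$specimen_id[meta$morphospecies == sp_names[receiver]][1L]
    seqs[dst] <- seqs[src]
    truth[dst] <- truth[src]
    events[[length(events) + 1L]] <-
      data.frame(type = "shared_haplotype", species = sp_names[receiver],
                 detail = sprintf("%s carries haplotype of %s", dst,
                                  sp_names[donor]))
  }

  lib <- barcode_library(seqs, meta)
  list(library = lib,
       truth = motu_partition(truth, method = "truth",
                              parameters = list(seed = config$seed)),
       events = if (length(events)) do.call(rbind, events)
                else data.frame(type = character(0), species = character(0),
                                detail = character(0)),
       species_tree = tr, config = config)
}

#' Write a simulated truth table as TSV
#' @param sim result of [simulate_library()].
#' @param path output path.
#' @export
write_truth <- function(sim, path) {
  df <- data.frame(specimen_id = names(sim$truth$assignment),
                   true_motu = unname(sim$truth$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
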