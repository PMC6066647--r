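ev_described <- function(...) {
  defaults <- list(morphospecies = "Testus testus",
                   nomenclature_status = "described")
  do.call(species_evidence, utils::modifyList(defaults, list(...)))
}

test_that("Rule D: deep divergence with congruent exclusive clusters flags a
           cryptic candidate", {
  # the worked example's strongest case: 21.36% divergence, 2/2/2 clusters
  d <- flag_described(ev_described(max_intra = 21.36, mean_intra = 10.76,
                                   n_clades = 2L, n_bin = 2L, n_abgd = 2L,
                                   n_bptp = 2L))
  expect_equal(d$verdict, "cryptic_candidate")
  expect_equal(d$n_new_motus, 1L)
  # method discordance leaves the species unresolved under strict congruence
  u <- flag_described(ev_described(max_intra = 3.07, n_bin = 1L,
                                   n_abgd = 2L, n_bptp = 1L))
  expect_equal(u$verdict, "unresolved")
  # deep divergence but cluster shared with another nominal species
  m <- flag_described(ev_described(max_intra = 3.35, n_bin = 2L,
                                   n_abgd = 2L, n_bptp = 2L,
                                   shares_cluster_with_nominal = TRUE))
  expect_equal(m$verdict, "misid_or_hybrid_suspect")
  # shallow species are assigned to themselves
  a <- flag_described(ev_described(max_intra = 0, n_bin = 1L, n_abgd = 1L,
                                   n_bptp = 1L))
  expect_equal(a$verdict, "assigned_to_nominal")
  expect_error(flag_described(ev_described()), "cluster counts")
})

test_that("Rule D: majority strictness accepts 2-of-3 method agreement", {
  ev <- ev_described(max_intra = 12.2, n_bin = 3L, n_abgd = 3L, n_bptp = 1L)
  expect_equal(flag_described(ev)$verdict, "unresolved")
  maj <- flag_described(ev, congruence_config(strictness = "majority"))
  expect_equal(maj$verdict, "cryptic_candidate")
  expect_equal(maj$n_new_motus, 2L)
})

ev_open <- function(...) {
  defaults <- list(morphospecies = "Testus sp.", nomenclature_status = "open")
  do.call(species_evidence, utils::modifyList(defaults, list(...)))
}

test_that("Rule U: exclusive clusters make new MOTUs; full assignment refers
           to the nominal neighbor", {
  # an exclusive cluster whose neighbor is itself open nomenclature
  h <- flag_undescribed(ev_open(n_exclusive = 1L, shares_any = FALSE,
                                nn_species = "Othera sp.",
                                max_similarity = 100))
  expect_equal(h$verdict, "new_motu")
  expect_equal(h$n_new_motus, 1L)
  expect_equal(h$n_cryptic_motus, 0L) # single cohesive MOTU is not cryptic
  # all clusters assign to a described nominal at high similarity
  b <- flag_undescribed(ev_open(n_exclusive = 0L, shares_any = TRUE,
                                nn_species = "Testus ferox",
                                max_similarity = 100))
  expect_equal(b$verdict, "assigned_to_nominal")
  expect_match(b$rationale, "Testus ferox")
  # a singleton far from every named species
  s <- flag_undescribed(ev_open(n_exclusive = 1L, shares_any = FALSE,
                                n_bin = 1L, n_abgd = 1L, n_bptp = 1L,
                                max_similarity = 90))
  expect_equal(s$verdict, "new_motu")
})

test_that("Rule U: deep divergence turns extra exclusive clusters into
           cryptic MOTUs", {
  # deep label with several exclusive clusters and no sharing: one cluster
  # is the label's own MOTU, the rest are cryptic
  r <- flag_undescribed(ev_open(max_intra = 12.2, n_exclusive = 3L,
                                shares_any = FALSE))
  expect_equal(r$n_cryptic_motus, 2L)
  # sharing labels count every exclusive cluster as hidden
  r2 <- flag_undescribed(ev_open(max_intra = 20.5, n_exclusive = 1L,
                                 shares_any = TRUE))
  expect_equal(r2$n_cryptic_motus, 1L)
  # without a divergence estimate the structural fallback needs >= 2
  r3 <- flag_undescribed(ev_open(n_exclusive = 1L, shares_any = TRUE))
  expect_equal(r3$n_cryptic_motus, 0L)
  r4 <- flag_undescribed(ev_open(n_exclusive = 2L, shares_any = FALSE))
  expect_equal(r4$n_cryptic_motus, 1L)
})

test_that("verdicts partition the species set and the tally adds up", {
  fx <- table_fixtures()
  dec <- flag_species(fx$evidence, congruence_config(strictness = "majority"))
  expect_equal(nrow(dec), nrow(fx$evidence))
  expect_false(anyDuplicated(dec$morphospecies) > 0)
  tal <- motu_tally(dec)
  expect_equal(tal$n_assigned + tal$n_suspect + tal$n_unresolved +
                 tal$n_cryptic_candidates + tal$n_new_motu_taxa,
               tal$n_species)
  expect_equal(tal$n_cryptic_motus, sum(dec$n_cryptic_motus))
})

test_that("raising the intraspecific threshold never increases the cryptic
           count", {
  fx <- table_fixtures()
  counts <- vapply(c(1, 2, 5), function(thr) {
    cfg <- congruence_config(intra_threshold = thr,
                             inter_low_threshold = 0.5,
                             strictness = "majority")
    motu_tally(flag_species(fx$evidence, cfg))$n_cryptic_motus
  }, numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("incongruence typing sees merges from label swaps and splits from
           cryptic lineages", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  truth <- motu_partition(
    stats::setNames(lib$records$morphospecies, lib$records$specimen_id))
  clean <- incongruence_types(list(truth), lib, mat)
  expect_true(all(lengths(clean) == 0L))
  # swap: q01 (species1) relabeled as species2
  swapped <- lib$records$morphospecies
  swapped[1L] <- "Genus1 species2"
  lib2 <- make_library(lib$sequences, swapped)
  inc <- incongruence_types(list(truth), lib2, build_matrix(lib2, "K2P"))
  expect_true("merge" %in% inc[["Genus1 species1"]])
  expect_true("merge" %in% inc[["Genus1 species2"]])
  expect_true("split" %in% inc[["Genus1 species2"]])
})
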