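test_that("ABGD recovers a clean 5-species library at every prior", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  sweep <- abgd_partition(mat)
  counts <- vapply(sweep, `[[`, 0L, "n_groups")
  priors <- vapply(sweep, `[[`, 0, "prior")
  expect_true(all(counts[priors <= 0.02] == 5L))
  truth <- motu_partition(
    stats::setNames(lib$records$morphospecies, lib$records$specimen_id))
  expect_true(same_partition(sweep[[1L]]$partition, truth))
})

test_that("ABGD boundary behavior: all-zero distances and prior above the
           maximum give one group", {
  same <- make_library(
    stats::setNames(rep(strrep("ACGT", 30), 4), paste0("z", 1:4)),
    rep(c("S a", "S b"), each = 2))
  sweep <- abgd_partition(build_matrix(same, "p"))
  expect_true(all(vapply(sweep, `[[`, 0L, "n_groups") == 1L))
  # prior >= max distance leaves nothing to scan
  lib <- five_species_library()
  sw2 <- abgd_partition(build_matrix(lib, "p"),
                        abgd_config(p_min = 0.5, p_max = 0.9, n_steps = 3L))
  expect_true(all(vapply(sw2, `[[`, 0L, "n_groups") == 1L))
})

test_that("ABGD group counts are non-increasing in the prior", {
  for (s in c(3L, 11L)) {
    sim <- simulate_library(sim_config(seed = s))
    sweep <- abgd_partition(build_matrix(sim$library, "K2P"))
    counts <- vapply(sweep, `[[`, 0L, "n_groups")
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("select_partition maximizes Rand agreement with ties to the
           smaller prior", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  sweep <- abgd_partition(mat)
  truth <- motu_partition(
    stats::setNames(lib$records$morphospecies, lib$records$specimen_id))
  sel <- select_partition(sweep, truth)
  expect_true(same_partition(sel, truth))
  expect_equal(sel$parameters$prior, sweep[[1L]]$prior)
  # companion identical to a candidate selects that candidate (Rand = 1)
  sel2 <- select_partition(sweep, sweep[[5L]]$partition)
  expect_equal(rand_index(sel2, sweep[[5L]]$partition), 1)
})

test_that("BIN-like clustering: separation, single-linkage chaining, order
           invariance", {
  lib <- five_species_library()
  bin <- binlike_partition(build_matrix(lib, "p"))
  expect_equal(n_clusters(bin), 5L)
  # chain A-B 1%, B-C 1%, A-C 2% stays one cluster
  L <- 100L
  root <- strrep("ACGT", 25L)
  seqs <- c(A = mutate_at(root, 1L, "T"), B = root, C = mutate_at(root, 5L, "T"))
  chain <- make_library(seqs, c("S a", "S a", "S a"))
  expect_equal(n_clusters(binlike_partition(build_matrix(chain, "p"))), 1L)
  # clusters 10% apart separate
  far <- make_library(
    c(x1 = root, x2 = mutate_at(root, 1L, "T"),
      y1 = mutate_at(root, 11:20, rep("A", 10)),
      y2 = mutate_at(root, c(11:20, 30), rep("A", 11))),
    c("S x", "S x", "S y", "S y"))
  expect_equal(n_clusters(binlike_partition(build_matrix(far, "p"))), 2L)
  # invariance to specimen order
  perm <- c(9:15, 1:8)
  lib2 <- make_library(lib$sequences[perm], lib$records$morphospecies[perm])
  b2 <- binlike_partition(build_matrix(lib2, "p"))
  expect_true(same_partition(b2, binlike_partition(build_matrix(lib, "p"))))
})

test_that("a deep internal split separates a label into two BIN-like
           clusters", {
  sim <- simulate_library(sim_config(n_cryptic_injections = 1L, seed = 4L))
  bin <- binlike_partition(build_matrix(sim$library, "p"))
  expect_true(same_partition(bin, sim$truth))
  sp <- sim$events$species[sim$events$type == "cryptic_injection"]
  ids <- sim$library$records$specimen_id[
    sim$library$records$morphospecies == sp]
  expect_equal(length(unique(bin$assignment[ids])), 2L)
})

test_that("concordance classification counts concordant, discordant and
           singleton clusters", {
  lib <- five_species_library()
  truth <- motu_partition(
    stats::setNames(lib$records$morphospecies, lib$records$specimen_id))
  cc <- classify_concordance(truth, lib)
  expect_equal(unname(cc$counts["concordant"]), 5L)
  expect_equal(sum(cc$counts), n_clusters(truth))
  # force a discordant cluster and a singleton
  a <- truth$assignment
  a[4:6] <- a[1L]          # species 2 merged into species 1's cluster
  a[15L] <- "solo"
  p2 <- motu_partition(a)
  cc2 <- classify_concordance(p2, lib)
  expect_equal(unname(cc2$counts["discordant"]), 1L)
  expect_gte(unname(cc2$counts["singleton"]), 1L)
  expect_equal(sum(cc2$counts), n_clusters(p2))
})
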