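test_that("K2P and JC69 match their closed forms on constructed pairs", {
  a <- strrep("A", 100)
  b10ts <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(pairwise_k2p(a, b10ts)$distance, -0.5 * log(0.8),
               tolerance = 1e-12)
  bPQ <- paste0(strrep("G", 10), strrep("C", 10), strrep("A", 80))
  expect_equal(pairwise_k2p(a, bPQ)$distance,
               -0.5 * log(0.7 * sqrt(0.8)), tolerance = 1e-12)
  expect_equal(pairwise_jc69(a, b10ts)$distance,
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_identical(pairwise_k2p(a, a)$distance, 0)
  expect_identical(pairwise_jc69(a, a)$distance, 0)
  # saturation at the formula's domain boundary
  sat <- paste0(strrep("G", 50), strrep("C", 25), strrep("A", 25))
  expect_true(pairwise_jc69(a, sat)$saturated)
})

test_that("pairwise deletion skips gaps and ambiguity codes", {
  a <- "ACGTACGTAC"
  b <- "-CGTRCGTAT" # gap + R (ambiguous) + 1 real transition at site 10
  r <- pairwise_k2p(a, b)
  expect_equal(r$stats$n_sites, 8L)
  expect_equal(r$stats$P, 1 / 8)
  expect_equal(r$stats$Q, 0)
  expect_error(pairwise_k2p("NNNN", "AC-T"), "comparable")
})

test_that("distances increase with mismatch count at fixed length", {
  L <- 50L
  base <- strrep("A", L)
  prev_k <- prev_j <- -1
  for (m in 0:15) {
    other <- paste0(strrep("G", m), strrep("A", L - m))
    dk <- pairwise_k2p(base, other)$distance
    dj <- pairwise_jc69(base, other)$distance
    expect_gt(dk, prev_k)
    expect_gt(dj, prev_j)
    prev_k <- dk; prev_j <- dj
  }
})

test_that("build_matrix agrees with per-pair calls, ape::dist.dna, and is
           invariant to specimen reordering", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  expect_identical(mat$values, t(mat$values))
  expect_true(all(diag(mat$values) == 0))
  ids <- mat$ids
  for (i in c(1L, 4L)) for (j in c(7L, 12L)) {
    expect_equal(mat$values[i, j],
                 pairwise_k2p(lib$sequences[[i]], lib$sequences[[j]])$distance)
  }
  # independent cross-check against ape's K80 distances
  dna <- ape::as.DNAbin(strsplit(tolower(lib$sequences), ""))
  ref <- as.matrix(ape::dist.dna(dna, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(mat$values), unname(ref[ids, ids]), tolerance = 1e-12)
  # reordering permutes values
  perm <- rev(seq_along(lib$sequences))
  lib2 <- make_library(lib$sequences[perm], lib$records$morphospecies[perm])
  mat2 <- build_matrix(lib2, "K2P")
  expect_equal(mat2$values[ids, ids], mat$values)
})

test_that("rank summaries pool shared-label pairs and order species <
           genus < family on structured data", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  rs <- summarize_ranks(mat, lib)
  expect_equal(rs$rank, c("species", "genus", "family"))
  means <- rs$mean
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
  expect_true(all(rs$min <= rs$mean & rs$mean <= rs$max))
})

test_that("rank summary arithmetic is exact on a 2-species p-distance case", {
  L <- 100L
  root <- strrep("ACGT", 25L)
  seqs <- c(a1 = root, a2 = mutate_at(root, 1L, "T"),
            b1 = mutate_at(root, 50:52, c("A", "A", "A")),
            b2 = mutate_at(root, c(50:52, 60:62),
                           c("A", "A", "A", "G", "G", "G")))
  lib <- make_library(seqs, c("Sp one", "Sp one", "Sp two", "Sp two"))
  mat <- build_matrix(lib, "p")
  rs <- summarize_ranks(mat, lib)
  sp <- rs[rs$rank == "species", ]
  expect_equal(sp$min, 1)
  expect_equal(sp$max, 3)
  expect_equal(sp$mean, 2)
})

test_that("divergence histogram conserves taxa and reports cumulative
           fractions", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  h <- divergence_histogram(mat, lib, "species")
  expect_equal(sum(h$table$count), h$n_taxa)
  expect_equal(h$n_taxa, 5L)
  expect_equal(h$fraction_below_1, 1) # intra ~0.4%
  # all-identical sequences land in the first bin
  same <- make_library(c(x1 = strrep("A", 60), x2 = strrep("A", 60)),
                       c("S one", "S one"))
  hs <- divergence_histogram(build_matrix(same, "p"), same, "species")
  expect_equal(hs$table$count[1L], 1L)
})

test_that("species summaries: barcode gap, nearest neighbor, shared
           haplotypes", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  ss <- species_summaries(mat, lib)
  expect_true(all(ss$barcode_gap > 0))
  expect_true(all(ss$nn_distance > ss$max_intra))
  # a haplotype shared across two labels zeroes the NND
  seqs <- lib$sequences
  seqs[["q04"]] <- seqs[["q01"]] # q04 is species2, q01 species1
  lib2 <- make_library(seqs, lib$records$morphospecies)
  ss2 <- species_summaries(build_matrix(lib2, "K2P"), lib2)
  row <- ss2[ss2$morphospecies == "Genus1 species2", ]
  expect_equal(row$nn_distance, 0)
  expect_equal(row$max_similarity, 100)
  # 1-2 specimen species have undefined intraspecific estimates
  expect_true(is.na(species_summaries(mat, lib, min_n_intra = 4L)$max_intra[1]))
})

test_that("matrix exports are readable and complete", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  p1 <- tempfile(fileext = ".phy"); p2 <- tempfile(fileext = ".tsv")
  write_matrix(mat, p1, "phylip")
  write_matrix(mat, p2, "long")
  expect_equal(as.integer(trimws(readLines(p1)[1L])), length(mat$ids))
  long <- utils::read.delim(p2)
  expect_equal(nrow(long), choose(length(mat$ids), 2L))
  expect_true(all(long$n_sites <= lib$alignment_length))
})
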