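test_that("three-taxon tree follows the closed three-point formulas", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  cop <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(cop), unname(d), tolerance = 1e-9)
})

test_that("a four-taxon additive matrix is recovered exactly (topology and
           branch lengths)", {
  nwk <- "((a:0.10,b:0.20):0.05,(c:0.15,d:0.25):0.05);"
  gen <- ape::read.tree(text = nwk)
  d <- ape::cophenetic.phylo(gen)
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(gen), tr), structure(0, names = "PH85"),
               ignore_attr = TRUE)
})

test_that("an ultrametric two-cluster matrix splits correctly", {
  d <- matrix(0.5, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tr <- neighbor_joining(d)
  expect_true(ape::is.monophyletic(tr, c("a", "b")) ||
              ape::is.monophyletic(tr, c("c", "d")))
})

test_that("NJ is consistent on random additive matrices and agrees with
           ape's implementation", {
  set.seed(99)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 0.5)
    d <- ape::cophenetic.phylo(gen)
    tr <- neighbor_joining(d)
    # exact additive recovery: path metric reproduces the input matrix
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
  }
})

test_that("negative branch-length estimates are clamped to zero", {
  # taxon c sits 'inside' the a-b path: classic negative-branch case
  d <- matrix(c(0, 0.2, 0.1, 0.35,
                0.2, 0, 0.08, 0.2,
                0.1, 0.08, 0, 0.28,
                0.35, 0.2, 0.28, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("clade exclusivity counts bipartitions, tolerates re-rooting, and
           drops under a label swap", {
  lib <- five_species_library()
  mat <- build_matrix(lib, "K2P")
  tr <- neighbor_joining(mat)
  ce <- clade_exclusivity(tr, lib)
  expect_equal(ce$fraction, 1)
  rerooted <- ape::root(tr, outgroup = tr$tip.label[1L],
                        resolve.root = TRUE)
  expect_equal(clade_exclusivity(rerooted, lib)$per_species, ce$per_species)
  # swap one label between species 1 and 2
  swapped <- lib$records$morphospecies
  swapped[1L] <- "Genus1 species2"
  lib2 <- make_library(lib$sequences, swapped)
  ce2 <- clade_exclusivity(tr, lib2)
  expect_false(ce2$per_species[["Genus1 species1"]])
  expect_false(ce2$per_species[["Genus1 species2"]])
  # singleton species count as exclusive
  single <- lib$records$morphospecies
  single[1L] <- "Genus9 species9"
  lib3 <- make_library(lib$sequences, single)
  expect_true(clade_exclusivity(tr, lib3)$per_species[["Genus9 species9"]])
})

test_that("newick export round-trips through ape", {
  lib <- five_species_library()
  tr <- neighbor_joining(build_matrix(lib, "K2P"))
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(as.numeric(ape::dist.topo(back, tr)), 0)
})
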