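# Shared builders and independent oracles used across the suite.

BASES <- c("A", "C", "G", "T")
TV_FLIP <- c(A = "C", C = "A", G = "T", T = "G") # transversion partner

# a library from explicit sequences and species labels
make_library <- function(seqs, species, genus = NULL, family = NULL) {
  ids <- names(seqs)
  if (is.null(genus)) genus <- vapply(strsplit(species, " "), `[[`, "", 1L)
  if (is.null(family)) family <- rep("Fam1", length(ids))
  barcode_library(seqs, data.frame(
    specimen_id = ids, morphospecies = species, genus = genus,
    family = family, site_id = "s1", basin = "b1",
    native_status = "native", voucher = ids, stringsAsFactors = FALSE))
}

# mutate single sites of a sequence string (1-based positions -> new base)
mutate_at <- function(seq, pos, base) {
  ch <- strsplit(seq, "")[[1L]]
  ch[pos] <- base
  paste0(ch, collapse = "")
}

# Deterministic 5-species library (L = 500): species ancestors differ in
# disjoint 30-site transversion blocks (~12% apart); each specimen carries
# one private transversion, so all intraspecific pairwise distances are
# equal (~0.4%) and the barcode gap is wide and noise-free.
five_species_library <- function(n_per = 3L) {
  root <- strrep("ACGT", 125L)
  anc <- vapply(1:5, function(s) {
    ch <- strsplit(root, "")[[1L]]
    idx <- ((s - 1L) * 30L + 1L):(s * 30L)
    ch[idx] <- TV_FLIP[ch[idx]]
    paste0(ch, collapse = "")
  }, "")
  seqs <- character(0); species <- character(0)
  for (s in 1:5) for (j in seq_len(n_per)) {
    pos <- 200L + (s - 1L) * n_per + j
    base <- substr(anc[s], pos, pos)
    seqs <- c(seqs, mutate_at(anc[s], pos, TV_FLIP[[base]]))
    species <- c(species, sprintf("Genus%d species%d", ceiling(s / 2), s))
  }
  names(seqs) <- sprintf("q%02d", seq_along(seqs))
  make_library(seqs, species)
}

# independent 3-frame stop counting oracle (vertebrate mito code)
oracle_min_stops <- function(seq) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  counts <- vapply(0:2, function(f) {
    s <- substring(seq, f + 1L)
    n <- nchar(s) %/% 3L
    if (n == 0L) return(0L)
    cods <- substring(s, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
    sum(cods %in% stops)
  }, integer(1L))
  list(min = min(counts), frame = which.min(counts) - 1L, counts = counts)
}

# exhaustive enumeration of PTP delimitations (cuts) on a small rooted
# tree, with its own likelihood computation, independent of the package's
# incremental state machinery
oracle_ptp_enumeration <- function(tree, eps = 1e-8) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  ancestors <- function(v) {
    out <- integer(0)
    while (!is.na(parent[v])) { v <- parent[v]; out <- c(out, v) }
    out
  }
  anc <- lapply(seq_len(nnode), ancestors)
  tips_of <- function(v)
    which(vapply(seq_len(ntip), function(t) t == v || v %in% anc[[t]],
                 logical(1L)))
  el <- pmax(tree$edge.length, eps)
  f <- function(n, L) if (n == 0L) 0 else n * log(n / L) - n
  lls <- numeric(0); keys <- character(0)
  for (mask in 0:(2^nnode - 1L)) {
    D <- which(bitwAnd(mask, 2^(seq_len(nnode) - 1L)) > 0)
    if (length(D) == 0L) next
    cover <- vapply(seq_len(ntip), function(t)
      sum(c(t, anc[[t]]) %in% D), integer(1L))
    if (!all(cover == 1L)) next
    coal <- vapply(seq_len(nrow(tree$edge)), function(k)
      any(anc[[tree$edge[k, 2L]]] %in% D), logical(1L))
    n_c <- sum(coal); L_c <- sum(el[coal])
    lls <- c(lls, f(nrow(tree$edge) - n_c, sum(el) - L_c) + f(n_c, L_c))
    keys <- c(keys, paste(sort(vapply(D, function(v)
      paste(sort(tips_of(v)), collapse = ","), "")), collapse = ";"))
  }
  post <- exp(lls - max(lls)); post <- post / sum(post)
  data.frame(key = keys, loglik = lls, posterior = post,
             stringsAsFactors = FALSE)
}
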