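# Poisson Tree Processes species delimitation.
#
# The model classes every branch as "speciation" (between-species process)
# or "coalescent" (within-species process), each class exponential with its
# own rate. A delimitation is a "cut": an antichain of nodes covering all
# tips; the subtree below each cut node is one MOTU and its internal edges
# are coalescent-class, everything else speciation-class. Rates are profiled
# out at their per-class maximum-likelihood estimates (1/mean branch
# length), so the criterion for a cut is the profile log-likelihood
#   l = n_s log(n_s/L_s) - n_s + n_c log(n_c/L_c) - n_c.

ptp_prep <- function(tree, eps = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("PTP needs a tree with at least 3 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # the cut state space needs a rooted tree whose root lies between
  # species; midpoint-root unrooted input (as the PTP server does)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  nnode <- ntip + tree$Nnode
  len <- rep(NA_real_, nnode)
  parent <- rep(NA_integer_, nnode)
  len[tree$edge[, 2L]] <- pmax(tree$edge.length, eps)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- vector("list", nnode)
  for (k in seq_len(nrow(tree$edge)))
    children[[tree$edge[k, 1L]]] <- c(children[[tree$edge[k, 1L]]],
                                      tree$edge[k, 2L])
  nchild <- lengths(children)
  root <- ntip + 1L
  # accumulate subtree edge counts/lengths and tip sets in postorder
  po <- ape::reorder.phylo(tree, "postorder")$edge
  sub_n <- integer(nnode); sub_L <- numeric(nnode)
  tips_below <- vector("list", nnode)
  for (t in seq_len(ntip)) tips_below[[t]] <- t
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]; v <- po[k, 2L]
    sub_n[p] <- sub_n[p] + 1L + sub_n[v]
    sub_L[p] <- sub_L[p] + len[v] + sub_L[v]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[v]])
  }
  list(tree = tree, ntip = ntip, nnode = nnode, root = root, len = len,
       parent = parent, children = children, nchild = nchild,
       internal = seq_len(nnode) > ntip, sub_n = sub_n, sub_L = sub_L,
       tips_below = tips_below, total_n = nrow(tree$edge),
       total_L = sum(pmax(tree$edge.length, eps)))
}

class_loglik <- function(n, L) if (n == 0L) 0 else n * log(n / L) - n

cut_loglik <- function(prep, n_c, L_c) {
  n_s <- prep$total_n - n_c
  L_s <- prep$total_L - L_c
  class_loglik(n_s, L_s) + class_loglik(n_c, L_c)
}

# state helpers -------------------------------------------------------------

new_state <- function(prep, d_nodes) {
  in_d <- rep(FALSE, prep$nnode)
  in_d[d_nodes] <- TRUE
  nch_in_d <- integer(prep$nnode)
  for (v in d_nodes) {
    p <- prep$parent[v]
    if (!is.na(p)) nch_in_d[p] <- nch_in_d[p] + 1L
  }
  n_c <- sum(prep$sub_n[d_nodes])
  L_c <- sum(prep$sub_L[d_nodes])
  list(in_d = in_d, nch_in_d = nch_in_d, n_c = n_c, L_c = L_c,
       loglik = cut_loglik(prep, n_c, L_c))
}

state_split <- function(prep, st, v) {
  ch <- prep$children[[v]]
  st$in_d[v] <- FALSE
  st$in_d[ch] <- TRUE
  st$nch_in_d[v] <- prep$nchild[v]
  p <- prep$parent[v]
  if (!is.na(p)) st$nch_in_d[p] <- st$nch_in_d[p] - 1L
  st$n_c <- st$n_c - prep$nchild[v]
  st$L_c <- st$L_c - sum(prep$len[ch])
  st$loglik <- cut_loglik(prep, st$n_c, st$L_c)
  st
}

state_merge <- function(prep, st, u) {
  ch <- prep$children[[u]]
  st$in_d[ch] <- FALSE
  st$in_d[u] <- TRUE
  st$nch_in_d[u] <- 0L
  p <- prep$parent[u]
  if (!is.na(p)) st$nch_in_d[p] <- st$nch_in_d[p] + 1L
  st$n_c <- st$n_c + prep$nchild[u]
  st$L_c <- st$L_c + sum(prep$len[ch])
  st$loglik <- cut_loglik(prep, st$n_c, st$L_c)
  st
}

state_moves <- function(prep, st) {
  splits <- which(st$in_d & prep$internal)
  merges <- which(prep$internal & prep$nchild > 0L &
                  st$nch_in_d == prep$nchild)
  list(splits = splits, merges = merges,
       n = length(splits) + length(merges))
}

state_partition <- function(prep, st, method, parameters = list()) {
  d_nodes <- which(st$in_d)
  assign <- integer(prep$ntip)
  for (k in seq_along(d_nodes))
    assign[prep$tips_below[[d_nodes[k]]]] <- k
  names(assign) <- prep$tree$tip.label
  motu_partition(assign, method = method, parameters = parameters)
}

# ---------------------------------------------------------------------------

#' Maximum-likelihood PTP delimitation
#'
#' Greedy descent over split/merge moves from the all-singleton
#' (all-speciation) state, with seeded random restarts; the returned model's
#' likelihood always dominates both the one-MOTU and the all-singleton
#' configurations.
#'
#' @param tree a `phylo` with branch lengths (zero lengths floored at
#'   `eps`).
#' @param n_restarts random restarts in addition to the two deterministic
#'   starts.
#' @param seed RNG seed for the restarts.
#' @param eps floor for zero branch lengths.
#' @return list with `partition` (a `motu_partition`, method `"PTP_ML"`),
#'   `model` (lambdas, edge-class counts, log_likelihood) and
#'   `low_confidence` flag (set when branch lengths carry no two-class
#'   signal).
#' @export
ptp_ml <- function(tree, n_restarts = 20L, seed = 42L, eps = 1e-8) {
  prep <- ptp_prep(tree, eps)
  flat <- stats::sd(tree$edge.length) == 0
  greedy <- function(st) {
    repeat {
      mv <- state_moves(prep, st)
      best <- NULL; best_ll <- st$loglik + 1e-9
      for (v in mv$splits) {
        cand <- state_split(prep, st, v)
        if (cand$loglik > best_ll) { best <- cand; best_ll <- cand$loglik }
      }
      for (u in mv$merges) {
        cand <- state_merge(prep, st, u)
        if (cand$loglik > best_ll) { best <- cand; best_ll <- cand$loglik }
      }
      if (is.null(best)) return(st)
      st <- best
    }
  }
  random_state <- function() {
    st <- new_state(prep, seq_len(prep$ntip))
    repeat {
      mv <- state_moves(prep, st)
      if (length(mv$merges) == 0L || stats::runif(1) > 0.7) break
      st <- state_merge(prep, st, sample(rep(mv$merges, 2L), 1L))
    }
    st
  }
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  starts <- c(list(new_state(prep, seq_len(prep$ntip)),
                   new_state(prep, prep$root)),
              lapply(seq_len(n_restarts), function(i) random_state()))
  fits <- lapply(starts, greedy)
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(lls)]]
  if (flat) best <- new_state(prep, prep$root)
  n_c <- best$n_c; L_c <- best$L_c
  n_s <- prep$total_n - n_c; L_s <- prep$total_L - L_c
  model <- list(
    lambda_speciation = if (n_s > 0) n_s / L_s else NA_real_,
    lambda_coalescent = if (n_c > 0) n_c / L_c else NA_real_,
    n_speciation_edges = n_s, n_coalescent_edges = n_c,
    log_likelihood = best$loglik)
  list(partition = state_partition(prep, best, "PTP_ML",
                                   list(seed = seed, restarts = n_restarts)),
       model = model, low_confidence = flat)
}

#' Bayesian PTP configuration
#' @param generations MCMC generations.
#' @param thinning record every `thinning`-th generation.
#' @param burn_in fraction of generations discarded.
#' @param seed RNG seed.
#' @export
bptp_config <- function(generations = 500000L, thinning = 100L,
                        burn_in = 0.10, seed = 42L) {
  stopifnot(burn_in >= 0, burn_in < 1, generations >= thinning)
  list(generations = as.integer(generations), thinning = as.integer(thinning),
       burn_in = burn_in, seed = as.integer(seed))
}

#' Bayesian PTP delimitation by Metropolis sampling
#'
#' Samples delimitations (cuts) in proportion to the PTP profile likelihood
#' under a flat prior over cuts, using split/merge proposals with a Hastings
#' correction for the varying move count. The support of a MOTU is the
#' posterior frequency with which its exact tip set is delimited; the
#' returned partition greedily stacks the highest-support non-conflicting
#' tip sets.
#'
#' @param tree a `phylo` with branch lengths.
#' @param config a [bptp_config()].
#' @param eps floor for zero branch lengths.
#' @return list with `partition` (method `"bPTP"`), `support` (named
#'   per-specimen posterior support in `[0, 1]`), `partition_freq` (table of
#'   sampled partition frequencies) and `n_samples`.
#' @export
bptp_sample <- function(tree, config = bptp_config(), eps = 1e-8) {
  prep <- ptp_prep(tree, eps)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  st <- new_state(prep, seq_len(prep$ntip))
  burn <- as.integer(config$generations * config$burn_in)
  node_counts <- integer(prep$nnode)
  part_counts <- new.env(hash = TRUE)
  n_samples <- 0L
  node_key <- vapply(prep$tips_below,
                     function(t) paste(sort(t), collapse = ","), "")
  for (g in seq_len(config$generations)) {
    mv <- state_moves(prep, st)
    if (mv$n > 0L) {
      pick <- sample.int(mv$n, 1L)
      cand <- if (pick <= length(mv$splits))
        state_split(prep, st, mv$splits[pick])
      else
        state_merge(prep, st, mv$merges[pick - length(mv$splits)])
      mv2 <- state_moves(prep, cand)
      log_acc <- cand$loglik - st$loglik + log(mv$n) - log(mv2$n)
      if (log(stats::runif(1)) < log_acc) st <- cand
    }
    if (g > burn && g %% config$thinning == 0L) {
      n_samples <- n_samples + 1L
      d <- which(st$in_d)
      node_counts[d] <- node_counts[d] + 1L
      key <- paste(sort(node_key[d]), collapse = ";")
      part_counts[[key]] <- (if (is.null(part_counts[[key]])) 0L
                             else part_counts[[key]]) + 1L
    }
  }
  support_by_node <- node_counts / n_samples
  ord <- order(support_by_node, decreasing = TRUE)
  taken <- logical(prep$ntip)
  chosen <- integer(0)
  for (v in ord) {
    tb <- prep$tips_below[[v]]
    if (support_by_node[v] <= 0) break
    if (!any(taken[tb])) { chosen <- c(chosen, v); taken[tb] <- TRUE }
    if (all(taken)) break
  }
  # tips never covered (vanishing support) become singletons
  for (t in which(!taken)) chosen <- c(chosen, t)
  assign <- integer(prep$ntip)
  supp <- numeric(prep$ntip)
  for (k in seq_along(chosen)) {
    tb <- prep$tips_below[[chosen[k]]]
    assign[tb] <- k
    supp[tb] <- support_by_node[chosen[k]]
  }
  names(assign) <- names(supp) <- prep$tree$tip.label
  freq <- unlist(as.list(part_counts)) / n_samples
  list(partition = motu_partition(assign, "bPTP",
                                  parameters = config),
       support = supp,
       partition_freq = sort(freq, decreasing = TRUE),
       n_samples = n_samples)
}
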