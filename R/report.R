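# Run configuration and report-writing entry points (distances / delimit /
# flag), mirroring the survey's outputs: rank summary and per-species
# tables, divergence histograms, method partitions, and the MOTU decision
# report.

#' Run configuration for the report entry points
#'
#' @param fasta,metadata input paths (aligned FASTA + specimen TSV).
#' @param tree optional Newick path; when given, the tree drives PTP
#'   instead of the internally built neighbor-joining tree.
#' @param model distance model, `"K2P"` or `"JC69"`.
#' @param out_dir output directory (created if missing).
#' @param seed seed forwarded to the stochastic steps.
#' @param abgd an [abgd_config()].
#' @param bptp a [bptp_config()]; its seed is replaced by `seed`.
#' @param congruence a [congruence_config()].
#' @param min_n_intra minimum specimens for intraspecific estimates.
#' @export
run_config <- function(fasta = NULL, metadata = NULL, tree = NULL,
                       model = c("K2P", "JC69"), out_dir = ".",
                       seed = 42L, abgd = abgd_config(),
                       bptp = bptp_config(), congruence = congruence_config(),
                       min_n_intra = 3L) {
  model <- match.arg(model)
  bptp$seed <- as.integer(seed)
  list(fasta = fasta, metadata = metadata, tree = tree, model = model,
       out_dir = out_dir, seed = as.integer(seed), abgd = abgd, bptp = bptp,
       congruence = congruence, min_n_intra = as.integer(min_n_intra))
}

# tiny FNV-1a hash so reports can carry a config fingerprint without extra
# dependencies
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

report_header <- function(config) {
  sprintf("# motudelim %s seed=%d config=%s",
          as.character(utils::packageVersion("motudelim")),
          config$seed, config_hash(config))
}

write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_input <- function(config) {
  if (is.null(config$fasta) || is.null(config$metadata))
    stop("run_config needs 'fasta' and 'metadata' paths")
  read_library(config$fasta, config$metadata)
}

#' Distance reports: rank summary, per-species summary, divergence
#' histograms
#'
#' @param config a [run_config()].
#' @param library optionally, an already-loaded `barcode_library` (the
#'   `fasta`/`metadata` paths are then ignored).
#' @return invisibly, a list with the computed tables and output paths.
#' @export
cmd_distances <- function(config, library = NULL) {
  if (is.null(library)) library <- load_input(config)
  if (n_specimens(library) == 0L) stop("empty library")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- report_header(config)
  mat <- build_matrix(library, config$model)
  ranks <- summarize_ranks(mat, library)
  summ <- species_summaries(mat, library, min_n_intra = config$min_n_intra)
  num <- vapply(summ, is.numeric, TRUE)
  summ[num] <- lapply(summ[num], round, 2L)
  paths <- file.path(config$out_dir,
                     c("rank_summary.tsv", "species_summary.tsv",
                       "histogram_species.tsv", "histogram_genus.tsv"))
  write_report(ranks, paths[1L], hdr)
  write_report(summ, paths[2L], hdr)
  hs <- divergence_histogram(mat, library, "species")
  hg <- divergence_histogram(mat, library, "genus")
  write_report(hs$table, paths[3L], hdr)
  write_report(hg$table, paths[4L], hdr)
  invisible(list(matrix = mat, rank_summary = ranks, species_summary = summ,
                 histogram_species = hs, histogram_genus = hg,
                 paths = paths))
}

run_delimitation <- function(config, library) {
  mat <- build_matrix(library, config$model)
  pmat <- build_matrix(library, "p")
  tree <- if (!is.null(config$tree)) ape::read.tree(config$tree)
          else neighbor_joining(mat)
  bin <- binlike_partition(pmat)
  sweep <- abgd_partition(mat, config$abgd)
  abgd_sel <- select_partition(sweep, bin)
  ml <- ptp_ml(tree, seed = config$seed)
  bptp <- bptp_sample(tree, config$bptp)
  list(matrix = mat, p_matrix = pmat, tree = tree, bin = bin, sweep = sweep,
       abgd = abgd_sel, ptp_ml = ml, bptp = bptp)
}

#' MOTU delimitation report: ABGD sweep, PTP (ML and Bayesian), BIN-like
#' clustering, and concordance with morphology
#'
#' @inheritParams cmd_distances
#' @return invisibly, the delimitation objects and output paths.
#' @export
cmd_delimit <- function(config, library = NULL) {
  if (is.null(library)) library <- load_input(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- report_header(config)
  del <- run_delimitation(config, library)
  parts <- list(del$bin, del$abgd, del$ptp_ml$partition,
                del$bptp$partition)
  long <- do.call(rbind, lapply(parts, function(p)
    data.frame(specimen_id = names(p$assignment), method = p$method,
               cluster_id = unname(p$assignment))))
  sweep_tab <- data.frame(
    prior = vapply(del$sweep, `[[`, 0, "prior"),
    n_groups = vapply(del$sweep, `[[`, 0L, "n_groups"))
  conc <- classify_concordance(del$bin, library)
  supp <- data.frame(specimen_id = names(del$bptp$support),
                     support = round(unname(del$bptp$support), 4L))
  paths <- file.path(config$out_dir,
                     c("partitions.tsv", "abgd_sweep.tsv",
                       "bptp_support.tsv", "concordance.tsv"))
  write_report(long, paths[1L], hdr)
  write_report(sweep_tab, paths[2L], hdr)
  write_report(supp, paths[3L], hdr)
  write_report(data.frame(label = names(conc$counts),
                          count = as.integer(conc$counts)),
               paths[4L], hdr)
  invisible(c(del, list(concordance = conc, paths = paths)))
}

#' MOTU decision report and cryptic-diversity tally
#'
#' Runs the full pipeline (distances, tree, three delimitation methods,
#' evidence assembly, congruence rules) and writes a decision table plus
#' tally. With `from_fixtures = TRUE` the congruence layer runs directly on
#' the packaged worked-example evidence ([table_fixtures()]) instead.
#'
#' @inheritParams cmd_distances
#' @param from_fixtures run on the packaged survey evidence fixtures.
#' @return invisibly, a list with `evidence`, `decisions`, `tally` and
#'   output paths.
#' @export
cmd_flag <- function(config, library = NULL, from_fixtures = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- report_header(config)
  if (from_fixtures) {
    evidence <- table_fixtures()$evidence
    extra <- NULL
  } else {
    if (is.null(library)) library <- load_input(config)
    del <- run_delimitation(config, library)
    evidence <- build_evidence(library, del$matrix, del$tree,
                               bin_partition = del$bin,
                               abgd_partition = del$abgd,
                               bptp_partition = del$bptp$partition,
                               min_n_intra = config$min_n_intra)
    extra <- del
  }
  decisions <- flag_species(evidence, config$congruence)
  tally <- motu_tally(decisions)
  paths <- file.path(config$out_dir, c("decisions.tsv", "tally.tsv"))
  write_report(decisions, paths[1L], hdr)
  write_report(data.frame(quantity = names(tally),
                          value = as.integer(unlist(tally))),
               paths[2L], hdr)
  invisible(list(evidence = evidence, decisions = decisions, tally = tally,
                 pipeline = extra, paths = paths))
}
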