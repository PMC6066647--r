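#' @keywords internal
"_PACKAGE"

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Read an aligned barcode library (FASTA + metadata TSV)
#'
#' Builds a `barcode_library` from an aligned FASTA file and a tab-separated
#' specimen metadata table. Every FASTA identifier must have exactly one
#' matching row in the metadata (column `specimen_id`); sequences must all
#' have the same length (the alignment length).
#'
#' @param fasta_path path to an aligned FASTA file (IUPAC codes, `-` gaps).
#' @param metadata_path path to a UTF-8 TSV with a header and at least the
#'   columns `specimen_id` and `morphospecies`; optional columns `genus`,
#'   `family`, `site_id`, `basin`, `native_status`, `voucher`. Lines starting
#'   with `#` are ignored.
#' @return an object of class `barcode_library`: a list with `records` (a
#'   data frame of metadata plus parsed nomenclature status/qualifier),
#'   `sequences` (named uppercase character vector) and `alignment_length`.
#' @export
read_library <- function(fasta_path, metadata_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("empty FASTA file: ", fasta_path)
  seqs <- toupper(vapply(as.character(dna), paste0, collapse = "", FUN.VALUE = ""))
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if (nrow(meta) == 0L) stop("empty metadata table: ", metadata_path)
  barcode_library(seqs, meta)
}

#' Construct a barcode library from sequences and metadata
#'
#' @param sequences named character vector of aligned IUPAC DNA strings.
#' @param metadata data frame with `specimen_id`, `morphospecies` and
#'   optionally `genus`, `family`, `site_id`, `basin`, `native_status`,
#'   `voucher`.
#' @return a `barcode_library` object.
#' @export
barcode_library <- function(sequences, metadata) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (!all(c("specimen_id", "morphospecies") %in% names(metadata)))
    stop("metadata must contain columns 'specimen_id' and 'morphospecies'")
  ids <- names(sequences)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(metadata$specimen_id))
    stop("duplicate specimen_id in metadata: ",
         paste(unique(metadata$specimen_id[duplicated(metadata$specimen_id)]), collapse = ", "))
  orphans <- setdiff(ids, metadata$specimen_id)
  if (length(orphans))
    stop("FASTA entries missing from metadata: ", paste(orphans, collapse = ", "))
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence for: ",
                            paste(ids[lens == 0L], collapse = ", "))
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(range(lens), collapse = "-"),
         "); input must be aligned before loading")
  bad <- vapply(strsplit(sequences, ""), function(s) any(!s %in% IUPAC_DNA), TRUE)
  if (any(bad))
    stop("non-IUPAC characters in sequences: ", paste(ids[bad], collapse = ", "))
  meta <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  for (col in c("genus", "family", "site_id", "basin", "voucher"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  if (is.null(meta$native_status)) meta$native_status <- "unknown"
  nom <- parse_nomenclature(meta$morphospecies)
  meta$nomenclature_status <- nom$status
  meta$qualifier <- nom$qualifier
  structure(list(records = meta, sequences = sequences,
                 alignment_length = unname(lens[1L])),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", length(x$sequences), "specimens,",
      length(unique(x$records$morphospecies)), "morphospecies, alignment length",
      x$alignment_length, "bp\n")
  invisible(x)
}

#' Number of specimens in a library
#' @param x a `barcode_library`.
#' @export
n_specimens <- function(x) length(x$sequences)

#' Write a barcode library back to FASTA + TSV
#'
#' Inverse of [read_library()]; the round trip is lossless for sequences and
#' the standard metadata columns.
#'
#' @param library a `barcode_library`.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_library <- function(library, fasta_path, metadata_path) {
  stopifnot(inherits(library, "barcode_library"))
  dna <- ape::as.DNAbin(strsplit(tolower(library$sequences), ""))
  names(dna) <- names(library$sequences)
  ape::write.FASTA(dna, fasta_path)
  cols <- intersect(c("specimen_id", "morphospecies", "genus", "family",
                      "site_id", "basin", "native_status", "voucher"),
                    names(library$records))
  utils::write.table(library$records[, cols, drop = FALSE], metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(c(fasta_path, metadata_path))
}

#' Parse open-nomenclature qualifiers from a morphospecies label
#'
#' Classifies labels as formally described binomials or open nomenclature:
#' `"Genus sp."` (undescribed), `"Genus aff. epithet"` / `"Genus cf. epithet"`
#' (uncertain affinity/conferral), `"Genus gr. epithet"` (species group) and
#' suprageneric labels such as subfamily names ending in a rank suffix.
#'
#' @param label character vector of morphospecies labels.
#' @param family_suffixes rank suffixes treated as family-level open
#'   nomenclature when a single-word label ends with one of them.
#' @return data frame with columns `status` (`"described"`/`"open"`) and
#'   `qualifier` (`"none"`, `"sp"`, `"aff"`, `"cf"`, `"gr"`, `"family_level"`).
#' @examples
#' parse_nomenclature(c("Hoplias malabaricus", "Characidium sp.",
#'                      "Trichomycterus aff. alternatus", "Neoplecostominae"))
#' @export
parse_nomenclature <- function(label,
                               family_suffixes = c("idae", "inae", "ini")) {
  stopifnot(is.character(label), all(nzchar(label)))
  one <- function(lab) {
    if (grepl("(^|\\s)sp\\.?($|\\s)", lab)) return(c("open", "sp"))
    if (grepl("\\saff\\.?\\s", lab)) return(c("open", "aff"))
    if (grepl("\\scf\\.?\\s", lab)) return(c("open", "cf"))
    if (grepl("\\sgr\\.?\\s", lab)) return(c("open", "gr"))
    words <- strsplit(trimws(lab), "\\s+")[[1L]]
    if (length(words) == 1L &&
        any(vapply(family_suffixes, function(s) endsWith(words, s), TRUE)))
      return(c("open", "family_level"))
    c("described", "none")
  }
  out <- t(vapply(label, one, character(2L)))
  data.frame(status = unname(out[, 1L]), qualifier = unname(out[, 2L]),
             stringsAsFactors = FALSE)
}

# stop codons per NCBI translation table id (DNA alphabet)
stop_codons <- function(code = 2L) {
  switch(as.character(code),
         "1" = c("TAA", "TAG", "TGA"),
         "2" = c("TAA", "TAG", "AGA", "AGG"),
         stop("unsupported genetic code table: ", code))
}

#' Screen a barcode sequence for NUMT artefacts
#'
#' Nuclear copies of mitochondrial genes (NUMTs) betray themselves in a
#' putative COI barcode through frame-shifting indels or in-frame stop
#' codons. The screen strips terminal gaps, picks the reading frame (of
#' three) minimizing the number of stop codons, and reports the stop count
#' in that frame together with an internal-gap flag. Only unambiguous
#' A/C/G/T codons are counted.
#'
#' @param sequence a single IUPAC DNA string (length >= 60), or a
#'   `barcode_library` whose every record is screened.
#' @param code NCBI genetic code table id; 2 = vertebrate mitochondrial
#'   (stops TAA, TAG, AGA, AGG).
#' @return a one-row data frame (or one row per specimen) with columns
#'   `specimen_id`, `frame`, `stop_codon_count`, `internal_gap`, `passed`;
#'   `passed` is true iff no stop codons and no internal gaps.
#' @export
numt_screen <- function(sequence, code = 2L) {
  if (inherits(sequence, "barcode_library")) {
    out <- do.call(rbind, lapply(names(sequence$sequences), function(id) {
      r <- numt_screen(sequence$sequences[[id]], code = code)
      r$specimen_id <- id
      r
    }))
    return(out[, c("specimen_id", "frame", "stop_codon_count",
                   "internal_gap", "passed")])
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1L]]
  nongap <- which(chars != "-")
  if (length(nongap) == 0L || all(chars[nongap] == "N"))
    stop("sequence is entirely gaps/Ns")
  if (length(nongap) < 60L) stop("sequence too short to screen (< 60 bp)")
  core <- chars[nongap[1L]:nongap[length(nongap)]]
  internal_gap <- any(core == "-")
  bases <- core[core != "-"]
  stops <- stop_codons(code)
  count_stops <- function(frame) {
    b <- bases[(frame + 1L):length(bases)]
    n <- length(b) %/% 3L
    if (n == 0L) return(0L)
    cod <- paste0(b[seq(1L, by = 3L, length.out = n)],
                  b[seq(2L, by = 3L, length.out = n)],
                  b[seq(3L, by = 3L, length.out = n)])
    ok <- !grepl("[^ACGT]", cod)
    sum(cod[ok] %in% stops)
  }
  counts <- vapply(0:2, count_stops, integer(1L))
  frame <- which.min(counts) - 1L
  data.frame(specimen_id = NA_character_, frame = frame,
             stop_codon_count = counts[frame + 1L],
             internal_gap = internal_gap,
             passed = counts[frame + 1L] == 0L && !internal_gap,
             stringsAsFactors = FALSE)
}

#' Reverse-complement a DNA string (IUPAC aware)
#' @param sequence a single DNA string.
#' @export
revcomp <- function(sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N", "-" = "-")
  chars <- rev(strsplit(toupper(sequence), "")[[1L]])
  paste0(comp[chars], collapse = "")
}
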