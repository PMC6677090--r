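#' Construct a mature-miRNA catalog
#'
#' A catalog is an ordered table of named mature miRNA sequences over the DNA
#' alphabet. The seed (positions 2-8, 1-based) is derived from the sequence at
#' construction and never stored independently. Identical sequences under
#' different names (miRNA families such as let-7) are kept and flagged via the
#' `duplicate_sequence` column; duplicate names are an error.
#'
#' @param name character vector of unique miRNA identifiers.
#' @param sequence character vector of DNA sequences (A/C/G/T only), one per
#'   name, each at least 8 nt.
#' @param source free-text provenance string (e.g. "miRBase 20.0 ssc subset").
#' @return A `mir_catalog` data frame with columns `name`, `sequence`, `seed`,
#'   `duplicate_sequence`.
#' @export
mir_catalog <- function(name, sequence, source = "unknown") {
  stopifnot(is.character(name), is.character(sequence))
  if (length(name) != length(sequence)) {
    stop("`name` and `sequence` must have the same length")
  }
  if (length(name) == 0L) stop("catalog is empty")
  if (anyDuplicated(name)) {
    dups <- unique(name[duplicated(name)])
    stop("duplicate miRNA name(s) in catalog: ", paste(dups, collapse = ", "))
  }
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T}: ", name[bad][1L])
  }
  short <- nchar(sequence) < 8L
  if (any(short)) {
    stop("sequence shorter than 8 nt (no seed): ", name[short][1L])
  }
  dup_seq <- duplicated(sequence) | duplicated(sequence, fromLast = TRUE)
  out <- data.frame(
    name = name,
    sequence = sequence,
    seed = seed_of(sequence),
    duplicate_sequence = dup_seq,
    stringsAsFactors = FALSE
  )
  attr(out, "source") <- source
  class(out) <- c("mir_catalog", "data.frame")
  out
}

#' Seed region of a mature miRNA
#'
#' The seed is the 7-mer at positions 2 to 8 (1-based, inclusive) of the
#' mature sequence, the primary determinant of target binding.
#'
#' @param sequence character vector of sequences, each at least 8 nt.
#' @return character vector of 7-mers.
#' @examples
#' seed_of("TGGAATGTAAAGAAGTATGTAT") # "GGAATGT"
#' @export
seed_of <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(nchar(sequence) < 8L)) {
    stop("sequence must be at least 8 nt to have a seed (positions 2-8)")
  }
  substr(sequence, 2L, 8L)
}

#' Load a mature-miRNA catalog from FASTA
#'
#' Reads a miRBase-dialect mature FASTA: headers are whitespace-delimited with
#' the name as first token; sequences may be RNA (U is converted to T) and may
#' span multiple lines. Records whose sequence contains N are dropped with a
#' warning. File order is preserved.
#'
#' @param path path to a FASTA file.
#' @param species_prefix optional name prefix (e.g. "ssc"); when given, only
#'   records whose name starts with it are retained.
#' @return A [mir_catalog()].
#' @export
load_mature_fasta <- function(path, species_prefix = NULL) {
  if (!file.exists(path)) stop("catalog FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[\r ]", "", seqs)
  if (!is.null(species_prefix)) {
    keep <- startsWith(nm, species_prefix)
    nm <- nm[keep]
    seqs <- seqs[keep]
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (any(has_n)) {
    warning(sum(has_n), " record(s) containing N rejected")
    nm <- nm[!has_n]
    seqs <- seqs[!has_n]
  }
  if (length(nm) == 0L) {
    stop("no catalog entries remain after filtering (prefix: ",
         if (is.null(species_prefix)) "<none>" else species_prefix, ")")
  }
  if (anyDuplicated(nm)) {
    dups <- unique(nm[duplicated(nm)])
    stop("duplicate miRNA name(s) in catalog: ", paste(dups, collapse = ", "))
  }
  mir_catalog(unname(nm), unname(seqs), source = path)
}

#' Write a catalog to FASTA
#'
#' Emits one `>name` header and a single sequence line per entry, in catalog
#' order. Reloading the file with [load_mature_fasta()] round-trips the
#' catalog.
#'
#' @param catalog a `mir_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mature_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "mir_catalog"))
  set <- Biostrings::BStringSet(stats::setNames(catalog$sequence, catalog$name))
  Biostrings::writeXStringSet(set, path, width = 100000L)
  invisible(path)
}

#' @export
print.mir_catalog <- function(x, ...) {
  cat("mature miRNA catalog: ", nrow(x), " entries (",
      sum(x$duplicate_sequence), " with shared sequence); source: ",
      attr(x, "source"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more\n", sep = "")
  invisible(x)
}
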