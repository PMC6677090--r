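# Read cleaning, tag collapsing and library-level summaries.
#
# Cleaning applies a fixed removal precedence so that every raw read lands in
# exactly one category and the report is a partition of the input:
#   low quality -> poly-N -> 5'-adapter contamination -> missing 3'-adapter
#   -> homopolymer -> length outside [min_len, max_len].

#' Clean raw small-RNA reads
#'
#' Filters a raw FASTQ library and trims the 3' adapter, reporting how many
#' reads each rule removed. The first matching rule claims a read, in the
#' precedence order: mean Phred below `min_mean_q`; any N; read begins with
#' `adapter5`; `adapter3` (its first 8 nt, exact match) absent — when present
#' it and everything after it is trimmed; any single base making up at least
#' `homopolymer_frac` of the trimmed insert; insert length outside
#' `[min_len, max_len]`. Pass `adapter3 = NULL` / `adapter5 = NULL` for
#' libraries whose adapters are already removed (e.g. simulated reads); the
#' corresponding rules are then skipped.
#'
#' @param fastq path to a Phred+33 FASTQ file.
#' @param adapter3,adapter5 adapter sequences over \{A,C,G,T\}, or `NULL`.
#' @param min_len,max_len retained insert length window (nt); the defaults
#'   reflect the 18-30 nt size-selection window of small-RNA library preps.
#' @param homopolymer_frac homopolymer fraction threshold in (0,1].
#' @param min_mean_q minimum mean Phred quality.
#' @return list with `reads` (character vector of clean trimmed inserts, in
#'   input order) and `report` (a `cleaning_report`).
#' @export
clean_reads <- function(fastq, adapter3 = NULL, adapter5 = NULL,
                        min_len = 18L, max_len = 30L,
                        homopolymer_frac = 0.8, min_mean_q = 20) {
  parsed <- read_fastq(fastq)
  seqs <- parsed$seq
  n <- length(seqs)
  status <- rep.int(0L, n) # 0 = unclaimed

  # 1. low quality
  if (n > 0L) {
    claim <- parsed$mean_q < min_mean_q
    status[claim] <- 1L
  }
  # 2. poly-N
  open <- status == 0L
  claim <- open & grepl("N", seqs, fixed = TRUE)
  status[claim] <- 2L
  # 3. 5'-adapter contamination
  if (!is.null(adapter5)) {
    open <- status == 0L
    claim <- open & startsWith(seqs, adapter5)
    status[claim] <- 3L
  }
  # 4. 3'-adapter search and trim (exact match of the adapter's first 8 nt)
  insert <- seqs
  if (!is.null(adapter3)) {
    key <- substr(adapter3, 1L, 8L)
    open <- status == 0L
    pos <- rep.int(-1L, n)
    pos[open] <- regexpr(key, seqs[open], fixed = TRUE)
    claim <- open & pos < 0L
    status[claim] <- 4L
    found <- open & pos > 0L
    insert[found] <- substr(seqs[found], 1L, pos[found] - 1L)
  }
  # 5. homopolymer insert
  open <- status == 0L
  if (any(open)) {
    ins <- insert[open]
    len <- nchar(ins)
    maxbase <- pmax(
      nchar(gsub("[^A]", "", ins)), nchar(gsub("[^C]", "", ins)),
      nchar(gsub("[^G]", "", ins)), nchar(gsub("[^T]", "", ins))
    )
    claim <- len > 0L & maxbase / pmax(len, 1L) >= homopolymer_frac
    status[which(open)[claim]] <- 5L
  }
  # 6. length window
  open <- status == 0L
  len <- nchar(insert)
  claim <- open & (len < min_len | len > max_len)
  status[claim] <- 6L

  report <- cleaning_report(
    raw_reads = n,
    removed_low_quality = sum(status == 1L),
    removed_polyN = sum(status == 2L),
    removed_5adapter = sum(status == 3L),
    removed_no3adapter = sum(status == 4L),
    removed_polyACGT = sum(status == 5L),
    removed_length = sum(status == 6L),
    clean_reads = sum(status == 0L)
  )
  list(reads = insert[status == 0L], report = report)
}

#' Cleaning report constructor
#'
#' @param raw_reads,removed_low_quality,removed_polyN,removed_5adapter,removed_no3adapter,removed_polyACGT,removed_length,clean_reads
#'   non-negative category counts; categories plus clean reads must equal raw
#'   reads.
#' @return a `cleaning_report` (named list).
#' @export
cleaning_report <- function(raw_reads, removed_low_quality, removed_polyN,
                            removed_5adapter, removed_no3adapter,
                            removed_polyACGT, removed_length, clean_reads) {
  rep <- list(
    raw_reads = raw_reads,
    removed_low_quality = removed_low_quality,
    removed_polyN = removed_polyN,
    removed_5adapter = removed_5adapter,
    removed_no3adapter = removed_no3adapter,
    removed_polyACGT = removed_polyACGT,
    removed_length = removed_length,
    clean_reads = clean_reads
  )
  vals <- unlist(rep)
  if (any(vals < 0)) stop("cleaning report counts must be non-negative")
  removed <- sum(vals) - rep$raw_reads - rep$clean_reads
  if (removed + rep$clean_reads != rep$raw_reads) {
    stop("cleaning report does not partition raw reads: ", rep$raw_reads,
         " != ", removed, " removed + ", rep$clean_reads, " clean")
  }
  class(rep) <- "cleaning_report"
  rep
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning report:", x$raw_reads, "raw ->", x$clean_reads, "clean\n")
  for (f in setdiff(names(x), c("raw_reads", "clean_reads"))) {
    cat("  ", f, ": ", x[[f]], "\n", sep = "")
  }
  invisible(x)
}

# Parse Phred+33 FASTQ via Biostrings; on failure, locate the offending
# record with a line-level scan so the error names its index.
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    seqs <- as.character(set)
    quals <- as.character(S4Vectors::mcols(set)$qualities)
    # short quality lines come back NUL-padded; long ones mismatch here
    if (any(nchar(quals) != nchar(seqs)) || any(nchar(seqs) == 0L)) {
      stop("sequence/quality mismatch")
    }
    list(seq = seqs, qual = quals)
  }, error = function(e) NULL)
  if (is.null(parsed)) {
    idx <- .locate_bad_fastq_record(path)
    stop("malformed FASTQ record ", idx, " in ", path, call. = FALSE)
  }
  seqs <- parsed$seq
  quals <- parsed$qual
  mean_q <- if (length(seqs)) {
    ints <- utf8ToInt(paste(quals, collapse = "")) - 33L
    grp <- rep.int(seq_along(quals), nchar(quals))
    as.vector(rowsum(ints, grp)) / nchar(quals)
  } else {
    numeric(0)
  }
  list(seq = unname(seqs), qual = unname(quals), mean_q = mean_q)
}

.locate_bad_fastq_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  for (i in seq_len(n_rec)) {
    b <- (i - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@") || !startsWith(lines[b + 3L], "+") ||
        nchar(lines[b + 2L]) == 0L ||
        nchar(lines[b + 2L]) != nchar(lines[b + 4L])) {
      return(i)
    }
  }
  n_rec + 1L
}

#' Collapse clean reads into counted unique tags
#'
#' Identical sequences are merged into one sRNA tag carrying its read count;
#' the total read count is preserved exactly. Tags are ordered by decreasing
#' count, then lexicographically, so output is deterministic.
#'
#' @param reads character vector of clean reads.
#' @param library_label label for the library (e.g. "LL", "ER").
#' @return a `tag_set` data frame (`tag`, `count`) with attributes
#'   `total_reads` and `library_label`.
#' @export
collapse_tags <- function(reads, library_label = "library") {
  if (length(reads) == 0L) {
    df <- data.frame(tag = character(0), count = integer(0),
                     stringsAsFactors = FALSE)
  } else {
    r <- rle(sort(reads, method = "radix"))
    df <- data.frame(tag = r$values, count = r$lengths,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$tag, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
  }
  tag_set(df, library_label)
}

#' Tag set constructor
#'
#' @param df data frame with columns `tag` (unique) and `count` (positive).
#' @param library_label library label.
#' @return a `tag_set`.
#' @export
tag_set <- function(df, library_label = "library") {
  stopifnot(is.data.frame(df), all(c("tag", "count") %in% names(df)))
  if (anyDuplicated(df$tag)) stop("tags must be unique")
  if (nrow(df) && any(df$count < 1)) stop("tag counts must be >= 1")
  attr(df, "total_reads") <- as.integer(sum(df$count))
  attr(df, "library_label") <- library_label
  class(df) <- c("tag_set", "data.frame")
  df
}

#' Total read count of a tag set
#' @param tags a `tag_set`.
#' @return integer total.
#' @export
total_reads <- function(tags) attr(tags, "total_reads")

#' Read-length distribution of a tag set
#'
#' Read counts (not unique-tag counts) aggregated by tag length; fractions
#' are over the library's total reads and sum to 1.
#'
#' @param tags a non-empty `tag_set`.
#' @return data frame (`length`, `reads`, `fraction`) sorted by length.
#' @export
length_distribution <- function(tags) {
  stopifnot(inherits(tags, "tag_set"))
  if (nrow(tags) == 0L) stop("empty tag set has no length distribution")
  len <- nchar(tags$tag)
  agg <- stats::aggregate(list(reads = tags$count), list(length = len), sum)
  agg <- agg[order(agg$length), , drop = FALSE]
  agg$fraction <- agg$reads / total_reads(tags)
  rownames(agg) <- NULL
  agg
}

#' Compare the tag content of two libraries
#'
#' Partitions the union of tags into common (present in both libraries) and
#' library-specific sets, at both the unique-tag and the total-read level. A
#' common tag's total contribution is its count in A plus its count in B;
#' fractions are over `total_reads(a) + total_reads(b)`.
#'
#' @param a,b `tag_set` objects.
#' @return a `library_comparison` (named list).
#' @export
compare_libraries <- function(a, b) {
  stopifnot(inherits(a, "tag_set"), inherits(b, "tag_set"))
  in_b <- a$tag %in% b$tag
  in_a <- b$tag %in% a$tag
  common_unique <- sum(in_b)
  common_total <- sum(a$count[in_b]) + sum(b$count[in_a])
  a_spec_total <- sum(a$count[!in_b])
  b_spec_total <- sum(b$count[!in_a])
  grand <- total_reads(a) + total_reads(b)
  grand_unique <- common_unique + sum(!in_b) + sum(!in_a)
  out <- list(
    common_unique = common_unique,
    a_specific_unique = sum(!in_b),
    b_specific_unique = sum(!in_a),
    common_total = common_total,
    a_specific_total = a_spec_total,
    b_specific_total = b_spec_total,
    common_total_fraction = common_total / grand,
    a_specific_total_fraction = a_spec_total / grand,
    b_specific_total_fraction = b_spec_total / grand,
    common_unique_fraction = common_unique / grand_unique,
    a_specific_unique_fraction = sum(!in_b) / grand_unique,
    b_specific_unique_fraction = sum(!in_a) / grand_unique
  )
  class(out) <- "library_comparison"
  out
}

#' @export
print.library_comparison <- function(x, ...) {
  cat(sprintf(
    "library comparison: %d common tags (%.2f%% of reads); %d / %d specific to A / B\n",
    x$common_unique, 100 * x$common_total_fraction,
    x$a_specific_unique, x$b_specific_unique))
  invisible(x)
}

#' Write a collapsed tag set as FASTA
#'
#' Header dialect `>t{serial}_x{count}`, e.g. `>t1_x12345`.
#'
#' @param tags a `tag_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  stopifnot(inherits(tags, "tag_set"))
  hdr <- paste0(">t", seq_len(nrow(tags)), "_x", tags$count)
  writeLines(as.vector(rbind(hdr, tags$tag)), path)
  invisible(path)
}
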