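# Exact-match quantification of mature miRNAs.
#
# A tag is assigned to a miRNA only by exact full-sequence identity (same
# length, zero mismatches); multimapping arises only from identical mature
# sequences (miRNA families) and a multimapped tag counts fully toward every
# matched entry. Unmatched tags form the unannotated pool consumed by the
# variant analysis.

#' Match tags against a catalog by exact sequence identity
#'
#' @param tags a `tag_set`.
#' @param catalog a non-empty [mir_catalog()].
#' @return a `tag_assignment` data frame (`tag`, `count`, `n_matches`,
#'   `multimap`) with a list-column `matches` of matched miRNA names.
#' @export
match_tags <- function(tags, catalog) {
  stopifnot(inherits(tags, "tag_set"), inherits(catalog, "mir_catalog"))
  if (nrow(catalog) == 0L) stop("catalog is empty")
  seq2names <- split(catalog$name, catalog$sequence)
  idx <- match(tags$tag, names(seq2names))
  matches <- vector("list", nrow(tags))
  matches[] <- list(character(0))
  hit <- !is.na(idx)
  matches[hit] <- seq2names[idx[hit]]
  out <- data.frame(tag = tags$tag, count = tags$count,
                    n_matches = lengths(matches),
                    stringsAsFactors = FALSE)
  out$multimap <- out$n_matches > 1L
  out$matches <- matches
  attr(out, "catalog_names") <- catalog$name
  attr(out, "tagset_signature") <- .tagset_signature(tags)
  class(out) <- c("tag_assignment", "data.frame")
  out
}

.tagset_signature <- function(tags) {
  list(n = nrow(tags), total = total_reads(tags),
       label = attr(tags, "library_label"))
}

#' Per-miRNA read counts from a tag assignment
#'
#' Sums the read counts of every tag matched to each miRNA. Multimapped tags
#' contribute their full count to every matched entry, so the column sum may
#' exceed the number of assigned reads. Catalog miRNAs with no matched tag
#' are reported with count 0 (enabling library-exclusive expression calls).
#'
#' @param assign a `tag_assignment` built from `tags`.
#' @param tags the same `tag_set` the assignment was built from.
#' @return data frame (`mirna`, `count`) in catalog order.
#' @export
count_mirnas <- function(assign, tags) {
  stopifnot(inherits(assign, "tag_assignment"), inherits(tags, "tag_set"))
  if (!identical(attr(assign, "tagset_signature"), .tagset_signature(tags))) {
    stop("tag assignment was not built from this tag set")
  }
  cat_names <- attr(assign, "catalog_names")
  counts <- stats::setNames(rep.int(0L, length(cat_names)), cat_names)
  hit <- assign$n_matches > 0L
  if (any(hit)) {
    nm <- unlist(assign$matches[hit], use.names = FALSE)
    ct <- rep.int(assign$count[hit], assign$n_matches[hit])
    agg <- rowsum(ct, nm)
    counts[rownames(agg)] <- counts[rownames(agg)] + as.vector(agg)
  }
  data.frame(mirna = cat_names, count = as.integer(unname(counts)),
             stringsAsFactors = FALSE)
}

#' Unannotated tag pool
#'
#' Tags with no exact catalog match, as a `tag_set`; the input to seed-edit
#' and isomiR profiling.
#'
#' @param assign a `tag_assignment`.
#' @param tags the `tag_set` it was built from.
#' @return a `tag_set`.
#' @export
unannotated_tags <- function(assign, tags) {
  stopifnot(inherits(assign, "tag_assignment"), inherits(tags, "tag_set"))
  if (!identical(attr(assign, "tagset_signature"), .tagset_signature(tags))) {
    stop("tag assignment was not built from this tag set")
  }
  keep <- assign$n_matches == 0L
  df <- data.frame(tag = assign$tag[keep], count = assign$count[keep],
                   stringsAsFactors = FALSE)
  tag_set(df, attr(tags, "library_label"))
}

#' Tags-per-million normalisation
#'
#' TPM of a miRNA is its read count divided by the library's total clean-read
#' count, times 1e6. The denominator is the total clean reads of the library,
#' not the annotated subtotal.
#'
#' @param counts data frame (`mirna`, `count`) from [count_mirnas()], or a
#'   named numeric vector.
#' @param N total clean reads in the library (>= 1).
#' @param library_label label stored on the profile.
#' @return an `expression_profile` data frame (`mirna`, `count`, `tpm`) with
#'   attributes `library_total` and `library_label`.
#' @export
tpm_normalize <- function(counts, N, library_label = "library") {
  if (!is.data.frame(counts)) {
    counts <- data.frame(mirna = names(counts), count = as.vector(counts),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mirna", "count") %in% names(counts)))
  if (length(N) != 1L || is.na(N) || N < 1) {
    stop("N must be a positive library total (clean reads)")
  }
  if (any(counts$count < 0)) stop("counts must be non-negative")
  out <- data.frame(mirna = counts$mirna, count = counts$count,
                    tpm = counts$count / N * 1e6,
                    stringsAsFactors = FALSE)
  attr(out, "library_total") <- N
  attr(out, "library_label") <- library_label
  class(out) <- c("expression_profile", "data.frame")
  out
}

#' Quantify a tag set against a catalog
#'
#' Convenience wrapper chaining [match_tags()], [count_mirnas()] and
#' [tpm_normalize()]; `N` defaults to the tag set's total reads (the clean
#' total when the tags come straight from cleaning).
#'
#' @param tags a `tag_set`.
#' @param catalog a [mir_catalog()].
#' @param N library total for the TPM denominator.
#' @return list with `profile` (an `expression_profile`), `assignment` and
#'   `unannotated` (a `tag_set`).
#' @export
quantify_library <- function(tags, catalog, N = total_reads(tags)) {
  assign <- match_tags(tags, catalog)
  counts <- count_mirnas(assign, tags)
  list(
    profile = tpm_normalize(counts, N, attr(tags, "library_label")),
    assignment = assign,
    unannotated = unannotated_tags(assign, tags)
  )
}
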