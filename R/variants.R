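# isomiR end-variant classification and seed-edit detection.
#
# End variants (3' trims/additions, 5' shifts) and internal single
# substitutions are profiled among tags that failed exact-match assignment.
# A seed edit is a length-preserving single substitution at positions 2-8 of
# the mature sequence; a position-1 or 3'-half substitution is reported as
# nonseed_sub and excluded from the substitution spectrum.

#' Classify an unannotated tag as an isomiR of a mature sequence
#'
#' Classes, in precedence order when several fit:
#' * `trim3`: tag equals the mature with 1-2 terminal 3' bases removed
#'   (offset -1 or -2);
#' * `add3`: tag equals the mature plus 1-2 extra 3' bases (offset +1 or +2,
#'   `bases` records the addition);
#' * `shift5`: tag equals the mature with its first base removed, or with one
#'   base prepended, the 3' end lying within +-2 nt of the mature 3' end;
#' * no-call (`NULL` class) otherwise.
#'
#' @param tag tag sequence (must differ from the mature sequence; canonical
#'   tags are handled by quantification).
#' @param mature mature miRNA sequence.
#' @return list with `class` (`"trim3"`, `"add3"`, `"shift5"` or `NA`),
#'   `offset` (signed 3' offset for end variants, 5' offset for shifts) and
#'   `bases` (added 3' bases for `add3`, else `NA`).
#' @export
classify_isomir <- function(tag, mature) {
  stopifnot(is.character(tag), length(tag) == 1L,
            is.character(mature), length(mature) == 1L)
  if (identical(tag, mature)) {
    stop("tag equals the mature sequence; canonical reads are not isomiRs")
  }
  nt <- nchar(tag)
  nm <- nchar(mature)
  # trim3: 1-2 terminal 3' bases removed
  if (nt %in% c(nm - 1L, nm - 2L) && tag == substr(mature, 1L, nt)) {
    return(list(class = "trim3", offset = nt - nm, bases = NA_character_))
  }
  # add3: 1-2 extra 3' bases
  if (nt %in% c(nm + 1L, nm + 2L) && substr(tag, 1L, nm) == mature) {
    return(list(class = "add3", offset = nt - nm,
                bases = substr(tag, nm + 1L, nt)))
  }
  # shift5: first mature base removed
  if (tag == substr(mature, 2L, nt + 1L) && abs(nt + 1L - nm) <= 2L) {
    return(list(class = "shift5", offset = 1L, bases = NA_character_))
  }
  # shift5: one base prepended
  if (nt >= 2L && substr(tag, 2L, nt) == substr(mature, 1L, nt - 1L) &&
      abs(nt - 1L - nm) <= 2L) {
    return(list(class = "shift5", offset = -1L,
                bases = substr(tag, 1L, 1L)))
  }
  list(class = NA_character_, offset = NA_integer_, bases = NA_character_)
}

# Single-substitution neighbourhood of a catalog: every sequence obtained by
# substituting one position of one mature sequence, with its provenance.
.substitution_index <- function(catalog) {
  recs <- lapply(seq_len(nrow(catalog)), function(i) {
    s <- catalog$sequence[i]
    L <- nchar(s)
    ref <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- rep(seq_len(L), each = 3L)
    to <- unlist(lapply(ref, function(b) setdiff(.BASES, b)),
                 use.names = FALSE)
    var <- rep.int(s, length(pos))
    substr(var, pos, pos) <- to
    data.frame(variant = var, mirna = catalog$name[i], position = pos,
               from = ref[pos], to = to, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Detect single-substitution variants (seed edits) among unannotated tags
#'
#' A tag yields a `seed_edit` event for a miRNA when it has the same length
#' as the mature sequence, differs from it at exactly one position, that
#' position lies in the seed (2-8), and the tag's read count reaches
#' `min_count`. Single mismatches outside the seed (including position 1)
#' yield `nonseed_sub` events, which are reported but excluded from the
#' substitution spectrum. The same abundance floor is applied to both
#' classes. A tag matching several miRNAs this way yields one event per
#' miRNA. Matching uses a one-substitution neighbourhood index over the
#' catalog; behaviour is identical to an all-pairs scan.
#'
#' @param unannotated a `tag_set` of tags with no exact catalog match.
#' @param catalog a [mir_catalog()].
#' @param min_count minimum supporting read count (>= 1); a floor against
#'   sequencing-error artifacts.
#' @return data frame of `VariantEvent`s: `mirna`, `class`, `position`
#'   (1-based on the mature sequence), `from`, `to`, `tag`, `count`.
#' @export
detect_seed_edits <- function(unannotated, catalog, min_count = 5L) {
  stopifnot(inherits(unannotated, "tag_set"), inherits(catalog, "mir_catalog"))
  if (min_count < 1L) stop("min_count must be >= 1")
  empty <- data.frame(mirna = character(0), class = character(0),
                      position = integer(0), from = character(0),
                      to = character(0), tag = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(unannotated) == 0L || nrow(catalog) == 0L) return(empty)
  idx <- .substitution_index(catalog)
  hits <- merge(
    data.frame(variant = unannotated$tag, count = unannotated$count,
               stringsAsFactors = FALSE),
    idx, by = "variant"
  )
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$count >= min_count, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(
    mirna = hits$mirna,
    class = ifelse(hits$position >= 2L & hits$position <= 8L,
                   "seed_edit", "nonseed_sub"),
    position = hits$position, from = hits$from, to = hits$to,
    tag = hits$variant, count = as.integer(hits$count),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna, out$position, out$to, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.SPECTRUM_CELLS <- {
  g <- expand.grid(to = c("A", "C", "G", "T"), from = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)[, 2:1]
  g[g$from != g$to, , drop = FALSE]
}

#' Substitution spectrum of seed-edit events
#'
#' Tallies the 12 possible from-to substitutions over seed-edit events. Each
#' distinct (miRNA, position, from, to) combination contributes one event to
#' its cell — event-level, not read-weighted — so one abundant edit cannot
#' dominate the spectrum. Percentages are over the total event count and sum
#' to 100 when any events exist; with no events all cells are zero and the
#' `empty` attribute is set.
#'
#' @param events data frame from [detect_seed_edits()]; only rows with class
#'   `seed_edit` are used.
#' @return data frame (`from`, `to`, `count`, `percent`) over the 12 ordered
#'   cells, with attribute `empty`.
#' @export
substitution_spectrum <- function(events) {
  ev <- events[events$class == "seed_edit", , drop = FALSE]
  ev <- unique(ev[, c("mirna", "position", "from", "to")])
  cells <- .SPECTRUM_CELLS
  key <- paste(cells$from, cells$to)
  counts <- table(factor(paste(ev$from, ev$to), levels = key))
  out <- data.frame(from = cells$from, to = cells$to,
                    count = as.integer(counts), stringsAsFactors = FALSE)
  total <- sum(out$count)
  out$percent <- if (total > 0) out$count / total * 100 else 0
  rownames(out) <- NULL
  attr(out, "empty") <- total == 0L
  out
}

#' Number of distinct seed-edited miRNAs
#'
#' @param events data frame from [detect_seed_edits()].
#' @return integer count of distinct miRNA names among `seed_edit` events.
#' @export
edited_mirna_count <- function(events) {
  length(unique(events$mirna[events$class == "seed_edit"]))
}
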