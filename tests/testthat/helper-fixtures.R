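# Fixtures are built in code; no binary or stored data.

# A tiny fixed catalog with two family members sharing a sequence.
toy_catalog <- function() {
  mir_catalog(
    name = c("mir-1", "mir-2", "mir-2b", "mir-3"),
    sequence = c(
      "TGGAATGTAAAGAAGTATGTAT",   # 22 nt
      "ACGTACGTACGTACGTACGTAC",   # 22 nt, shared
      "ACGTACGTACGTACGTACGTAC",   # family member of mir-2
      "TTTACCGGTTAACCGGTTAACC"    # 22 nt
    ),
    source = "toy"
  )
}

# Write a FASTQ file from sequences and per-read qualities (single character
# recycled over the read, or full-length strings).
write_fastq_fixture <- function(seqs, quals = "I", path = tempfile(fileext = ".fastq")) {
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(path)
  }
  quals <- rep_len(quals, length(seqs))
  q <- ifelse(nchar(quals) == 1L, strrep(quals, nchar(seqs)), quals)
  writeLines(as.vector(rbind(
    paste0("@r", seq_along(seqs)), seqs, "+", q
  )), path)
  path
}

tag_set_of <- function(...) {
  counts <- c(...)
  tag_set(data.frame(tag = names(counts), count = as.integer(counts),
                     stringsAsFactors = FALSE), "test")
}

# Brute-force all-pairs oracle for single-substitution detection: compares
# every tag to every equal-length mature sequence position by position.
brute_force_substitutions <- function(unannotated, catalog, min_count) {
  out <- list()
  for (i in seq_len(nrow(unannotated))) {
    tg <- unannotated$tag[i]
    ct <- unannotated$count[i]
    if (ct < min_count) next
    for (j in seq_len(nrow(catalog))) {
      mt <- catalog$sequence[j]
      if (nchar(tg) != nchar(mt)) next
      a <- strsplit(tg, "")[[1]]
      b <- strsplit(mt, "")[[1]]
      d <- which(a != b)
      if (length(d) != 1L) next
      out[[length(out) + 1L]] <- data.frame(
        mirna = catalog$name[j],
        class = if (d >= 2 && d <= 8) "seed_edit" else "nonseed_sub",
        position = d, from = b[d], to = a[d], tag = tg, count = ct,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(0), class = character(0),
                      position = integer(0), from = character(0),
                      to = character(0), tag = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$mirna, df$position, df$to, method = "radix"), ]
  rownames(df) <- NULL
  df
}

# Exhaustive enumeration oracle for the hypergeometric upper tail:
# P(overlap >= k) by enumerating all size-n query subsets is infeasible, so
# enumerate the overlap distribution directly from counting combinations.
hyper_tail_oracle <- function(k, K, M, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}
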