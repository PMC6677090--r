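# Shared helpers: TSV conventions and stage-derived RNG seeds.

#' Write a data frame as tab-delimited text
#'
#' The interchange format between pipeline stages: tab-delimited, header row,
#' "." for missing values, no quoting, no row names.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a tab-delimited file written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Deterministic per-stage sub-seed: one global seed governs all stochastic
# stages; each stage derives its own seed from its name so stages stay
# independent yet reproducible.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}
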