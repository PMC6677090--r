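# Hypergeometric over-representation analysis over a user-supplied term map,
# and relative qPCR quantification by the 2^-ddCt method.

#' Build a term-to-gene map
#'
#' @param terms named list mapping term identifiers to character vectors of
#'   gene identifiers.
#' @param universe character vector of all annotated genes; must contain
#'   every gene of every term.
#' @return a `term_map` list with elements `terms` and `universe`.
#' @export
term_map <- function(terms, universe) {
  stopifnot(is.list(terms))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  outside <- setdiff(unique(unlist(terms, use.names = FALSE)), universe)
  if (length(outside)) {
    stop("term genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  out <- list(terms = terms, universe = universe)
  class(out) <- "term_map"
  out
}

#' Read a term map from long-format TSV
#'
#' Expects two tab-separated columns, `term` and `gene` (header optional in
#' the sense that a header row named exactly `term`/`gene` is dropped). The
#' universe defaults to all genes appearing in the file, optionally extended
#' by `extra_universe`.
#'
#' @param path TSV path.
#' @param extra_universe additional annotated genes outside any term.
#' @return a [term_map()].
#' @export
read_term_map <- function(path, extra_universe = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("term", "gene"))
  if (nrow(df) && df$term[1] == "term" && df$gene[1] == "gene") {
    df <- df[-1L, , drop = FALSE]
  }
  term_map(split(df$gene, df$term), unique(c(df$gene, extra_universe)))
}

#' Hypergeometric term enrichment of a gene set
#'
#' For each term annotating `K` of the `M` universe genes, with a query of
#' size `n` overlapping the term in `k` genes, the over-representation
#' p-value is the upper tail `P(X >= k)` of the hypergeometric distribution;
#' `q` is the BH adjustment over all tested terms. Query genes outside the
#' universe are dropped (their number is recorded in the `dropped` attribute).
#' Terms with `k = 0` are reported with `p = 1`.
#'
#' @param query character vector of gene identifiers.
#' @param map a [term_map()].
#' @return data frame (`term`, `k`, `K`, `n`, `M`, `p`, `q`) sorted by `p`,
#'   with attribute `dropped`.
#' @export
hypergeom_enrich <- function(query, map) {
  stopifnot(inherits(map, "term_map"))
  M <- length(map$universe)
  if (M == 0L) stop("universe is empty")
  query <- unique(as.character(query))
  dropped <- sum(!(query %in% map$universe))
  if (dropped > 0L) {
    warning(dropped, " query gene(s) outside the universe dropped")
    query <- query[query %in% map$universe]
  }
  n <- length(query)
  K <- vapply(map$terms, length, integer(1))
  k <- vapply(map$terms, function(g) sum(query %in% g), integer(1))
  p <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(map$terms), k = k, K = K, n = n, M = M,
                    p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Read a Ct table from TSV
#'
#' Expects columns `sample`, `group`, `gene`, `ct` with `group` in
#' \{treatment, control\}.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; `ddCt` is the mean
#' treatment dCt minus the mean control dCt, and the relative fold change is
#' `2^-ddCt`. The reference subtraction makes the result invariant to a
#' constant shift of all Ct values within a sample.
#'
#' @param table data frame with columns `sample`, `group` (values
#'   `"treatment"` / `"control"`), `gene`, `ct` (positive).
#' @param reference_gene internal-control gene (e.g. the U6 small nuclear
#'   RNA).
#' @param target_gene gene/miRNA of interest.
#' @return list with `fold_change` (`2^-ddCt`), `ddct`, and `per_sample`
#'   (data frame `sample`, `group`, `dct`).
#' @export
ddct <- function(table, reference_gene, target_gene) {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  if (any(table$ct <= 0)) stop("Ct values must be positive")
  if (!all(table$group %in% c("treatment", "control"))) {
    stop('group must be "treatment" or "control"')
  }
  samples <- unique(table$sample)
  dct <- vapply(samples, function(s) {
    sub <- table[table$sample == s, , drop = FALSE]
    tgt <- sub$ct[sub$gene == target_gene]
    ref <- sub$ct[sub$gene == reference_gene]
    if (length(tgt) == 0L) stop("target gene missing for sample ", s)
    if (length(ref) == 0L) stop("reference gene missing for sample ", s)
    mean(tgt) - mean(ref)
  }, numeric(1))
  grp <- vapply(samples, function(s) {
    table$group[table$sample == s][1L]
  }, character(1))
  if (!any(grp == "treatment") || !any(grp == "control")) {
    stop("both treatment and control samples are required")
  }
  dd <- mean(dct[grp == "treatment"]) - mean(dct[grp == "control"])
  list(
    fold_change = 2^(-dd),
    ddct = dd,
    per_sample = data.frame(sample = samples, group = unname(grp),
                            dct = unname(dct), stringsAsFactors = FALSE,
                            row.names = NULL)
  )
}
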