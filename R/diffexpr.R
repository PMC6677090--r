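# Exact conditional test for one transcript's counts in two pooled
# libraries (Audic-Claverie family), fold change, filtering, BH-FDR and
# differential-expression calls.
#
# The point statistic for counts x (library 1, total N1) and y (library 2,
# total N2) is
#
#   p(x|y) = (N2/N1)^y * (x+y)! / (x! y!) * (1 + N2/N1)^-(x+y+1)
#
# evaluated in log space via log-gamma. As a function of y given x it is a
# proper negative-binomial distribution (sums to 1); summed over x it gives
# N1/N2.

#' Exact conditional point probability for two count libraries
#'
#' Computes `p(x|y) = (N2/N1)^y * (x+y)!/(x! y!) * (1+N2/N1)^-(x+y+1)` in
#' log space via `lgamma`, so it is finite and in (0, 1] for counts up to
#' around 1e7. `x` and `y` are raw read counts (non-negative integers), not
#' normalised expressions: the factorials require integers, and normalisation
#' is a separate reporting step.
#'
#' @param x,y non-negative integer counts in libraries 1 and 2 (vectorised).
#' @param N1,N2 positive total clean-read counts of libraries 1 and 2.
#' @return numeric vector of probabilities.
#' @export
ac_point_prob <- function(x, y, N1, N2) {
  .check_counts(x, y, N1, N2)
  exp(.ac_log_point(x, y, N1, N2))
}

.ac_log_point <- function(x, y, N1, N2) {
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

.check_counts <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    stop("x and y must be non-negative integers (raw counts)")
  }
  if (any(N1 <= 0) || any(N2 <= 0)) stop("N1 and N2 must be positive")
  invisible(TRUE)
}

#' Direct-evaluation oracle for the exact conditional point probability
#'
#' An independent check on [ac_point_prob()]: evaluates the same formula by
#' direct products — `choose(x+y, x) * (N2/N1)^y / (1+N2/N1)^(x+y+1)` — with
#' no log-gamma. `choose()` is exact for binomial coefficients below 2^53,
#' which covers the supported range `x + y <= 200`.
#'
#' @inheritParams ac_point_prob
#' @return numeric vector of probabilities.
#' @export
ac_point_prob_oracle <- function(x, y, N1, N2) {
  .check_counts(x, y, N1, N2)
  if (any(x + y > 200)) stop("oracle supports x + y <= 200 only")
  r <- N2 / N1
  choose(x + y, x) * r^y / (1 + r)^(x + y + 1)
}

#' Exact conditional p-value for two count libraries
#'
#' `mode = "point"` returns the literal point probability [ac_point_prob()].
#' `mode = "two_sided"` (default) returns the doubled smaller tail capped at
#' 1: `min(1, 2 * min(sum_{k <= x} p(k|y), sum_{k >= x} p(k|y)))`. Both
#' tails are cumulative masses of the conditional distribution of the
#' library-1 count given the library-2 count. Since
#' `p(k|y) = (N1/N2) * dnbinom(k, size = y + 1, prob = r/(1+r))` with
#' `r = N2/N1`, the tails are evaluated through the negative-binomial CDF
#' (a regularized incomplete beta), which keeps far tails exact at any
#' count scale — no complement subtraction, hence no catastrophic
#' cancellation for extreme counts. A direct compensated log-space
#' summation of `p(k|y)` verifies this identity in the test suite.
#'
#' @inheritParams ac_point_prob
#' @param mode `"two_sided"` or `"point"`.
#' @return numeric vector of p-values.
#' @export
ac_pvalue <- function(x, y, N1, N2, mode = c("two_sided", "point")) {
  mode <- match.arg(mode)
  .check_counts(x, y, N1, N2)
  if (mode == "point") return(ac_point_prob(x, y, N1, N2))
  r <- N2 / N1
  pr <- r / (1 + r)
  mass <- N1 / N2  # total conditional mass over the library-1 count
  lower <- mass * stats::pnbinom(x, size = y + 1, prob = pr)
  upper <- mass * stats::pnbinom(x - 1, size = y + 1, prob = pr,
                                 lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# sum of exp(log-terms), smallest terms first, with Kahan compensation;
# reference route for the tail masses, quadratic-free but O(x) per call
.sum_exp <- function(lt) {
  m <- max(lt)
  t <- exp(sort(lt - m))
  s <- 0
  c <- 0
  for (v in t) {
    yv <- v - c
    tt <- s + yv
    c <- (tt - s) - yv
    s <- tt
  }
  exp(m) * s
}

# lower/upper conditional tail masses by direct compensated summation
# (test oracle for ac_pvalue's CDF route; feasible for moderate counts)
.ac_tails_sum <- function(x, y, N1, N2, upper_terms = 20000L) {
  lower <- .sum_exp(.ac_log_point(0:x, y, N1, N2))
  upper <- .sum_exp(.ac_log_point(x:(x + upper_terms), y, N1, N2))
  c(lower = lower, upper = upper)
}

#' Log2 fold change between two expression values
#'
#' `log2((tpm2 + pseudocount) / (tpm1 + pseudocount))`. With a zero
#' pseudocount, expression exclusive to one library is flagged by sentinels:
#' `+Inf` (exclusive to library 2), `-Inf` (exclusive to library 1), `NaN`
#' (zero in both; undefined). Vectorised.
#'
#' @param tpm1,tpm2 non-negative expression values (library 1, library 2).
#' @param pseudocount non-negative value added to both sides before the
#'   ratio; 0 preserves the exclusivity sentinels.
#' @return numeric vector; `log2(ratio)` with the sentinel conventions above.
#' @export
log2_fold_change <- function(tpm1, tpm2, pseudocount = 0) {
  if (any(tpm1 < 0) || any(tpm2 < 0)) stop("expression values must be >= 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log2((tpm2 + pseudocount) / (tpm1 + pseudocount))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: `adj_i = min_{j >= i} (p_(j) * m / j)`,
#' restored to input order. Invariant to permutation of the input.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (no NA).
#' @return adjusted p-values in \[0, 1\], same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pair two expression profiles for differential testing
#'
#' @param profile1,profile2 `expression_profile` objects (library 1 and 2)
#'   over the same catalog.
#' @param confidence optional per-miRNA probability in \[0, 1\] that the
#'   entry is a genuine miRNA (e.g. a novel-miRNA prediction score); catalog
#'   miRNAs default to 1 and are never confidence-filtered.
#' @return a `paired_expression` data frame (`mirna`, `count_1`, `count_2`,
#'   `tpm_1`, `tpm_2`, `confidence`) with attributes `N1`, `N2`.
#' @export
paired_expression <- function(profile1, profile2, confidence = NULL) {
  stopifnot(inherits(profile1, "expression_profile"),
            inherits(profile2, "expression_profile"))
  if (!identical(profile1$mirna, profile2$mirna)) {
    stop("profiles must cover the same miRNAs in the same order")
  }
  N1 <- attr(profile1, "library_total")
  N2 <- attr(profile2, "library_total")
  if (any(profile1$count > N1) || any(profile2$count > N2)) {
    stop("counts exceed their library totals; inconsistent N")
  }
  if (is.null(confidence)) confidence <- rep(1, nrow(profile1))
  if (anyNA(confidence) || any(confidence < 0 | confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  out <- data.frame(
    mirna = profile1$mirna,
    count_1 = profile1$count, count_2 = profile2$count,
    tpm_1 = profile1$tpm, tpm_2 = profile2$tpm,
    confidence = confidence, stringsAsFactors = FALSE
  )
  attr(out, "N1") <- N1
  attr(out, "N2") <- N2
  class(out) <- c("paired_expression", "data.frame")
  out
}

#' Call differentially expressed miRNAs between two pooled libraries
#'
#' The calling procedure:
#' 1. floor filter — miRNAs with TPM below `tpm_floor` in *both* libraries
#'    are removed (`filtered_floor`); a miRNA expressed in only one library
#'    survives if that library reaches the floor;
#' 2. confidence filter — entries with confidence below `confidence_floor`
#'    are removed (`filtered_confidence`);
#' 3. log2 fold change on TPM (library 2 over library 1) and the exact
#'    conditional p-value on raw counts for every survivor;
#' 4. BH adjustment over all surviving tests;
#' 5. status `up` when `p_adj < alpha` and `log2fc > fc_threshold`, `down`
#'    symmetric (strict inequalities). miRNAs exclusive to one library carry
#'    the `+-Inf` fold-change sentinel; their significance is decided by
#'    `p_adj` alone with direction from the nonzero side, and the `note`
#'    column records `exclusive_lib1` / `exclusive_lib2`. Non-significant
#'    exclusives keep that label as their status.
#'
#' @param paired a [paired_expression()] table.
#' @param alpha adjusted-p significance threshold.
#' @param fc_threshold absolute log2 fold-change threshold.
#' @param tpm_floor minimum TPM; the removal rule is "below the floor in each
#'   of the two libraries".
#' @param confidence_floor minimum per-miRNA confidence.
#' @param pvalue_mode `"two_sided"` or `"point"`, passed to [ac_pvalue()].
#' @param pseudocount pseudocount for the fold change; 0 keeps exclusivity
#'   sentinels.
#' @return a `dem_table` data frame: `mirna`, `count_1`, `count_2`, `tpm_1`,
#'   `tpm_2`, `log2fc`, `p_raw`, `p_adj`, `status`, `note`. Filtered rows
#'   carry NA p-values.
#' @export
call_dems <- function(paired, alpha = 0.05, fc_threshold = 1,
                      tpm_floor = 1, confidence_floor = 0.95,
                      pvalue_mode = c("two_sided", "point"),
                      pseudocount = 0) {
  stopifnot(inherits(paired, "paired_expression"))
  pvalue_mode <- match.arg(pvalue_mode)
  N1 <- attr(paired, "N1")
  N2 <- attr(paired, "N2")
  n <- nrow(paired)
  status <- rep(NA_character_, n)
  note <- rep(NA_character_, n)
  log2fc <- rep(NA_real_, n)
  p_raw <- rep(NA_real_, n)
  p_adj <- rep(NA_real_, n)

  floored <- paired$tpm_1 < tpm_floor & paired$tpm_2 < tpm_floor
  status[floored] <- "filtered_floor"
  lowconf <- !floored & paired$confidence < confidence_floor
  status[lowconf] <- "filtered_confidence"
  test <- !floored & !lowconf

  if (any(test)) {
    log2fc[test] <- log2_fold_change(paired$tpm_1[test], paired$tpm_2[test],
                                     pseudocount)
    p_raw[test] <- ac_pvalue(paired$count_1[test], paired$count_2[test],
                             N1, N2, mode = pvalue_mode)
    p_adj[test] <- bh_adjust(p_raw[test])

    excl2 <- test & is.infinite(log2fc) & log2fc > 0
    excl1 <- test & is.infinite(log2fc) & log2fc < 0
    note[excl2] <- "exclusive_lib2"
    note[excl1] <- "exclusive_lib1"
    sig <- test & p_adj < alpha
    up <- sig & ((is.finite(log2fc) & log2fc > fc_threshold) | excl2)
    down <- sig & ((is.finite(log2fc) & log2fc < -fc_threshold) | excl1)
    status[up] <- "up"
    status[down] <- "down"
    rest <- test & is.na(status)
    status[rest & excl2] <- "exclusive_lib2"
    status[rest & excl1] <- "exclusive_lib1"
    status[test & is.na(status)] <- "not_significant"
  }

  out <- data.frame(
    mirna = paired$mirna,
    count_1 = paired$count_1, count_2 = paired$count_2,
    tpm_1 = paired$tpm_1, tpm_2 = paired$tpm_2,
    log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
    status = status, note = note, stringsAsFactors = FALSE
  )
  attr(out, "N1") <- N1
  attr(out, "N2") <- N2
  attr(out, "parameters") <- list(
    alpha = alpha, fc_threshold = fc_threshold, tpm_floor = tpm_floor,
    confidence_floor = confidence_floor, pvalue_mode = pvalue_mode,
    pseudocount = pseudocount
  )
  class(out) <- c("dem_table", "data.frame")
  out
}
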