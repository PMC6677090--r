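---
title: "Methods: exact differential expression and variant profiling for two pooled small-RNA libraries"
author: "srnapool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact differential expression and variant profiling for two pooled small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapool)
```

## The experimental design this package targets

Many small-RNA sequencing studies — particularly older breed- or
tissue-comparison designs — sequence **one pooled library per condition**:
equal RNA amounts from several animals are pooled, size-selected to the
18–30 nt small-RNA window, and sequenced once. With no biological
replicates, dispersion-based tools (negative-binomial GLMs such as DESeq2 or
edgeR) are not applicable; what *is* well defined is the comparison of a
single transcript's counts between two libraries of known sequencing depth.
`srnapool` implements that complete workflow: read cleaning, tag
collapsing, exact-match miRNA quantification, the exact conditional count
test with FDR control, isomiR and seed-edit profiling, and the downstream
enrichment and qPCR-validation arithmetic.

Throughout, "library 1" and "library 2" are the two conditions (e.g. two pig
breeds), with total clean-read counts $N_1$ and $N_2$.

## Sequence conventions

All sequences are held in the DNA alphabet; catalogs distributed in RNA
alphabet (miRBase dialect) are converted U→T on load, because sequenced
reads are cDNA. User-facing coordinates are 1-based inclusive; the **seed**
of a mature miRNA is the 7-mer at positions 2–8. Catalog entries with
identical sequences under different names (families such as let-7) are both
kept and flagged; a tag matching such a sequence counts fully toward every
member, since any fractional split would be arbitrary under exact matching.
Records containing N are rejected at load.

## Cleaning and tag collapsing

Raw reads pass through six filters in a **fixed precedence order**, so each
read is claimed by exactly one category and the cleaning report partitions
the input — a conservation property tested on randomized fixtures:

1. low quality (mean Phred < 20);
2. poly-N (any N);
3. 5′-adapter contamination (read begins with the 5′ adapter);
4. missing 3′ adapter (the adapter's first 8 nt, exact match; when found,
   the adapter and everything after it is trimmed);
5. homopolymer insert (any single base ≥ 80% of the trimmed insert);
6. insert length outside 18–30 nt (the gel-excision window of standard
   small-RNA preps).

Adapter matching is deliberately exact rather than mismatch-tolerant:
vendor cleaning pipelines vary and are rarely specified, and exact matching
keeps the behaviour auditable. All thresholds are configuration, not
constants. Surviving inserts are collapsed into unique **sRNA tags** with
read counts; collapsing preserves the total read count exactly.

## Quantification and TPM

A tag is assigned to a mature miRNA only by **exact full-sequence
identity** (same length, zero mismatches) — the hash-lookup equivalent of
zero-mismatch alignment, which makes an aligner unnecessary at catalog
scale. Unmatched tags form the *unannotated pool* consumed by the variant
analysis. Expression is normalised as tags per million:

$$\mathrm{TPM} = \frac{\text{miRNA count}}{\text{total clean reads}} \times 10^6,$$

where the denominator is the library's total clean reads, not the annotated
subtotal. Canonical counts are exact-match only; isomiR reads are profiled
separately and never added into mature counts.

## The exact conditional test

For a miRNA with raw counts $x$ (library 1) and $y$ (library 2), the point
statistic is

$$p(x \mid y) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!}
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

the Audic–Claverie-type posterior probability of observing $x$ given $y$
under equal underlying abundance. Two implementation points matter:

* **$x$ and $y$ are raw counts, not normalised expressions.** The
  factorials require non-negative integers; the TPM normalisation is a
  separate reporting step. (Descriptions of this statistic sometimes phrase
  it in terms of "normalised expression"; taken literally that would be
  circular.)
* **Evaluation is in log space** via `lgamma`, so the statistic is finite
  and in $(0,1]$ for counts up to ~$10^7$.

A point mass is not a p-value, so the default test is the conventional
doubled-tail construction: with the cumulative conditional masses
$L = \sum_{k \le x} p(k\mid y)$ and $U = \sum_{k \ge x} p(k\mid y)$, the
two-sided p-value is $\min(1,\, 2\min(L, U))$. `mode = "point"` reproduces
the literal point formula for users who want it.

How the tails are evaluated is a deliberate design choice. As a function
of $y$ given $x$ the statistic is exactly a negative-binomial density
(mass 1), while summed over $x$ it gives $N_1/N_2$; equivalently
$p(k \mid y) = (N_1/N_2)\,\mathrm{dnbinom}(k;\, y+1,\, r/(1+r))$ with
$r = N_2/N_1$. Computing $U$ as the complement $1 - \sum_{k<x}$ would be
wrong twice over: it assumes unit mass (flooring every p-value at
$2\,|1-N_1/N_2|$, which at realistic depths buries even astronomically
significant miRNAs), and it cancels catastrophically when the complement
is tiny. Both tails are therefore evaluated through the negative-binomial
CDF (a regularized incomplete beta), exact at any count scale; an
independent compensated log-space summation of $p(k\mid y)$, and the mass
identities above, are asserted in the test suite. The oracle for the point
formula is a separate direct-product evaluation using exact binomial
coefficients. At $N_1 = N_2$ the CDF route and the complement form
coincide.

At equal depths the statistic reduces to the closed form
$p(x\mid y) = \binom{x+y}{x}/2^{x+y+1}$, a further test anchor. On
simulated null counts (expected count 100 per library, $N_1=N_2=10^6$) the
two-sided rejection fraction at $\alpha = 0.05$ sits near 0.046 — slightly
conservative, as expected of exact tests on discrete counts.

## DEM calling

The calling procedure, with every threshold configurable:

1. **Floor filter**: remove miRNAs with TPM < 1 in *each of the two*
   libraries. The "both" reading matters: filtering on "either" would
   discard miRNAs genuinely exclusive to one condition, which are among the
   most interesting calls.
2. **Confidence filter**: remove entries whose confidence (e.g. a
   novel-miRNA prediction score supplied as an input column) is below 0.95.
   Catalog miRNAs default to confidence 1 and are never removed here.
3. Fold change $\log_2(\mathrm{TPM}_2/\mathrm{TPM}_1)$ and the two-sided
   exact p-value on raw counts.
4. Benjamini–Hochberg step-up adjustment over all surviving tests
   ($m$ = number of tested miRNAs; the filters are independent of the test
   statistic).
5. Calls: `up` when $p_{adj} < 0.05$ and $\log_2\mathrm{FC} > 1$; `down`
   symmetric. Inequalities are strict.

MiRNAs expressed in only one library have no finite fold change; they carry
a $\pm\infty$ sentinel, are tested like any other row, and are called by
$p_{adj}$ alone with direction from the nonzero side (the `note` column
records the exclusivity). With a nonzero `pseudocount` the sentinel
disappears and the fold change becomes finite, which is the transform
commonly used for plotting.

## isomiR classes and seed editing

End-variant classes among unannotated tags, with precedence
trim3 > add3 > shift5 when several fit:

* `trim3` — mature with 1–2 terminal 3′ bases removed;
* `add3` — mature plus 1–2 non-templated 3′ bases;
* `shift5` — first base removed or one base prepended, 3′ end within ±2 nt.

A **seed edit** is a tag of the *same length* as a mature sequence
differing at exactly one position within 2–8. Length variation combined
with an internal substitution is deliberately out of scope of detection:
without a combined model the event definition would be ambiguous.
Substitutions at position 1 are a documented ambiguity of "5′-end variant"
phrasing — they are reported as `nonseed_sub`, never as seed edits, and are
excluded from the spectrum. A support floor (`min_count`, default 5 reads)
suppresses sequencing-error artifacts; it is applied uniformly to both
substitution classes.

Candidates are found with a one-substitution neighbourhood index (3L
variants per mature sequence of length L) rather than all-pairs scanning;
the tests assert exact agreement with a brute-force scan. The substitution
spectrum counts distinct (miRNA, position, from, to) **events, not reads**,
over the 12 possible substitutions, so one abundant edit cannot dominate
the percentages.

## Enrichment and qPCR validation

Term enrichment is a hypergeometric upper tail
$P = \sum_{i \ge k} \binom{K}{i}\binom{M-K}{n-i}/\binom{M}{n}$
(over-representation only) with BH-adjusted Q-values, over a user-supplied
term→gene map. No ontology files or DAG propagation: published term
statistics are database-version-bound, so the universe is an explicit,
required input. qPCR validation uses the $2^{-\Delta\Delta Ct}$ method with
group-mean $\Delta Ct$ (reference gene per sample, e.g. U6 snRNA); the
reference subtraction makes the result invariant to per-sample Ct shifts,
which is tested.

## The synthetic-data generator

The generator emits exactly two libraries — the pooled design the test is
defined for — with complete ground truth: per-miRNA true TPM in each
condition, DE labels and signs, planted seed-edit templates with realized
read counts, and per-type contaminant counts.

* **Abundance**: log-normal baseline (default $\sigma = 1$), renormalised
  to $10^6$ TPM over catalog-derived mass. Real miRNA abundance spans
  orders of magnitude with a few dominant species; the log-normal
  reproduces that long tail. An optional `min_tpm` floor
  (truncation-with-renormalisation) supports scenarios that require every
  miRNA to be comfortably detectable.
* **Effects**: `round(de_fraction * n)` miRNAs get $\pm$`effect_log2fc`
  applied to condition B with random sign, then both conditions are
  renormalised. Renormalisation shifts every realized log2FC by a common
  constant (compositional closure) — ground-truth labels, not realized fold
  changes, define the DE set.
* **isomiRs**: per-read probabilities of 3′ trim (default 0.15), 3′
  addition (0.05), 5′ shift (0.02) and seed edit (0.002). 3′ variation
  dominates by construction, as it does in real data; trim/addition lengths
  are geometric(0.5) truncated at 2 nt, keeping tags inside the 18–30 nt
  window. These rates are plausible orders of magnitude chosen for test
  power, not biological estimates. Each miRNA has **one** planted seed-edit
  template (random position 2–8, random substitution), so the manifest is
  an exact, countable target for the detector.
* **Contaminants** (default 5%): poly-A runs, sub-18 nt fragments, and
  random in-window sequence — exercising the homopolymer, length, and
  unannotated paths respectively. **Sequencing error** is a per-base
  substitution (default 0.001) applied last. Simulated FASTQ carries
  constant quality "I" (Phred 40); the quality filter is exercised by
  crafted fixtures instead, keeping concerns separate.

What the generator does **not** emulate: adapter sequence at the nucleotide
level (cleaning is tested on crafted adapter-bearing fixtures), indels,
position-dependent error profiles, replicate structure, or genomic context
for novel-miRNA discovery. Passing tests on simulated data therefore
validate the *computational* contracts — count recovery, calibration,
variant recovery, determinism — not the biological realism of any
particular rate.

## Numerical and design choices

* Tail masses: negative-binomial CDF in the implementation; the reference
  log-sum-exp route (ascending, Kahan-compensated) truncates only where
  the remaining mass is < 1e-12.
* The direct-evaluation oracle is restricted to $x+y \le 200$, where
  `choose()` is exact or correctly rounded.
* BH is `stats::p.adjust(method = "BH")` behind a validating wrapper;
  hand-computed step-up values are asserted in tests.
* Ties and ordering: collapsed tags sort by decreasing count then sequence;
  variant events by (miRNA, position, substitution) — all outputs are
  byte-deterministic under a fixed seed. One global seed governs every
  stochastic stage; stages derive sub-seeds from their names, so stages are
  independently reproducible.
* Degenerate inputs are defined, not accidental: empty FASTQ gives an
  all-zero report; an empty unannotated pool gives zero events; an empty
  seed-edit set gives an all-zero spectrum with an `empty` flag; both-zero
  fold change with zero pseudocount is NaN.

## Problem sizes used in validation

The shipped validation suite runs, per execution: the oracle grid
($31 \times 31 \times 4$ ratios), null calibration on 10,000 simulated null
miRNAs at depth $10^6$, effect recovery on 300 miRNAs (30 DE at
$|\log_2\mathrm{FC}| = 2$, $10^6$ reads per library), variant recovery on
an 80-miRNA catalog at $1.5\times10^5$ reads, 200–1,000 randomized cleaning
fixtures, and two full pipeline runs at $2\times10^5$ reads per library for
the determinism check. These sizes give stable statistics (binomial SE of
the null rejection rate ≈ 0.002) while keeping a full validation run in
well under a minute of compute per component.

## Known limitations

* No replicate-aware inference: with $n = 1$ library per condition the
  test treats sequencing depth as the only noise source; biological
  variability between pools is invisible and p-values are accordingly
  optimistic for generalisation beyond the sequenced pools.
* Exact matching cannot assign reads from miRNAs absent from the catalog,
  and isomiR reads are not added to mature counts (a documented divergence
  from pipelines that count them in).
* Seed-edit detection is blind to edits co-occurring with length variation
  and to position-1 substitutions (reported separately).
* The enrichment module tests over-representation only and performs no
  ontology-aware propagation.
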