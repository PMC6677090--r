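#' Simulation configuration for two pooled small-RNA libraries
#'
#' Bundles and validates every parameter of the synthetic-data generator. The
#' generator emulates the statistical structure the downstream analysis
#' assumes: two pooled libraries (one per condition, no replicates) of
#' 18-30 nt tags drawn from a mature-miRNA catalog with a long-tailed
#' (log-normal) abundance distribution, condition-specific fold changes on a
#' subset of miRNAs, 3'-dominant isomiR variation, rare single-substitution
#' seed edits, contaminant reads, and per-base sequencing error.
#'
#' @param n_mirnas number of catalog miRNAs.
#' @param depth_a,depth_b total reads per library.
#' @param de_fraction proportion in \[0,1) of miRNAs given a true effect.
#' @param effect_log2fc magnitude of the true log2 fold change, applied to
#'   condition B with random sign per affected miRNA.
#' @param abundance_sigma log-normal sigma of the baseline abundance.
#' @param min_tpm floor (in TPM units) applied to baseline abundances by
#'   truncation-with-renormalisation; 0 disables it.
#' @param trim3_prob,add3_prob,shift5_prob per-read probabilities of 3'
#'   trimming (1-2 nt, truncated geometric), 3' non-templated addition
#'   (1-2 random nt) and 5' shift (+-1 nt).
#' @param seed_edit_rate per-read probability of carrying the miRNA's planted
#'   single-substitution seed edit.
#' @param contaminant_fraction proportion of reads not derived from the
#'   catalog (poly-A runs, short fragments, random sequence).
#' @param error_rate per-base substitution sequencing error.
#' @param seed RNG seed governing all stochastic stages.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_mirnas = 300L,
                              depth_a = 1e6, depth_b = 1e6,
                              de_fraction = 0.1,
                              effect_log2fc = 2,
                              abundance_sigma = 1,
                              min_tpm = 0,
                              trim3_prob = 0.15,
                              add3_prob = 0.05,
                              shift5_prob = 0.02,
                              seed_edit_rate = 0.002,
                              contaminant_fraction = 0.05,
                              error_rate = 0.001,
                              seed = 1L) {
  cfg <- list(
    n_mirnas = as.integer(n_mirnas),
    depth_a = as.integer(depth_a), depth_b = as.integer(depth_b),
    de_fraction = de_fraction, effect_log2fc = effect_log2fc,
    abundance_sigma = abundance_sigma, min_tpm = min_tpm,
    trim3_prob = trim3_prob, add3_prob = add3_prob,
    shift5_prob = shift5_prob, seed_edit_rate = seed_edit_rate,
    contaminant_fraction = contaminant_fraction,
    error_rate = error_rate, seed = as.integer(seed)
  )
  probs <- c(cfg$trim3_prob, cfg$add3_prob, cfg$shift5_prob,
             cfg$seed_edit_rate, cfg$contaminant_fraction, cfg$error_rate,
             cfg$de_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cfg$de_fraction >= 1) stop("de_fraction must be < 1")
  if (cfg$trim3_prob + cfg$add3_prob + cfg$shift5_prob + cfg$seed_edit_rate > 1) {
    stop("trim3_prob + add3_prob + shift5_prob + seed_edit_rate must be <= 1")
  }
  if (cfg$depth_a < 1L || cfg$depth_b < 1L) stop("library depths must be >= 1")
  if (cfg$n_mirnas < 1L) stop("n_mirnas must be >= 1")
  if (cfg$abundance_sigma < 0) stop("abundance_sigma must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")

#' Simulate a random mature-miRNA catalog
#'
#' Generates `n` unique random sequences with uniform base composition and
#' lengths drawn uniformly from `length_range`, named "sim-mir-001" onward.
#' Deterministic under a fixed seed.
#'
#' @param n number of miRNAs (>= 1).
#' @param length_range integer vector `c(min, max)` of mature lengths.
#' @param seed optional RNG seed; when `NULL` the current RNG state is used.
#' @return A [mir_catalog()].
#' @export
simulate_catalog <- function(n, length_range = c(18L, 25L), seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(seq.int(length_range[1L], length_range[2L]), n, replace = TRUE)
  seqs <- character(0)
  for (attempt in seq_len(100L)) {
    need <- n - length(seqs)
    if (need == 0L) break
    fresh <- vapply(lens[seq_len(need)], function(L) {
      paste(sample(.BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, fresh))
    lens <- sample(seq.int(length_range[1L], length_range[2L]), n, replace = TRUE)
  }
  if (length(seqs) < n) stop("could not generate ", n, " unique sequences")
  seqs <- seqs[seq_len(n)]
  width <- max(3L, nchar(as.character(n)))
  nm <- sprintf(paste0("sim-mir-%0", width, "d"), seq_len(n))
  mir_catalog(nm, seqs, source = "simulated")
}

#' Simulate ground-truth abundances and effects
#'
#' Draws a log-normal baseline abundance per miRNA, renormalises to TPM
#' (summing to 1e6 over catalog-derived mass), optionally floors baselines at
#' `min_tpm`, applies +-`effect_log2fc` to `round(de_fraction * n)` randomly
#' chosen miRNAs in condition B, renormalises both conditions, and plants one
#' seed-edit template (random position 2-8, random substitution) per miRNA.
#'
#' @param catalog a [mir_catalog()].
#' @param config a [simulation_config()].
#' @param seed optional RNG seed; when `NULL` the current RNG state is used.
#' @return A `sim_truth` list with elements `profile` (data frame: `name`,
#'   `tpm_a`, `tpm_b`, `log2fc_true`, `is_de`), `templates` (data frame:
#'   `mirna`, `position`, `from`, `to`) and `config`.
#' @export
simulate_abundances <- function(catalog, config, seed = NULL) {
  stopifnot(inherits(catalog, "mir_catalog"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(catalog)
  base <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sigma)
  tpm_a <- .renorm_floor(base, config$min_tpm)

  n_de <- round(config$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0L) is_de[sample.int(n, n_de)] <- TRUE
  sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  w_b <- tpm_a
  w_b[is_de] <- w_b[is_de] * 2^(sgn[is_de] * config$effect_log2fc)
  tpm_b <- w_b / sum(w_b) * 1e6

  templates <- data.frame(
    mirna = catalog$name,
    position = sample(2:8, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  templates$from <- substr(catalog$sequence, templates$position, templates$position)
  templates$to <- vapply(templates$from, function(b) {
    sample(setdiff(.BASES, b), 1L)
  }, character(1), USE.NAMES = FALSE)

  truth <- list(
    profile = data.frame(
      name = catalog$name, tpm_a = tpm_a, tpm_b = tpm_b,
      log2fc_true = log2(tpm_b / tpm_a), is_de = is_de,
      stringsAsFactors = FALSE
    ),
    templates = templates,
    config = config
  )
  class(truth) <- "sim_truth"
  truth
}

# floor baseline TPMs by clamping and renormalising until stable
.renorm_floor <- function(w, min_tpm) {
  tpm <- w / sum(w) * 1e6
  if (min_tpm <= 0) return(tpm)
  for (i in seq_len(100L)) {
    if (all(tpm >= min_tpm - 1e-9)) break
    tpm <- pmax(tpm, min_tpm)
    tpm <- tpm / sum(tpm) * 1e6
  }
  pmax(tpm, min_tpm)
}

#' Simulate two read libraries with known provenance
#'
#' Draws catalog-derived reads multinomially from the true TPMs of each
#' condition; each read is independently emitted as canonical, 3'-trimmed
#' (1-2 nt, truncated geometric), 3'-extended (1-2 random nt), 5'-shifted
#' (+-1 nt) or seed-edited (the miRNA's planted template), per the config
#' probabilities. Contaminants (poly-A runs, short fragments, random
#' sequence) are appended per `contaminant_fraction`, per-base substitution
#' errors applied last, and read order shuffled. The manifest records each
#' realized seed-edit template with its supporting read count (before
#' sequencing error) and per-type contaminant counts.
#'
#' @param catalog a [mir_catalog()].
#' @param truth a `sim_truth` from [simulate_abundances()].
#' @param config a [simulation_config()].
#' @param seed optional RNG seed; when `NULL` the current RNG state is used.
#' @return A `sim_reads` list: `reads_a`, `reads_b` (character vectors),
#'   `manifest` (list with `seed_edits` and `contaminants` data frames, both
#'   carrying a `library` column), `truth`, `config`.
#' @export
simulate_reads <- function(catalog, truth, config, seed = NULL) {
  stopifnot(inherits(catalog, "mir_catalog"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  lib_a <- .simulate_library(catalog, truth$profile$tpm_a, truth$templates,
                             config, config$depth_a, "A")
  lib_b <- .simulate_library(catalog, truth$profile$tpm_b, truth$templates,
                             config, config$depth_b, "B")
  out <- list(
    reads_a = lib_a$reads, reads_b = lib_b$reads,
    manifest = list(
      seed_edits = rbind(lib_a$seed_edits, lib_b$seed_edits),
      contaminants = rbind(lib_a$contaminants, lib_b$contaminants)
    ),
    truth = truth, config = config
  )
  class(out) <- "sim_reads"
  out
}

.simulate_library <- function(catalog, tpm, templates, config, depth, label) {
  n_cont <- round(depth * config$contaminant_fraction)
  n_cat <- depth - n_cont
  counts <- as.vector(stats::rmultinom(1L, n_cat, prob = tpm / sum(tpm)))
  mir_idx <- rep.int(seq_len(nrow(catalog)), counts)
  reads <- rep.int(catalog$sequence, counts)

  p <- c(config$trim3_prob, config$add3_prob, config$shift5_prob,
         config$seed_edit_rate)
  cls <- sample.int(5L, n_cat, replace = TRUE, prob = c(p, 1 - sum(p)))

  i <- which(cls == 1L) # trim3: remove 1-2 terminal 3' bases
  if (length(i)) {
    k <- sample(1:2, length(i), replace = TRUE, prob = c(2 / 3, 1 / 3))
    reads[i] <- substr(reads[i], 1L, nchar(reads[i]) - k)
  }
  i <- which(cls == 2L) # add3: 1-2 random non-templated 3' bases
  if (length(i)) {
    k <- sample(1:2, length(i), replace = TRUE, prob = c(2 / 3, 1 / 3))
    ext <- vapply(k, function(m) paste(sample(.BASES, m, replace = TRUE),
                                       collapse = ""), character(1))
    reads[i] <- paste0(reads[i], ext)
  }
  i <- which(cls == 3L) # shift5: drop first base or prepend a random base
  if (length(i)) {
    drop <- stats::runif(length(i)) < 0.5
    reads[i[drop]] <- substr(reads[i[drop]], 2L, nchar(reads[i[drop]]))
    add <- i[!drop]
    if (length(add)) {
      reads[add] <- paste0(sample(.BASES, length(add), replace = TRUE),
                           reads[add])
    }
  }
  i <- which(cls == 4L) # seed edit: apply this miRNA's planted template
  if (length(i)) {
    pos <- templates$position[mir_idx[i]]
    substr(reads[i], pos, pos) <- templates$to[mir_idx[i]]
  }
  se_counts <- table(mir_idx[cls == 4L])
  se_idx <- as.integer(names(se_counts))
  seed_edits <- data.frame(
    library = rep(label, length(se_idx)),
    mirna = templates$mirna[se_idx],
    position = templates$position[se_idx],
    from = templates$from[se_idx],
    to = templates$to[se_idx],
    reads = as.integer(se_counts),
    stringsAsFactors = FALSE
  )

  cont <- character(0)
  cont_tab <- data.frame(library = character(0), type = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  if (n_cont > 0L) {
    type <- sample(c("polyA", "short_fragment", "random"), n_cont,
                   replace = TRUE)
    cont <- character(n_cont)
    j <- type == "polyA"
    if (any(j)) cont[j] <- strrep("A", sample(20:24, sum(j), replace = TRUE))
    j <- type == "short_fragment"
    if (any(j)) {
      cont[j] <- vapply(sample(10:17, sum(j), replace = TRUE), function(L) {
        paste(sample(.BASES, L, replace = TRUE), collapse = "")
      }, character(1))
    }
    j <- type == "random"
    if (any(j)) {
      cont[j] <- vapply(sample(18:30, sum(j), replace = TRUE), function(L) {
        paste(sample(.BASES, L, replace = TRUE), collapse = "")
      }, character(1))
    }
    tb <- table(type)
    cont_tab <- data.frame(library = rep(label, length(tb)),
                           type = names(tb), count = as.integer(tb),
                           stringsAsFactors = FALSE)
  }

  reads <- c(reads, cont)
  if (config$error_rate > 0) reads <- .apply_base_errors(reads, config$error_rate)
  reads <- reads[sample.int(length(reads))]
  list(reads = reads, seed_edits = seed_edits, contaminants = cont_tab)
}

# independent per-base substitution errors; only affected reads are touched
.apply_base_errors <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(.BASES, old), 1L)
    }
  }
  reads
}

#' Write a simulated library to FASTQ
#'
#' Emits Phred+33 FASTQ with constant quality "I" (Phred 40) and serial read
#' identifiers.
#'
#' @param reads character vector of read sequences.
#' @param path output FASTQ path.
#' @param id_prefix prefix for read identifiers.
#' @return `path`, invisibly.
#' @export
write_library_fastq <- function(reads, path, id_prefix = "read") {
  ids <- paste0(id_prefix, seq_along(reads))
  qual <- strrep("I", nchar(reads))
  rec <- paste0("@", ids, "\n", reads, "\n+\n", qual)
  writeLines(rec, path)
  invisible(path)
}

#' Write a ground-truth manifest to TSV files
#'
#' @param truth a `sim_truth`.
#' @param sim a `sim_reads` (for realized seed-edit counts and contaminants),
#'   or `NULL` to write the truth profile only.
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_truth_tsv <- function(truth, sim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profile = file.path(dir, "truth_profile.tsv"))
  write_tsv(truth$profile, paths[["profile"]])
  if (!is.null(sim)) {
    paths[["seed_edits"]] <- file.path(dir, "truth_seed_edits.tsv")
    paths[["contaminants"]] <- file.path(dir, "truth_contaminants.tsv")
    write_tsv(sim$manifest$seed_edits, paths[["seed_edits"]])
    write_tsv(sim$manifest$contaminants, paths[["contaminants"]])
  }
  invisible(paths)
}
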