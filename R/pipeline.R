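# Stage orchestration: chains simulate -> clean -> quantify -> variants -> de
# over on-disk TSV/FASTA/FASTQ artifacts, with flat key=value configuration,
# per-stage derived RNG seeds and JSON run metadata. All interchange between
# stages is diffable text.

#' Default pipeline configuration
#'
#' Returns the flat key-value configuration with every stage parameter at its
#' default: the 18-30 nt length window, TPM floor 1 (removal only when below
#' the floor in each library), confidence floor 0.95, alpha 0.05 and
#' |log2FC| > 1 for DEM calling, seed-edit support floor 5, and the
#' synthetic-data defaults of [simulation_config()]. Any entry can be
#' overridden via `...` or a config file.
#'
#' @param ... named overrides of individual keys.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  sim <- simulation_config()
  cfg <- list(
    # paths (filled per run; NULL means "use the pipeline output directory")
    catalog = NULL, fastq_a = NULL, fastq_b = NULL,
    label_a = "A", label_b = "B",
    # cleaning
    adapter3 = NULL, adapter5 = NULL,
    min_len = 18L, max_len = 30L, homopolymer_frac = 0.8, min_mean_q = 20,
    # variants
    min_count = 5L,
    # differential expression
    alpha = 0.05, fc_threshold = 1, tpm_floor = 1, confidence_floor = 0.95,
    pvalue_mode = "two_sided", pseudocount = 0,
    # downstream inputs (optional)
    enrich_query = NULL, enrich_map = NULL,
    ddct_table = NULL, ddct_reference_gene = NULL, ddct_target_gene = NULL,
    # global seed; stages derive sub-seeds by name
    seed = 1L
  )
  cfg <- c(cfg, unclass(sim)[setdiff(names(unclass(sim)), "seed")])
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; numeric-looking
#' values are coerced, `true`/`false` become logicals, `NULL` stays unset.
#'
#' @param path config file path.
#' @return named list suitable for `do.call(pipeline_config, ...)`.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  vals <- lapply(kv, function(x) {
    v <- x[[2L]]
    if (v %in% c("NULL", "null")) return(NULL)
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

.require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing input for stage: ", what, " (",
         if (is.null(path)) "not configured" else path, ")")
  }
  path
}

.write_metadata <- function(stage, config, inputs, outputs, out_dir) {
  existing <- inputs[file.exists(inputs)]
  checksums <- tools::md5sum(existing)
  names(checksums) <- basename(names(checksums))
  # paths recorded relative to the run directory so reruns compare equal
  meta <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("srnapool")),
    parameters = config[!vapply(config, is.null, logical(1))],
    input_checksums = as.list(checksums),
    outputs = unname(basename(outputs))
  )
  path <- file.path(out_dir, paste0("run_metadata_", stage, ".json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (two FASTQ libraries + ground truth), `clean`
#' (cleaning reports, length distributions, collapsed tags), `quantify`
#' (per-library and combined expression tables, unannotated pools),
#' `variants` (isomiR/seed-edit events and substitution spectra), `de` (DEM
#' table), `enrich`, `ddct`, or `all` (simulate through de plus a summary).
#' Each stage writes its artifacts plus a JSON run-metadata file into
#' `out_dir` and logs a stage-tagged line to stderr.
#'
#' @param name stage name.
#' @param config configuration from [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of artifact paths, invisibly.
#' @export
run_stage <- function(name, config = pipeline_config(), out_dir) {
  stages <- c("simulate", "clean", "quantify", "variants", "de",
              "enrich", "ddct", "all")
  if (!name %in% stages) {
    stop("unknown subcommand: ", name, " (expected one of ",
         paste(stages, collapse = ", "), ")")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("[", name, "] running in ", out_dir)
  out <- switch(name,
    simulate = .stage_simulate(config, out_dir),
    clean = .stage_clean(config, out_dir),
    quantify = .stage_quantify(config, out_dir),
    variants = .stage_variants(config, out_dir),
    de = .stage_de(config, out_dir),
    enrich = .stage_enrich(config, out_dir),
    ddct = .stage_ddct(config, out_dir),
    all = run_pipeline(config, out_dir)
  )
  invisible(out)
}

#' Run the full pipeline on simulated data
#'
#' Chains simulate, clean, quantify, variants and de, then writes
#' `summary.json` with headline numbers (library sizes, tag counts, DEM
#' calls, seed-edit counts). Deterministic under a fixed `config$seed`:
#' reruns produce byte-identical artifacts.
#'
#' @param config configuration from [pipeline_config()].
#' @param out_dir output directory.
#' @return named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    .stage_simulate(config, out_dir),
    .stage_clean(config, out_dir),
    .stage_quantify(config, out_dir),
    .stage_variants(config, out_dir),
    .stage_de(config, out_dir)
  )
  dem <- read_tsv(paths[["dem"]])
  events_a <- read_tsv(paths[["variants_a"]])
  summary <- list(
    n_mirnas = nrow(dem),
    dem_up = sum(dem$status == "up"),
    dem_down = sum(dem$status == "down"),
    filtered_floor = sum(dem$status == "filtered_floor"),
    seed_edited_mirnas_a = edited_mirna_count(events_a),
    seed_edited_mirnas_b = edited_mirna_count(read_tsv(paths[["variants_b"]]))
  )
  spath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["summary"]] <- spath
  message("[all] done: ", summary$dem_up, " up, ", summary$dem_down,
          " down of ", summary$n_mirnas, " miRNAs")
  invisible(paths)
}

.sim_config_from <- function(config) {
  simulation_config(
    n_mirnas = config$n_mirnas, depth_a = config$depth_a,
    depth_b = config$depth_b, de_fraction = config$de_fraction,
    effect_log2fc = config$effect_log2fc,
    abundance_sigma = config$abundance_sigma, min_tpm = config$min_tpm,
    trim3_prob = config$trim3_prob, add3_prob = config$add3_prob,
    shift5_prob = config$shift5_prob, seed_edit_rate = config$seed_edit_rate,
    contaminant_fraction = config$contaminant_fraction,
    error_rate = config$error_rate, seed = config$seed
  )
}

.stage_simulate <- function(config, out_dir) {
  sim_cfg <- .sim_config_from(config)
  catalog <- simulate_catalog(sim_cfg$n_mirnas,
                              seed = stage_seed(config$seed, "catalog"))
  truth <- simulate_abundances(catalog, sim_cfg,
                               seed = stage_seed(config$seed, "abundances"))
  sim <- simulate_reads(catalog, truth, sim_cfg,
                        seed = stage_seed(config$seed, "reads"))
  paths <- c(
    catalog = file.path(out_dir, "catalog.fasta"),
    fastq_a = file.path(out_dir, "library_a.fastq"),
    fastq_b = file.path(out_dir, "library_b.fastq")
  )
  write_mature_fasta(catalog, paths[["catalog"]])
  write_library_fastq(sim$reads_a, paths[["fastq_a"]], "simA_")
  write_library_fastq(sim$reads_b, paths[["fastq_b"]], "simB_")
  paths <- c(paths, write_truth_tsv(truth, sim, out_dir))
  paths[["metadata"]] <- .write_metadata("simulate", config, character(0),
                                         paths, out_dir)
  message("[simulate] ", length(sim$reads_a), " + ", length(sim$reads_b),
          " reads over ", nrow(catalog), " miRNAs")
  paths
}

.stage_clean <- function(config, out_dir) {
  paths <- character(0)
  totals <- data.frame(library = character(0), label = character(0),
                       total_clean_reads = integer(0),
                       stringsAsFactors = FALSE)
  for (lib in c("a", "b")) {
    fq <- config[[paste0("fastq_", lib)]]
    if (is.null(fq)) fq <- file.path(out_dir, paste0("library_", lib, ".fastq"))
    .require_input(fq, paste0("fastq_", lib))
    res <- clean_reads(fq, adapter3 = config$adapter3,
                       adapter5 = config$adapter5,
                       min_len = config$min_len, max_len = config$max_len,
                       homopolymer_frac = config$homopolymer_frac,
                       min_mean_q = config$min_mean_q)
    label <- config[[paste0("label_", lib)]]
    tags <- collapse_tags(res$reads, label)
    p <- c(
      stats::setNames(file.path(out_dir, paste0(
        c("cleaning_report_", "tags_", "collapsed_", "length_dist_"),
        lib, c(".tsv", ".tsv", ".fasta", ".tsv"))),
        paste0(c("report_", "tags_", "collapsed_", "lengths_"), lib))
    )
    write_tsv(as.data.frame(unclass(res$report)), p[[paste0("report_", lib)]])
    write_tsv(as.data.frame(tags), p[[paste0("tags_", lib)]])
    write_collapsed_fasta(tags, p[[paste0("collapsed_", lib)]])
    if (nrow(tags)) {
      write_tsv(length_distribution(tags), p[[paste0("lengths_", lib)]])
    }
    totals <- rbind(totals, data.frame(
      library = lib, label = label,
      total_clean_reads = total_reads(tags), stringsAsFactors = FALSE))
    paths <- c(paths, p)
    message("[clean] library ", lib, ": ", res$report$raw_reads, " raw -> ",
            res$report$clean_reads, " clean")
  }
  paths[["library_totals"]] <- file.path(out_dir, "library_totals.tsv")
  write_tsv(totals, paths[["library_totals"]])
  paths[["metadata"]] <- .write_metadata("clean", config, character(0),
                                         paths, out_dir)
  paths
}

.load_tags <- function(out_dir, lib, totals) {
  path <- file.path(out_dir, paste0("tags_", lib, ".tsv"))
  .require_input(path, paste0("collapsed tags (tags_", lib, ".tsv)"))
  df <- read_tsv(path)
  tag_set(df, totals$label[totals$library == lib])
}

.stage_quantify <- function(config, out_dir) {
  cat_path <- config$catalog
  if (is.null(cat_path)) cat_path <- file.path(out_dir, "catalog.fasta")
  .require_input(cat_path, "catalog FASTA")
  totals_path <- .require_input(file.path(out_dir, "library_totals.tsv"),
                                "library totals (run clean first)")
  totals <- read_tsv(totals_path)
  catalog <- load_mature_fasta(cat_path)
  paths <- character(0)
  quants <- list()
  for (lib in c("a", "b")) {
    tags <- .load_tags(out_dir, lib, totals)
    N <- totals$total_clean_reads[totals$library == lib]
    q <- quantify_library(tags, catalog, N = N)
    quants[[lib]] <- q
    p <- c(stats::setNames(file.path(out_dir, paste0(
      c("expression_", "unannotated_"), lib, ".tsv")),
      paste0(c("expression_", "unannotated_"), lib)))
    write_tsv(as.data.frame(q$profile), p[[paste0("expression_", lib)]])
    write_tsv(as.data.frame(q$unannotated), p[[paste0("unannotated_", lib)]])
    paths <- c(paths, p)
    message("[quantify] library ", lib, ": ",
            sum(q$profile$count > 0), "/", nrow(catalog),
            " miRNAs detected")
  }
  combined <- data.frame(
    mirna = quants$a$profile$mirna,
    count_1 = quants$a$profile$count, count_2 = quants$b$profile$count,
    tpm_1 = quants$a$profile$tpm, tpm_2 = quants$b$profile$tpm,
    confidence = 1, stringsAsFactors = FALSE
  )
  paths[["expression_combined"]] <- file.path(out_dir,
                                              "expression_combined.tsv")
  write_tsv(combined, paths[["expression_combined"]])
  paths[["metadata"]] <- .write_metadata(
    "quantify", config, c(cat_path, totals_path), paths, out_dir)
  paths
}

.stage_variants <- function(config, out_dir) {
  cat_path <- config$catalog
  if (is.null(cat_path)) cat_path <- file.path(out_dir, "catalog.fasta")
  .require_input(cat_path, "catalog FASTA")
  catalog <- load_mature_fasta(cat_path)
  totals <- read_tsv(.require_input(file.path(out_dir, "library_totals.tsv"),
                                    "library totals (run clean first)"))
  paths <- character(0)
  for (lib in c("a", "b")) {
    upath <- .require_input(
      file.path(out_dir, paste0("unannotated_", lib, ".tsv")),
      paste0("unannotated pool (run quantify first)"))
    pool <- tag_set(read_tsv(upath), totals$label[totals$library == lib])
    events <- detect_seed_edits(pool, catalog, min_count = config$min_count)
    spec <- substitution_spectrum(events)
    p <- stats::setNames(file.path(out_dir, paste0(
      c("variants_", "spectrum_"), lib, ".tsv")),
      paste0(c("variants_", "spectrum_"), lib))
    write_tsv(events, p[[paste0("variants_", lib)]])
    write_tsv(spec, p[[paste0("spectrum_", lib)]])
    paths <- c(paths, p)
    message("[variants] library ", lib, ": ",
            sum(events$class == "seed_edit"), " seed-edit events on ",
            edited_mirna_count(events), " miRNAs")
  }
  paths[["metadata"]] <- .write_metadata("variants", config, cat_path,
                                         paths, out_dir)
  paths
}

.stage_de <- function(config, out_dir) {
  comb_path <- .require_input(file.path(out_dir, "expression_combined.tsv"),
                              "combined expression table (run quantify first)")
  totals <- read_tsv(.require_input(file.path(out_dir, "library_totals.tsv"),
                                    "library totals (run clean first)"))
  comb <- read_tsv(comb_path)
  N1 <- totals$total_clean_reads[totals$library == "a"]
  N2 <- totals$total_clean_reads[totals$library == "b"]
  p1 <- tpm_normalize(data.frame(mirna = comb$mirna, count = comb$count_1),
                      N1, totals$label[totals$library == "a"])
  p2 <- tpm_normalize(data.frame(mirna = comb$mirna, count = comb$count_2),
                      N2, totals$label[totals$library == "b"])
  paired <- paired_expression(p1, p2, confidence = comb$confidence)
  dem <- call_dems(paired, alpha = config$alpha,
                   fc_threshold = config$fc_threshold,
                   tpm_floor = config$tpm_floor,
                   confidence_floor = config$confidence_floor,
                   pvalue_mode = config$pvalue_mode,
                   pseudocount = config$pseudocount)
  paths <- c(dem = file.path(out_dir, "dem.tsv"))
  write_tsv(as.data.frame(dem), paths[["dem"]])
  paths[["metadata"]] <- .write_metadata("de", config, comb_path, paths,
                                         out_dir)
  message("[de] ", sum(dem$status == "up"), " up / ",
          sum(dem$status == "down"), " down at alpha=", config$alpha)
  paths
}

.stage_enrich <- function(config, out_dir) {
  qpath <- .require_input(config$enrich_query, "enrichment query gene list")
  mpath <- .require_input(config$enrich_map, "term-to-gene map TSV")
  query <- readLines(qpath, warn = FALSE)
  query <- trimws(query[nzchar(trimws(query))])
  enr <- hypergeom_enrich(query, read_term_map(mpath))
  paths <- c(enrichment = file.path(out_dir, "enrichment.tsv"))
  write_tsv(enr, paths[["enrichment"]])
  paths[["metadata"]] <- .write_metadata("enrich", config, c(qpath, mpath),
                                         paths, out_dir)
  message("[enrich] ", sum(enr$q < 0.05), " term(s) at Q < 0.05")
  paths
}

.stage_ddct <- function(config, out_dir) {
  tpath <- .require_input(config$ddct_table, "Ct table TSV")
  if (is.null(config$ddct_reference_gene) || is.null(config$ddct_target_gene)) {
    stop("ddct_reference_gene and ddct_target_gene must be configured")
  }
  res <- ddct(read_ct_table(tpath), config$ddct_reference_gene,
              config$ddct_target_gene)
  out <- data.frame(target = config$ddct_target_gene,
                    reference = config$ddct_reference_gene,
                    ddct = res$ddct, fold_change = res$fold_change,
                    stringsAsFactors = FALSE)
  paths <- c(ddct = file.path(out_dir, "ddct.tsv"),
             ddct_per_sample = file.path(out_dir, "ddct_per_sample.tsv"))
  write_tsv(out, paths[["ddct"]])
  write_tsv(res$per_sample, paths[["ddct_per_sample"]])
  paths[["metadata"]] <- .write_metadata("ddct", config, tpath, paths,
                                         out_dir)
  message("[ddct] fold change ", signif(res$fold_change, 4))
  paths
}
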