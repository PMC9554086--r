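.PIPELINE_KEYS <- c("seed", "cohort_a", "cohort_b", "threshold",
                    "motif_threshold", "label", "simulate", "inputs")

.validatePipelineConfig <- function(config) {
  bad <- setdiff(names(config), .PIPELINE_KEYS)
  msg <- character()
  if (length(bad))
    msg <- c(msg, paste("unknown config key(s):", paste(bad, collapse = ", ")))
  for (key in c("cohort_a", "cohort_b"))
    if (is.null(config[[key]]))
      msg <- c(msg, paste("missing required config key:", key))
  if (is.null(config$simulate) && is.null(config$inputs))
    msg <- c(msg, "config needs either a 'simulate' block or an 'inputs' block")
  if (length(msg))
    stop("invalid pipeline config: ", paste(msg, collapse = "; "))
  invisible(config)
}

.configToSimConfig <- function(block, seed) {
  block <- as.list(block)
  known <- c("n_per_cohort", "clones_per_repertoire", "zipf_exponent",
             "count_scale", "tissue_sharing")
  bad <- setdiff(names(block), known)
  if (length(bad))
    stop("invalid pipeline config: unknown simulate key(s): ",
         paste(bad, collapse = ", "))
  args <- block
  if (!is.null(args$n_per_cohort)) args$n_per_cohort <- unlist(args$n_per_cohort)
  do.call(simConfig, c(list(seed = seed), args))
}

#' Run the full discovery pipeline
#'
#' One-command analysis: obtain repertoires (from the synthetic generator
#' or from AIRR files on disk), scan clonotype families between two
#' cohorts, derive the consensus CDR3 motif of the top-ranked family,
#' compute per-individual burden records and cohort comparisons, build the
#' sharing network, and write all result files plus a machine-readable
#' summary. Deterministic given (config, seed).
#'
#' Output files: `families.tsv`, `sequence_tests.tsv`, `pfm.tsv`,
#' `motif.txt`, `burden.tsv`, `network.graphml`, `summary.json`.
#'
#' @param config path to a YAML file or a named list with keys:
#'   `seed`; `cohort_a`, `cohort_b` (required cohort labels);
#'   `threshold` (abundance threshold, default 0.025);
#'   `motif_threshold` (consensus conservation threshold, default 0.7);
#'   `label` (class label for burden/network stages, default `"CAIT"`);
#'   and either `simulate` (a block of [simConfig()] arguments) or
#'   `inputs` (list with `metadata` path and `dir` of AIRR files).
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when given.
#' @return invisibly, a list with the in-memory results (`scan`, `motif`,
#'   `pfm`, `burden`, `comparison`, `summary`).
#' @export
runPipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  .validatePipelineConfig(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  threshold <- config$threshold %||% 0.025
  motif_threshold <- config$motif_threshold %||% 0.7
  label <- config$label %||% "CAIT"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    cfg <- .configToSimConfig(config$simulate, seed)
    study <- genCohortStudy(cfg)
    reps <- study$repertoires
    message(sprintf("simulate: %d repertoires generated", length(reps)))
  } else {
    metadata <- readSampleMetadata(config$inputs$metadata)
    reps <- readRepertoires(metadata, dir = config$inputs$dir %||% ".")
    message(sprintf("inputs: %d repertoires read", length(reps)))
  }

  cohorts <- vapply(reps, cohort, character(1))
  for (key in c("cohort_a", "cohort_b"))
    if (!any(cohorts == config[[key]]))
      stop(sprintf("no repertoires with cohort '%s'", config[[key]]))
  reps_a <- reps[cohorts == config$cohort_a]
  reps_b <- reps[cohorts == config$cohort_b]

  scan <- scanFamilies(reps_a, reps_b)
  data.table::fwrite(scan, file.path(out_dir, "families.tsv"), sep = "\t")
  top <- scan[1, ]
  message(sprintf("enrich: %d families scanned; top %s/%s/%d (q=%.3g)",
                  nrow(scan), top$v_gene, top$j_gene, top$cdr3_length,
                  top$q_value))

  seq_tests <- sequencePresenceScan(reps_a, reps_b, v_gene = top$v_gene,
                                    j_gene = top$j_gene,
                                    cdr3_length = top$cdr3_length)
  data.table::fwrite(seq_tests, file.path(out_dir, "sequence_tests.tsv"),
                     sep = "\t")

  fam_seqs <- familySequences(reps_a, top$v_gene, top$j_gene, top$cdr3_length)
  motif <- NULL
  if (nrow(fam_seqs) >= 2L) {
    pfm <- buildPFM(fam_seqs$cdr3_aa)
    motif <- deriveConsensus(pfm, motif_threshold)
    writePFM(pfm, file.path(out_dir, "pfm.tsv"))
    writeLines(as.character(motif), file.path(out_dir, "motif.txt"))
    message(sprintf("motif: %d sequences -> %s", nrow(fam_seqs),
                    as.character(motif)))
  }

  records <- burdenTable(reps, label = label, threshold = threshold)
  data.table::fwrite(records, file.path(out_dir, "burden.tsv"), sep = "\t")
  comparison <- compareCohorts(records,
                               pairs = list(c(config$cohort_a, config$cohort_b)))
  summary_tab <- cohortSummary(records)
  message(sprintf("burden: %d records; %s vs %s q=%.3g",
                  nrow(records), config$cohort_a, config$cohort_b,
                  comparison$q_value[1]))

  network <- sharingNetwork(reps, label = label)
  writeNetwork(network, file.path(out_dir, "network.graphml"))

  summary <- list(
    seed = seed, label = label, threshold = threshold,
    n_repertoires = length(reps),
    top_family = list(v_gene = top$v_gene, j_gene = top$j_gene,
                      cdr3_length = top$cdr3_length,
                      q_value = top$q_value, log2_ratio = top$log2_ratio),
    consensus_motif = if (!is.null(motif)) as.character(motif) else NA,
    burden_comparison = as.list(comparison[1, ]),
    cohort_summary = summary_tab,
    network_nodes = igraph::vcount(network$graph)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(scan = scan, sequence_tests = seq_tests, motif = motif,
                 burden = records, comparison = comparison,
                 summary = summary))
}
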