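#' Strip IMGT allele suffixes from gene calls
#'
#' Removes the `*NN` allele designation from IMGT gene names
#' (`"TRAV12-1*01"` becomes `"TRAV12-1"`) and trims whitespace. Idempotent.
#'
#' @param x character vector of gene calls.
#' @return character vector of gene names without allele suffixes.
#' @examples
#' stripAllele(c("TRAV12-1*01", "TRAJ6"))
#' @export
stripAllele <- function(x) sub("\\*.*$", "", trimws(as.character(x)))

.productive <- function(junction) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]{5,}$", junction)
}

#' Read a bulk repertoire from an AIRR Rearrangement TSV
#'
#' Reads one sample's rearrangements in AIRR TSV format, keeps productive
#' amino-acid junctions (the 20 standard residues only, length >= 5), strips
#' allele suffixes from gene calls, merges duplicate (chain, V, J, CDR3) rows
#' by summing counts and computes relative frequencies from the merged
#' counts. The chain is inferred from the V gene prefix (`TRAV` -> TRA,
#' `TRBV` -> TRB); rows of other loci are dropped.
#'
#' @param path path to a tab-separated AIRR Rearrangement file with at least
#'   the columns `v_call`, `j_call` and `junction_aa`. A `duplicate_count`
#'   column is used as the clone size when present; otherwise each row counts
#'   as one.
#' @param metadata a list or one-row data.frame with fields `sample_id`,
#'   `subject_id`, `cohort`, `tissue`, `fraction` (missing fields fall back
#'   to the file name / `"bulk"` defaults).
#' @return A [Repertoire-class] object.
#' @seealso [writeAIRR()], [readSampleMetadata()]
#' @export
readAIRR <- function(path, metadata = list()) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", showProgress = FALSE)
  required <- c("v_call", "j_call", "junction_aa")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop(sprintf("AIRR file '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  count <- if ("duplicate_count" %in% names(dt)) as.numeric(dt$duplicate_count) else rep(1, nrow(dt))
  count[is.na(count)] <- 1
  v <- stripAllele(dt$v_call)
  j <- stripAllele(dt$j_call)
  chain <- substr(v, 1L, 3L)
  chain[chain == "TRA"] <- "TRA"
  chain[chain == "TRB"] <- "TRB"
  keep <- chain %in% .CHAINS & .productive(dt$junction_aa) & count > 0
  if (!any(keep))
    stop(sprintf("AIRR file '%s' has no productive TRA/TRB rows after filtering", path))
  md <- as.list(metadata)
  default_id <- tools::file_path_sans_ext(basename(path))
  Repertoire(
    data.frame(chain = chain[keep], v_gene = v[keep], j_gene = j[keep],
               cdr3_aa = dt$junction_aa[keep], count = count[keep],
               stringsAsFactors = FALSE),
    sample_id  = md$sample_id  %||% default_id,
    subject_id = md$subject_id %||% md$sample_id %||% default_id,
    cohort     = md$cohort     %||% "HC",
    tissue     = md$tissue     %||% "blood",
    fraction   = md$fraction   %||% "bulk")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write a Repertoire as an AIRR Rearrangement TSV
#'
#' Serializes the clonotype table with columns `v_call`, `j_call`,
#' `junction_aa`, `duplicate_count`. Re-reading the file with [readAIRR()]
#' reproduces the same clonotypes and frequencies.
#'
#' @param rep a [Repertoire-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAIRR <- function(rep, path) {
  cl <- clonotypes(rep)
  out <- data.frame(v_call = cl$v_gene, j_call = cl$j_gene,
                    junction_aa = cl$cdr3_aa, duplicate_count = cl$count)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sample-metadata table
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `cohort`,
#'   `tissue`, `fraction`.
#' @return data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  need <- c("sample_id", "subject_id", "cohort", "tissue", "fraction")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata file missing column(s): ", paste(missing_cols, collapse = ", "))
  data.table::setDF(md)
}

#' Read a cohort of AIRR files listed in a metadata table
#'
#' @param metadata data.frame as returned by [readSampleMetadata()], with an
#'   additional `path` column (or files named `<sample_id>.tsv` under `dir`).
#' @param dir directory holding the AIRR files when `metadata` has no
#'   `path` column.
#' @return list of [Repertoire-class] objects, named by sample id.
#' @export
readRepertoires <- function(metadata, dir = ".") {
  paths <- if ("path" %in% names(metadata)) metadata$path
           else file.path(dir, paste0(metadata$sample_id, ".tsv"))
  reps <- lapply(seq_len(nrow(metadata)), function(i)
    readAIRR(paths[i], metadata[i, , drop = FALSE]))
  names(reps) <- metadata$sample_id
  reps
}

#' Read a 10x-style filtered-contig table into cell records
#'
#' Parses a contig CSV (columns `barcode`, `chain`, `v_gene`, `j_gene`,
#' `cdr3`; optional `umis`) into one [CellRecord-class] per barcode.
#' Multiple contigs of the same chain (e.g. dual-alpha cells) are kept.
#' Allele suffixes are stripped from gene names.
#'
#' @param path contig CSV path.
#' @param markers_path optional TSV keyed by `barcode` whose remaining
#'   columns are per-cell marker expression values (e.g. `KLRB1`, `CD8A`).
#' @return list of [CellRecord-class] objects, named by barcode.
#' @export
readContigs <- function(path, markers_path = NULL) {
  contigs <- data.table::fread(path, header = TRUE, showProgress = FALSE)
  markers <- if (!is.null(markers_path))
    data.table::fread(markers_path, sep = "\t", header = TRUE, showProgress = FALSE)
  asCellRecords(contigs, markers)
}

#' Convert a contig table (and optional marker table) to cell records
#'
#' @param contigs data.frame with columns `barcode`, `chain`, `v_gene`,
#'   `j_gene`, `cdr3` and optional `umis`.
#' @param markers optional data.frame with a `barcode` column plus one
#'   column per marker gene.
#' @return list of [CellRecord-class] objects, named by barcode.
#' @export
asCellRecords <- function(contigs, markers = NULL) {
  need <- c("barcode", "chain", "v_gene", "j_gene", "cdr3")
  missing_cols <- setdiff(need, names(contigs))
  if (length(missing_cols))
    stop("contig table missing column(s): ", paste(missing_cols, collapse = ", "))
  contigs <- as.data.frame(contigs)
  bad <- setdiff(unique(contigs$chain), .CHAINS)
  if (length(bad))
    stop("unknown chain value(s) in contig table: ", paste(bad, collapse = ", "))
  contigs$v_gene <- stripAllele(contigs$v_gene)
  contigs$j_gene <- stripAllele(contigs$j_gene)
  contigs$umis <- if ("umis" %in% names(contigs)) as.numeric(contigs$umis) else NA_real_
  marker_map <- NULL
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    if (!"barcode" %in% names(markers))
      stop("marker table must have a 'barcode' column")
    marker_map <- markers[!duplicated(markers$barcode), , drop = FALSE]
    rownames(marker_map) <- marker_map$barcode
  }
  chainDF <- function(df) data.frame(v_gene = df$v_gene, j_gene = df$j_gene,
                                     cdr3_aa = df$cdr3, umis = df$umis,
                                     stringsAsFactors = FALSE)
  split_rows <- split(seq_len(nrow(contigs)), contigs$barcode)
  cells <- lapply(names(split_rows), function(bc) {
    rows <- contigs[split_rows[[bc]], , drop = FALSE]
    mk <- numeric(0)
    if (!is.null(marker_map) && bc %in% rownames(marker_map)) {
      row <- marker_map[bc, setdiff(names(marker_map), "barcode"), drop = FALSE]
      mk <- setNames(as.numeric(row), names(row))
    }
    new("CellRecord", barcode = bc,
        alpha = chainDF(rows[rows$chain == "TRA", , drop = FALSE]),
        beta  = chainDF(rows[rows$chain == "TRB", , drop = FALSE]),
        markers = mk)
  })
  names(cells) <- names(split_rows)
  cells
}
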