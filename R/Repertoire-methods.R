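#' Construct a Repertoire
#'
#' Builds a [Repertoire-class] object from a clonotype table, merging
#' duplicate (chain, V, J, CDR3) rows by summing counts and recomputing
#' relative frequencies from the merged counts.
#'
#' @param clonotypes data.frame with columns `chain`, `v_gene`, `j_gene`,
#'   `cdr3_aa` and `count`. A `frequency` column, if present, is ignored and
#'   recomputed. Gene names are normalized with [stripAllele()].
#' @param sample_id,subject_id sample and donor identifiers.
#' @param cohort one of `"CD"`, `"UC"`, `"HC"`, `"CRC"`.
#' @param tissue one of `"blood"`, `"gut"`, `"lymph_node"`.
#' @param fraction `"bulk"` (default) or a sorted fraction
#'   (`"CD8"`, `"CD4_mem"`, `"CD4_naive"`, `"Treg"`).
#'
#' @return A validated [Repertoire-class] object.
#' @examples
#' rep <- Repertoire(
#'   data.frame(chain = "TRA", v_gene = "TRAV12-1", j_gene = "TRAJ6",
#'              cdr3_aa = "CVVNLASGGSYIPTF", count = 10),
#'   sample_id = "s1", subject_id = "d1", cohort = "CD", tissue = "blood")
#' clonotypes(rep)
#' @export
Repertoire <- function(clonotypes, sample_id, subject_id = sample_id,
                       cohort = "HC", tissue = "blood", fraction = "bulk") {
  need <- c("chain", "v_gene", "j_gene", "cdr3_aa", "count")
  missing_cols <- setdiff(need, names(clonotypes))
  if (length(missing_cols))
    stop("clonotype table missing column(s): ", paste(missing_cols, collapse = ", "))
  dt <- data.table::as.data.table(clonotypes[, need])
  dt[, `:=`(v_gene = stripAllele(v_gene), j_gene = stripAllele(j_gene),
            count = as.numeric(count))]
  dt <- dt[, .(count = sum(count)), by = .(chain, v_gene, j_gene, cdr3_aa)]
  data.table::setorder(dt, -count, chain, v_gene, j_gene, cdr3_aa)
  total <- sum(dt$count)
  if (!is.finite(total) || total <= 0)
    stop("repertoire has zero total count")
  dt[, frequency := count / total]
  new("Repertoire",
      sample_id = as.character(sample_id), subject_id = as.character(subject_id),
      cohort = as.character(cohort), tissue = as.character(tissue),
      fraction = as.character(fraction),
      clonotypes = data.table::setDF(dt))
}

#' Accessors for Repertoire objects
#'
#' @param x a [Repertoire-class] object.
#' @return `sampleID`, `subjectID`, `cohort`, `tissue` and `cellFraction`
#'   return the corresponding metadata string; `clonotypes` returns the
#'   clonotype data.frame.
#' @name Repertoire-accessors
#' @aliases sampleID subjectID cohort tissue cellFraction clonotypes
NULL

#' @rdname Repertoire-accessors
#' @export
setMethod("sampleID", "Repertoire", function(x) x@sample_id)

#' @rdname Repertoire-accessors
#' @export
setMethod("subjectID", "Repertoire", function(x) x@subject_id)

#' @rdname Repertoire-accessors
#' @export
setMethod("cohort", "Repertoire", function(x) x@cohort)

#' @rdname Repertoire-accessors
#' @export
setMethod("tissue", "Repertoire", function(x) x@tissue)

#' @rdname Repertoire-accessors
#' @export
setMethod("cellFraction", "Repertoire", function(x) x@fraction)

#' @rdname Repertoire-accessors
#' @export
setMethod("clonotypes", "Repertoire", function(x) x@clonotypes)

setMethod("show", "Repertoire", function(object) {
  cl <- object@clonotypes
  cat(sprintf("Repertoire '%s' (subject %s, %s/%s/%s)\n",
              object@sample_id, object@subject_id, object@cohort,
              object@tissue, object@fraction))
  cat(sprintf("  %d clonotypes, %s total counts\n",
              nrow(cl), format(sum(cl$count), big.mark = ",")))
  if (nrow(cl)) {
    top <- head(cl[order(-cl$frequency), ], 3L)
    cat(sprintf("  top clonotype: %s %s/%s (%.3g)\n",
                top$cdr3_aa[1], top$v_gene[1], top$j_gene[1], top$frequency[1]))
  }
  invisible(NULL)
})

#' Accessors for CellRecord objects
#'
#' @param x a [CellRecord-class] object.
#' @return `barcode` returns the barcode string; `alphaChains`/`betaChains`
#'   the corresponding chain data.frames; `markers` the named expression
#'   vector.
#' @name CellRecord-accessors
#' @aliases barcode alphaChains betaChains markers
NULL

#' @rdname CellRecord-accessors
#' @export
setMethod("barcode", "CellRecord", function(x) x@barcode)

#' @rdname CellRecord-accessors
#' @export
setMethod("alphaChains", "CellRecord", function(x) x@alpha)

#' @rdname CellRecord-accessors
#' @export
setMethod("betaChains", "CellRecord", function(x) x@beta)

#' @rdname CellRecord-accessors
#' @export
setMethod("markers", "CellRecord", function(x) x@markers)

setMethod("show", "CellRecord", function(object) {
  cat(sprintf("CellRecord %s: %d TRA, %d TRB chain(s)",
              object@barcode, nrow(object@alpha), nrow(object@beta)))
  if (length(object@markers))
    cat(sprintf(", markers: %s", paste(names(object@markers), collapse = ",")))
  cat("\n")
  invisible(NULL)
})
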