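#' Construct a MotifPattern from a pattern string
#'
#' @param pattern a string over the 20 amino-acid letters and the wildcard
#'   character, e.g. `"CVV**A*GGSYIPTF"`.
#' @param wildcard the wildcard character (default `"*"`).
#' @return A [MotifPattern-class] object.
#' @examples
#' motifPattern("CVV**A*GGSYIPTF")
#' @export
motifPattern <- function(pattern, wildcard = "*") {
  chars <- strsplit(pattern, "")[[1]]
  chars[chars == wildcard] <- NA_character_
  new("MotifPattern", positions = chars)
}

#' @describeIn motifPattern number of positions in the pattern.
#' @param x a [MotifPattern-class] object.
#' @export
setMethod("length", "MotifPattern", function(x) length(x@positions))

#' @export
setMethod("as.character", "MotifPattern", function(x) {
  p <- x@positions
  p[is.na(p)] <- "*"
  paste(p, collapse = "")
})

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern %s (%d positions, %d fixed)\n",
              as.character(object), length(object@positions),
              sum(!is.na(object@positions))))
  invisible(NULL)
})

#' Match CDR3 junctions against a motif pattern
#'
#' A junction matches when its length equals the pattern length and every
#' fixed position carries exactly the pattern's residue; wildcard positions
#' accept anything. Vectorized over junctions.
#'
#' @param cdr3_aa character vector of amino-acid junctions.
#' @param pattern a [MotifPattern-class] object.
#' @return logical vector.
#' @examples
#' matchMotif(c("CVVNLASGGSYIPTF", "CVVNLTSGGSYIPTF"), caitMotif())
#' @export
matchMotif <- function(cdr3_aa, pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  n <- length(pattern@positions)
  ok <- nchar(cdr3_aa) == n & !is.na(cdr3_aa)
  if (!any(ok)) return(ok)
  fixed <- which(!is.na(pattern@positions))
  idx <- which(ok)
  for (i in fixed) {
    idx <- idx[substr(cdr3_aa[idx], i, i) == pattern@positions[i]]
    if (!length(idx)) break
  }
  out <- rep(FALSE, length(cdr3_aa))
  out[idx] <- TRUE
  out
}

#' Construct a classification rule
#'
#' @param label class label (e.g. `"CAIT"`).
#' @param chain `"TRA"` or `"TRB"`.
#' @param v,j character vectors of permitted V and J genes.
#' @param cdr3_length required junction length, or `NA` for no constraint.
#' @param motif optional [MotifPattern-class] (or pattern string).
#' @return A [ClassRule-class] object.
#' @examples
#' classRule("CAIT", v = "TRAV12-1", j = "TRAJ6",
#'           cdr3_length = 15, motif = "CVV**A*GGSYIPTF")
#' @export
classRule <- function(label, chain = "TRA", v, j, cdr3_length = NA, motif = NULL) {
  if (is.character(motif)) motif <- motifPattern(motif)
  new("ClassRule", label = label, chain = chain,
      allowed_v = stripAllele(v), allowed_j = stripAllele(j),
      cdr3_length = as.integer(cdr3_length), motif = motif)
}

setMethod("show", "ClassRule", function(object) {
  cat(sprintf("ClassRule '%s': %s, V in {%s}, J in {%s}%s%s\n",
              object@label, object@chain,
              paste(object@allowed_v, collapse = ","),
              paste(object@allowed_j, collapse = ","),
              if (is.na(object@cdr3_length)) "" else
                sprintf(", CDR3 length %d", object@cdr3_length),
              if (is.null(object@motif)) "" else
                sprintf(", motif %s", as.character(object@motif))))
  invisible(NULL)
})

#' The CAIT CDR3 alpha motif
#'
#' The semi-invariant 15-residue junction motif of Crohn-associated invariant
#' T (CAIT) alpha chains, `CVV**A*GGSYIPTF`: positions 4, 5 and 7 are
#' variable wildcards, all other positions (including the conserved C/F
#' anchors) are fixed.
#'
#' @return A [MotifPattern-class] object.
#' @export
caitMotif <- function() motifPattern("CVV**A*GGSYIPTF")

#' Default invariant T cell classification rules
#'
#' Three rules, evaluated in precedence order:
#' \describe{
#'   \item{CAIT}{TRAV12-1 + TRAJ6, junction length 15, motif
#'     `CVV**A*GGSYIPTF`.}
#'   \item{MAIT}{TRAV1-2 + TRAJ33/TRAJ20/TRAJ12 (broad gene-based
#'     definition; no length constraint by default).}
#'   \item{iNKT}{TRAV10 + TRAJ18.}
#' }
#' The gene sets are disjoint, so precedence only matters defensively.
#'
#' @param mait_length optional junction-length constraint for the MAIT rule
#'   (`NA` by default; set to 12 for the narrow canonical family).
#' @return list of [ClassRule-class] objects in evaluation order.
#' @export
defaultRules <- function(mait_length = NA) {
  list(
    classRule("CAIT", v = "TRAV12-1", j = "TRAJ6",
              cdr3_length = 15, motif = caitMotif()),
    classRule("MAIT", v = "TRAV1-2", j = c("TRAJ33", "TRAJ20", "TRAJ12"),
              cdr3_length = mait_length),
    classRule("iNKT", v = "TRAV10", j = "TRAJ18")
  )
}

.ruleMatches <- function(rule, chain, v, j, cdr3) {
  hit <- chain == rule@chain & v %in% rule@allowed_v & j %in% rule@allowed_j
  if (!is.na(rule@cdr3_length))
    hit <- hit & nchar(cdr3) == rule@cdr3_length
  if (!is.null(rule@motif))
    hit <- hit & matchMotif(cdr3, rule@motif)
  hit
}

#' Classify clonotypes into invariant T categories
#'
#' Applies a list of [ClassRule-class] rules in order; the first matching
#' rule assigns the label, non-matching clonotypes (including all TRB
#' clonotypes under the default TRA rules) are labelled `"other"`.
#'
#' @param x a [Repertoire-class] or a clonotype data.frame with columns
#'   `chain`, `v_gene`, `j_gene`, `cdr3_aa`.
#' @param rules list of [ClassRule-class] objects (default [defaultRules()]).
#' @return character vector of labels, one per clonotype.
#' @examples
#' df <- data.frame(chain = "TRA", v_gene = "TRAV12-1", j_gene = "TRAJ6",
#'                  cdr3_aa = "CVVNLASGGSYIPTF")
#' classifyClonotypes(df)
#' @export
classifyClonotypes <- function(x, rules = defaultRules()) {
  cl <- if (is(x, "Repertoire")) clonotypes(x) else x
  labels <- rep("other", nrow(cl))
  v <- stripAllele(cl$v_gene)
  j <- stripAllele(cl$j_gene)
  for (rule in rules) {
    open <- labels == "other"
    if (!any(open)) break
    hit <- .ruleMatches(rule, cl$chain[open], v[open], j[open], cl$cdr3_aa[open])
    labels[open][hit] <- rule@label
  }
  labels
}

#' Classify a single cell by its TCR alpha chains
#'
#' A cell takes the highest-priority label matched by any of its alpha
#' chains (a cell with any CAIT alpha is CAIT, otherwise any MAIT alpha
#' makes it MAIT, then iNKT, else `"other"`). Cells without an alpha chain
#' cannot be classified and return `NA`.
#'
#' @param cell a [CellRecord-class] object.
#' @param rules list of [ClassRule-class] objects in precedence order.
#' @return character(1) label, or `NA_character_` for cells with no alpha
#'   chain.
#' @seealso [classifyCells()] for a vector of cells.
#' @export
classifyCell <- function(cell, rules = defaultRules()) {
  a <- alphaChains(cell)
  if (!nrow(a)) return(NA_character_)
  for (rule in rules) {
    if (rule@chain != "TRA") next
    if (any(.ruleMatches(rule, rep("TRA", nrow(a)), a$v_gene, a$j_gene, a$cdr3_aa)))
      return(rule@label)
  }
  "other"
}

#' @describeIn classifyCell classify a list of cells; returns a character
#'   vector named by barcode.
#' @param cells list of [CellRecord-class] objects.
#' @export
classifyCells <- function(cells, rules = defaultRules()) {
  vapply(cells, classifyCell, character(1), rules = rules)
}
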