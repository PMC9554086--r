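.pairedClonotypes <- function(cells, label, rules) {
  lab <- classifyCells(cells, rules)
  keep <- which(!is.na(lab) & lab == label)
  rows <- lapply(keep, function(i) {
    cell <- cells[[i]]
    a <- alphaChains(cell)
    hit_a <- .ruleMatchesAny(a, rules, label)
    if (!any(hit_a)) return(NULL)
    a <- a[which(hit_a)[1], , drop = FALSE]
    b <- betaChains(cell)
    if (!nrow(b)) return(NULL)
    if (nrow(b) > 1L) {
      # with per-contig abundance, keep the dominant beta; otherwise count
      # both pairings as separate clonotypes
      if (!all(is.na(b$umis))) b <- b[which.max(b$umis), , drop = FALSE]
    }
    data.frame(alpha_v = a$v_gene, alpha_j = a$j_gene, alpha_cdr3 = a$cdr3_aa,
               beta_v = b$v_gene, beta_j = b$j_gene, beta_cdr3 = b$cdr3_aa,
               stringsAsFactors = FALSE)
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) return(data.table::setDF(out))
  unique(data.table::setDF(out))
}

.ruleMatchesAny <- function(chains, rules, label) {
  rule <- Filter(function(r) r@label == label, rules)
  if (!length(rule)) stop(sprintf("no rule with label '%s'", label))
  rule <- rule[[1]]
  if (!nrow(chains)) return(logical(0))
  .ruleMatches(rule, rep(rule@chain, nrow(chains)),
               chains$v_gene, chains$j_gene, chains$cdr3_aa)
}

#' TRBV gene usage among paired clonotypes of one class
#'
#' For cells classified into a class (default CAIT) that carry a beta chain,
#' collapses cells to unique paired clonotypes (alpha V/J/CDR3 + beta
#' V/J/CDR3, so clonal expansion does not inflate usage) and returns the
#' proportion of unique clonotypes using each TRBV gene. Cells with two
#' beta chains contribute their dominant beta when per-contig UMI counts are
#' available, otherwise both pairings count as separate clonotypes.
#'
#' @param cells list of [CellRecord-class] objects.
#' @param label class label (default `"CAIT"`).
#' @param rules classification rules.
#' @return named numeric vector of proportions over unique clonotypes
#'   (sums to 1), sorted decreasing; empty when no labelled cell has a beta
#'   chain.
#' @export
trbvUsage <- function(cells, label = "CAIT", rules = defaultRules()) {
  pc <- .pairedClonotypes(cells, label, rules)
  if (!nrow(pc)) return(setNames(numeric(0), character(0)))
  tab <- table(pc$beta_v)
  sort(tab / sum(tab), decreasing = TRUE)
}

#' Fraction of labelled cells among V-gene-restricted, gated cells
#'
#' The denominator is the set of cells carrying at least one alpha chain
#' with the requested V gene and passing every marker gate; the numerator
#' is those classified into the requested label. Used e.g. for the fraction
#' of CAIT cells among TRAV12-1+ cells, optionally restricted to KLRB1- or
#' CD8A-expressing cells.
#'
#' @param cells list of [CellRecord-class] objects.
#' @param v_gene alpha V gene defining the denominator (e.g. `"TRAV12-1"`).
#' @param label class label for the numerator (default `"CAIT"`).
#' @param rules classification rules.
#' @param gates optional named numeric vector: a cell passes when its
#'   expression of each named marker is strictly greater than the given
#'   value (e.g. `c(KLRB1 = 0)` for KLRB1-expressing cells). Cells lacking
#'   a gated marker raise an error.
#' @return one-row data.frame: `fraction`, `n_cells` (denominator),
#'   `n_label` (numerator), `empty_denominator` (flag; fraction is 0 with a
#'   warning when no cell passes).
#' @export
fractionAmongV <- function(cells, v_gene, label = "CAIT",
                           rules = defaultRules(), gates = NULL) {
  passesGates <- function(cell) {
    if (is.null(gates) || !length(gates)) return(TRUE)
    mk <- markers(cell)
    missing_mk <- setdiff(names(gates), names(mk))
    if (length(missing_mk))
      stop("gate references marker(s) absent from cell ", barcode(cell), ": ",
           paste(missing_mk, collapse = ", "))
    all(mk[names(gates)] > gates)
  }
  inV <- vapply(cells, function(cell) {
    a <- alphaChains(cell)
    nrow(a) > 0L && v_gene %in% a$v_gene
  }, logical(1))
  gated <- vapply(cells, passesGates, logical(1))
  denom <- cells[inV & gated]
  if (!length(denom)) {
    warning(sprintf("no %s+ cells pass the gates; returning fraction 0", v_gene))
    return(data.frame(fraction = 0, n_cells = 0L, n_label = 0L,
                      empty_denominator = TRUE))
  }
  lab <- classifyCells(denom, rules)
  n_label <- sum(!is.na(lab) & lab == label)
  data.frame(fraction = n_label / length(denom),
             n_cells = length(denom), n_label = n_label,
             empty_denominator = FALSE)
}
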