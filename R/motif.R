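#' Build a position frequency matrix from equal-length junctions
#'
#' Columns are junction positions, rows the 20 standard residues; each
#' column sums to 1. By default every distinct sequence contributes equally
#' (logo over unique clonotypes); optional non-negative weights (e.g. number
#' of carrying subjects) reweight the sequences.
#'
#' @param sequences character vector of >= 2 equal-length amino-acid
#'   junctions.
#' @param weights optional non-negative numeric weights, one per sequence.
#' @return numeric matrix (20 residues x L positions), columns summing to 1.
#' @examples
#' pfm <- buildPFM(c("CVVA", "CVVG"))
#' pfm[c("A", "G"), 4]
#' @export
buildPFM <- function(sequences, weights = NULL) {
  if (length(sequences) < 2L)
    stop("need at least 2 sequences to build a position frequency matrix")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop(sprintf("sequences must all have the same length (found lengths %s)",
                 paste(sort(unique(lens)), collapse = ", ")))
  if (is.null(weights)) weights <- rep(1, length(sequences))
  if (length(weights) != length(sequences) || any(weights < 0))
    stop("weights must be non-negative, one per sequence")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  L <- lens[1]
  chars <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                  nrow = L)
  pfm <- matrix(0, nrow = length(AA_ALPHABET), ncol = L,
                dimnames = list(AA_ALPHABET, seq_len(L)))
  for (pos in seq_len(L)) {
    tab <- tapply(weights, factor(chars[pos, ], levels = AA_ALPHABET), sum)
    tab[is.na(tab)] <- 0
    pfm[, pos] <- tab / sum(weights)
  }
  pfm
}

#' Derive a consensus motif from a position frequency matrix
#'
#' A position is fixed to its modal residue when the modal frequency reaches
#' the conservation threshold, and becomes a wildcard otherwise. Modal ties
#' are broken alphabetically so the result is deterministic.
#'
#' @param pfm matrix as returned by [buildPFM()].
#' @param conservation_threshold fraction in (0, 1]; default 0.7.
#' @return A [MotifPattern-class] object.
#' @examples
#' pfm <- buildPFM(c("CVVA", "CVVG"))
#' as.character(deriveConsensus(pfm, 0.6))  # "CVV*"
#' @export
deriveConsensus <- function(pfm, conservation_threshold = 0.7) {
  if (!is.numeric(conservation_threshold) ||
      length(conservation_threshold) != 1L ||
      conservation_threshold <= 0 || conservation_threshold > 1)
    stop("conservation_threshold must be a single value in (0, 1]")
  if (any(abs(colSums(pfm) - 1) > 1e-6))
    stop("pfm columns must sum to 1")
  # rows are sorted alphabetically by construction; which.max keeps the
  # alphabetically first residue on ties
  pfm <- pfm[order(rownames(pfm)), , drop = FALSE]
  positions <- apply(pfm, 2, function(col) {
    i <- which.max(col)
    if (col[i] >= conservation_threshold - 1e-12) rownames(pfm)[i]
    else NA_character_
  })
  new("MotifPattern", positions = unname(positions))
}

#' Write a position frequency matrix as TSV
#'
#' Logo-ready orientation: one row per position, one column per residue
#' (the transpose of [buildPFM()] output), as consumed by standard
#' sequence-logo tools.
#'
#' @param pfm matrix from [buildPFM()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePFM <- function(pfm, path) {
  out <- data.frame(position = seq_len(ncol(pfm)), t(pfm), check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
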