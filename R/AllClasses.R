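#' @import methods
#' @importFrom stats fisher.test p.adjust rlnorm rpois runif setNames wilcox.test
#' @importFrom utils combn head
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.COHORTS   <- c("CD", "UC", "HC", "CRC")
.TISSUES   <- c("blood", "gut", "lymph_node")
.FRACTIONS <- c("bulk", "CD8", "CD4_mem", "CD4_naive", "Treg")
.CHAINS    <- c("TRA", "TRB")

CLONOTYPE_COLS <- c("chain", "v_gene", "j_gene", "cdr3_aa", "count", "frequency")

#' Repertoire: one sample's clonotype collection
#'
#' An S4 container holding the unique clonotypes of a single TCR repertoire
#' sample together with its metadata. A clonotype is identified by
#' (chain, V gene, J gene, CDR3 amino-acid junction); the junction string
#' includes the conserved cysteine and phenylalanine/tryptophan anchors.
#' Relative frequencies are computed from counts and sum to one.
#'
#' @slot sample_id character(1) unique sample identifier.
#' @slot subject_id character(1) donor identifier (several samples may share one).
#' @slot cohort character(1), one of `"CD"`, `"UC"`, `"HC"`, `"CRC"`.
#' @slot tissue character(1), one of `"blood"`, `"gut"`, `"lymph_node"`.
#' @slot fraction character(1), `"bulk"` or a sorted T cell fraction
#'   (`"CD8"`, `"CD4_mem"`, `"CD4_naive"`, `"Treg"`).
#' @slot clonotypes data.frame with columns `chain`, `v_gene`, `j_gene`,
#'   `cdr3_aa`, `count`, `frequency`.
#'
#' @seealso [Repertoire()], [readAIRR()], [clonotypes()]
#' @exportClass Repertoire
setClass("Repertoire",
  representation(
    sample_id  = "character",
    subject_id = "character",
    cohort     = "character",
    tissue     = "character",
    fraction   = "character",
    clonotypes = "data.frame"
  )
)

setValidity("Repertoire", function(object) {
  msg <- character()
  for (s in c("sample_id", "subject_id", "cohort", "tissue", "fraction")) {
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  }
  if (!object@cohort %in% .COHORTS)
    msg <- c(msg, sprintf("cohort must be one of %s", paste(.COHORTS, collapse = ", ")))
  if (!object@tissue %in% .TISSUES)
    msg <- c(msg, sprintf("tissue must be one of %s", paste(.TISSUES, collapse = ", ")))
  if (!object@fraction %in% .FRACTIONS)
    msg <- c(msg, sprintf("fraction must be one of %s", paste(.FRACTIONS, collapse = ", ")))
  cl <- object@clonotypes
  missing_cols <- setdiff(CLONOTYPE_COLS, names(cl))
  if (length(missing_cols))
    msg <- c(msg, paste("clonotypes missing column(s):", paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols) && nrow(cl) > 0L) {
    if (!all(cl$chain %in% .CHAINS))
      msg <- c(msg, "chain values must be TRA or TRB")
    if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cl$cdr3_aa)))
      msg <- c(msg, "cdr3_aa must use the 20-letter amino-acid alphabet")
    if (any(nchar(cl$cdr3_aa) < 5L))
      msg <- c(msg, "cdr3_aa must be at least 5 residues long")
    if (any(cl$count < 0))
      msg <- c(msg, "counts must be non-negative")
    if (abs(sum(cl$frequency) - 1) > 1e-6)
      msg <- c(msg, "clonotype frequencies must sum to 1 within 1e-6")
    if (max(abs(cl$frequency - cl$count / sum(cl$count))) > 1e-9)
      msg <- c(msg, "frequency must equal count / total count within 1e-9")
    key <- paste(cl$chain, cl$v_gene, cl$j_gene, cl$cdr3_aa, sep = "|")
    if (anyDuplicated(key))
      msg <- c(msg, "(chain, v_gene, j_gene, cdr3_aa) must be unique within a repertoire")
  }
  if (length(msg)) msg else TRUE
})

#' MotifPattern: per-position CDR3 constraint
#'
#' A fixed-length amino-acid pattern in which each position is either a fixed
#' residue or a wildcard (stored as `NA`). Rendered as a string, wildcards are
#' shown as `*`, e.g. the Crohn-associated invariant T (CAIT) alpha-chain
#' motif `"CVV**A*GGSYIPTF"`.
#'
#' @slot positions character vector; one entry per position, `NA` = wildcard.
#'
#' @seealso [motifPattern()], [matchMotif()], [deriveConsensus()]
#' @exportClass MotifPattern
setClass("MotifPattern", representation(positions = "character"))

setValidity("MotifPattern", function(object) {
  p <- object@positions
  msg <- character()
  if (length(p) < 1L)
    msg <- c(msg, "pattern must have at least one position")
  fixed <- !is.na(p)
  if (!any(fixed))
    msg <- c(msg, "pattern must have at least one fixed position")
  if (any(fixed & !(p %in% AA_ALPHABET)))
    msg <- c(msg, "fixed positions must be single standard amino-acid letters")
  if (length(msg)) msg else TRUE
})

setClassUnion("MotifPatternOrNULL", c("MotifPattern", "NULL"))

#' ClassRule: rule defining one invariant T cell class
#'
#' A gene-usage rule (with optional CDR3 length and motif constraints) used to
#' assign clonotypes to invariant T categories such as MAIT
#' (TRAV1-2 + TRAJ33/20/12), iNKT (TRAV10 + TRAJ18) and CAIT
#' (TRAV12-1 + TRAJ6 + 15-mer motif).
#'
#' @slot label character(1) class label.
#' @slot chain character(1), `"TRA"` or `"TRB"`.
#' @slot allowed_v character, permitted V genes (allele suffixes stripped).
#' @slot allowed_j character, permitted J genes.
#' @slot cdr3_length integer(1) required junction length, or `NA` for none.
#' @slot motif [MotifPattern-class] or `NULL`.
#'
#' @seealso [classRule()], [defaultRules()], [classifyClonotypes()]
#' @exportClass ClassRule
setClass("ClassRule",
  representation(
    label       = "character",
    chain       = "character",
    allowed_v   = "character",
    allowed_j   = "character",
    cdr3_length = "integer",
    motif       = "MotifPatternOrNULL"
  )
)

setValidity("ClassRule", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a non-empty string")
  if (length(object@chain) != 1L || !object@chain %in% .CHAINS)
    msg <- c(msg, "chain must be TRA or TRB")
  if (length(object@allowed_v) < 1L) msg <- c(msg, "allowed_v must be non-empty")
  if (length(object@allowed_j) < 1L) msg <- c(msg, "allowed_j must be non-empty")
  if (length(object@cdr3_length) != 1L)
    msg <- c(msg, "cdr3_length must be a single integer or NA")
  if (length(msg)) msg else TRUE
})

#' CellRecord: one single-cell barcode with its chains
#'
#' Holds the TRA and TRB chain assignments of one cell barcode from a
#' 10x-style filtered-contig table, plus optional per-cell marker expression
#' values (e.g. KLRB1, CD8A) used for gating.
#'
#' @slot barcode character(1).
#' @slot alpha data.frame of TRA chains (`v_gene`, `j_gene`, `cdr3_aa`, `umis`).
#' @slot beta data.frame of TRB chains (same columns).
#' @slot markers named numeric vector of expression values (may be empty).
#'
#' @seealso [readContigs()], [classifyCell()]
#' @exportClass CellRecord
setClass("CellRecord",
  representation(
    barcode = "character",
    alpha   = "data.frame",
    beta    = "data.frame",
    markers = "numeric"
  )
)

setValidity("CellRecord", function(object) {
  msg <- character()
  if (length(object@barcode) != 1L || !nzchar(object@barcode))
    msg <- c(msg, "barcode must be a non-empty string")
  if (nrow(object@alpha) + nrow(object@beta) < 1L)
    msg <- c(msg, "cell must carry at least one chain")
  for (s in c("alpha", "beta")) {
    df <- slot(object, s)
    if (nrow(df) && !all(c("v_gene", "j_gene", "cdr3_aa") %in% names(df)))
      msg <- c(msg, sprintf("%s chains need v_gene, j_gene, cdr3_aa columns", s))
  }
  if (any(object@markers < 0, na.rm = TRUE))
    msg <- c(msg, "marker expression values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SpikeSpec: one planted semi-invariant clonotype class
#'
#' Describes how the simulator plants a semi-invariant clonotype family into
#' generated repertoires: the gene pair, a junction generator, the per-cohort
#' carrier prevalence, and the distribution of the cumulative abundance the
#' planted clonotypes should reach in a carrier.
#'
#' @slot label character(1) class label (e.g. `"CAIT"`).
#' @slot v_gene,j_gene character(1) genes of the planted family.
#' @slot cdr3_fun function(n) returning n junction strings.
#' @slot prevalence named numeric, per-cohort probability that a sample carries
#'   the spike.
#' @slot abundance_meanlog named numeric (or single value applied to every
#'   cohort): meanlog of the log-normal cumulative-abundance target.
#' @slot abundance_sdlog numeric(1) sdlog of the same distribution.
#' @slot n_clonotypes_lambda numeric(1); a carrier receives
#'   `1 + rpois(lambda)` distinct planted clonotypes.
#'
#' @seealso [caitSpike()], [maitSpike()], [simConfig()]
#' @exportClass SpikeSpec
setClass("SpikeSpec",
  representation(
    label               = "character",
    v_gene              = "character",
    j_gene              = "character",
    cdr3_fun            = "function",
    prevalence          = "numeric",
    abundance_meanlog   = "numeric",
    abundance_sdlog     = "numeric",
    n_clonotypes_lambda = "numeric"
  )
)

setValidity("SpikeSpec", function(object) {
  msg <- character()
  if (any(object@prevalence < 0 | object@prevalence > 1))
    msg <- c(msg, "prevalence values must lie in [0, 1]")
  if (is.null(names(object@prevalence)))
    msg <- c(msg, "prevalence must be named by cohort")
  if (object@abundance_sdlog < 0)
    msg <- c(msg, "abundance_sdlog must be non-negative")
  if (any(exp(object@abundance_meanlog) >= 1))
    msg <- c(msg, "median abundance target must be below 1 (a spike cannot exceed the whole repertoire)")
  if (object@n_clonotypes_lambda < 0)
    msg <- c(msg, "n_clonotypes_lambda must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic repertoire study configuration
#'
#' Parameters of the synthetic-data generator: cohort sizes, per-repertoire
#' clone number, the Zipf clone-size law, V/J usage and CDR3 length and
#' residue distributions for the background repertoire, the planted
#' semi-invariant spikes, cross-tissue sharing, and the paired single-cell
#' scenario. See [simConfig()] for defaults.
#'
#' @slot seed integer(1) base seed; all generated data derive from it.
#' @slot n_per_cohort named integer, samples per cohort.
#' @slot clones_per_repertoire integer(1).
#' @slot zipf_exponent numeric(1) > 1; clone sizes follow rank^(-exponent).
#' @slot count_scale numeric(1); multiplier on the Zipf counts, controls the
#'   sequencing depth (and hence the resolution of relative frequencies).
#' @slot v_usage,j_usage named numeric background gene-usage distributions.
#' @slot cdr3_length_dist named numeric distribution over junction lengths.
#' @slot background_aa_dist named numeric distribution over the 20 residues
#'   used for non-anchor junction positions.
#' @slot spikes list of [SpikeSpec-class] objects.
#' @slot tissue_sharing numeric(1) in `[0, 1]`: probability that a planted
#'   clonotype of a multi-tissue subject is also present in each non-blood
#'   tissue.
#' @slot paired named list of paired single-cell scenario parameters
#'   (see [simConfig()]).
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed                  = "integer",
    n_per_cohort          = "integer",
    clones_per_repertoire = "integer",
    zipf_exponent         = "numeric",
    count_scale           = "numeric",
    v_usage               = "numeric",
    j_usage               = "numeric",
    cdr3_length_dist      = "numeric",
    background_aa_dist    = "numeric",
    spikes                = "list",
    tissue_sharing        = "numeric",
    paired                = "list"
  )
)

.checkDist <- function(x, what) {
  msg <- character()
  if (is.null(names(x)) || any(!nzchar(names(x))))
    msg <- c(msg, sprintf("%s must be a named probability vector", what))
  if (any(x < 0)) msg <- c(msg, sprintf("%s must be non-negative", what))
  if (abs(sum(x) - 1) > 1e-9)
    msg <- c(msg, sprintf("%s must sum to 1 within 1e-9", what))
  msg
}

setValidity("SimConfig", function(object) {
  msg <- character()
  msg <- c(msg, .checkDist(object@v_usage, "v_usage"))
  msg <- c(msg, .checkDist(object@j_usage, "j_usage"))
  msg <- c(msg, .checkDist(object@cdr3_length_dist, "cdr3_length_dist"))
  msg <- c(msg, .checkDist(object@background_aa_dist, "background_aa_dist"))
  if (!setequal(names(object@background_aa_dist), AA_ALPHABET))
    msg <- c(msg, "background_aa_dist must cover exactly the 20 standard residues")
  if (object@zipf_exponent <= 1)
    msg <- c(msg, "zipf_exponent must be > 1")
  if (object@clones_per_repertoire < 1)
    msg <- c(msg, "clones_per_repertoire must be positive")
  if (object@tissue_sharing < 0 || object@tissue_sharing > 1)
    msg <- c(msg, "tissue_sharing must lie in [0, 1]")
  if (!all(vapply(object@spikes, inherits, logical(1), "SpikeSpec")))
    msg <- c(msg, "spikes must be a list of SpikeSpec objects")
  if (length(msg)) msg else TRUE
})
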