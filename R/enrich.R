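#' Per-sample clonotype family table
#'
#' Aggregates a repertoire's clonotype frequencies into TCR "families"
#' defined by (V gene, J gene, CDR3 amino-acid length). Every clonotype
#' belongs to exactly one family, so the family frequencies sum to 1.
#'
#' @param rep a [Repertoire-class] object.
#' @param chain restrict to one chain (default `"TRA"`; use `NULL` for both).
#' @return data.frame with columns `v_gene`, `j_gene`, `cdr3_length`,
#'   `frequency`. When restricted to one chain, frequencies are renormalized
#'   within that chain.
#' @export
familyTable <- function(rep, chain = "TRA") {
  cl <- data.table::as.data.table(clonotypes(rep))
  if (!is.null(chain)) cl <- cl[cl$chain %in% chain, ]
  if (!nrow(cl)) {
    return(data.frame(v_gene = character(), j_gene = character(),
                      cdr3_length = integer(), frequency = numeric()))
  }
  cl[, cdr3_length := nchar(cdr3_aa)]
  fam <- cl[, .(frequency = sum(frequency)), by = .(v_gene, j_gene, cdr3_length)]
  fam[, frequency := frequency / sum(frequency)]
  data.table::setorder(fam, -frequency, v_gene, j_gene, cdr3_length)
  data.table::setDF(fam)
}

.familyLong <- function(reps, chain) {
  data.table::rbindlist(lapply(seq_along(reps), function(i) {
    ft <- familyTable(reps[[i]], chain = chain)
    if (!nrow(ft)) return(NULL)
    ft$sample <- i
    ft
  }))
}

#' Scan clonotype families for cohort enrichment
#'
#' The discovery stage: for every (V gene, J gene, CDR3 length) family
#' observed in at least one sample, compares per-sample within-repertoire
#' family frequencies between two cohorts with a two-sided Mann-Whitney U
#' test (samples lacking the family contribute frequency 0), and adjusts the
#' p-values across all families with Benjamini-Hochberg. Results are sorted
#' by adjusted p-value, then by larger absolute log2 mean-frequency ratio,
#' then lexicographically by family key, so the ordering is deterministic.
#'
#' @param cohort_a,cohort_b lists of [Repertoire-class] objects (at least 2
#'   samples each).
#' @param chain chain to scan (default `"TRA"`).
#' @return data.frame with one row per family: `v_gene`, `j_gene`,
#'   `cdr3_length`, `mean_freq_a`, `mean_freq_b`, `n_carriers_a`,
#'   `n_carriers_b`, `log2_ratio`, `p_value`, `q_value`.
#' @examples
#' \dontrun{
#' scan <- scanFamilies(cd_reps, hc_reps)
#' head(scan)  # top family: enriched / depleted candidates
#' }
#' @export
scanFamilies <- function(cohort_a, cohort_b, chain = "TRA") {
  if (length(cohort_a) < 2L || length(cohort_b) < 2L)
    stop("each cohort needs at least 2 repertoires")
  na <- length(cohort_a); nb <- length(cohort_b)
  long_a <- .familyLong(cohort_a, chain)
  long_b <- .familyLong(cohort_b, chain)
  long_a$side <- "a"; long_b$side <- "b"
  long <- data.table::rbindlist(list(long_a, long_b))
  if (!nrow(long)) stop("no clonotypes of the requested chain in either cohort")
  long[, fam := paste(v_gene, j_gene, cdr3_length, sep = "|")]
  fams <- unique(long[, .(fam, v_gene, j_gene, cdr3_length)])
  # family x sample frequency matrices, absent = 0
  famMatrix <- function(d, n) {
    m <- matrix(0, nrow = nrow(fams), ncol = n,
                dimnames = list(fams$fam, NULL))
    if (nrow(d)) m[cbind(match(d$fam, fams$fam), d$sample)] <- d$frequency
    m
  }
  ma <- famMatrix(long[side == "a"], na)
  mb <- famMatrix(long[side == "b"], nb)
  p <- vapply(seq_len(nrow(fams)), function(i) .mwApprox(ma[i, ], mb[i, ]),
              numeric(1))
  res <- data.frame(
    v_gene = fams$v_gene, j_gene = fams$j_gene, cdr3_length = fams$cdr3_length,
    mean_freq_a = rowMeans(ma), mean_freq_b = rowMeans(mb),
    n_carriers_a = rowSums(ma > 0), n_carriers_b = rowSums(mb > 0),
    p_value = p, row.names = NULL)
  res$log2_ratio <- .log2Ratio(res$mean_freq_a, res$mean_freq_b)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  key <- paste(res$v_gene, res$j_gene, res$cdr3_length, sep = "|")
  res[order(res$q_value, -abs(res$log2_ratio), key), ]
}

.hasClonotype <- function(rep, v, j, cdr3, chain = "TRA") {
  cl <- clonotypes(rep)
  any(cl$chain == chain & cl$v_gene == v & cl$j_gene == j & cl$cdr3_aa == cdr3)
}

#' Fisher presence test for a single clonotype
#'
#' Tests whether a clonotype (V gene, J gene, CDR3) is present (count >= 1)
#' in more samples of one cohort than the other, using a two-sided Fisher
#' exact test on the 2x2 carrier table. The reported odds ratio is the
#' conditional maximum-likelihood estimate of [stats::fisher.test()].
#'
#' @param v_gene,j_gene,cdr3_aa the clonotype key.
#' @param cohort_a,cohort_b lists of [Repertoire-class] objects.
#' @param chain chain of the clonotype (default `"TRA"`).
#' @return one-row data.frame: `v_gene`, `j_gene`, `cdr3_aa`, `carriers_a`,
#'   `n_a`, `carriers_b`, `n_b`, `odds_ratio`, `p_value`.
#' @export
fisherPresence <- function(v_gene, j_gene, cdr3_aa, cohort_a, cohort_b,
                           chain = "TRA") {
  if (!length(cohort_a) || !length(cohort_b))
    stop("both cohorts must be non-empty")
  ca <- sum(vapply(cohort_a, .hasClonotype, logical(1), v_gene, j_gene, cdr3_aa, chain))
  cb <- sum(vapply(cohort_b, .hasClonotype, logical(1), v_gene, j_gene, cdr3_aa, chain))
  na <- length(cohort_a); nb <- length(cohort_b)
  ft <- fisher.test(matrix(c(ca, na - ca, cb, nb - cb), nrow = 2))
  data.frame(v_gene = v_gene, j_gene = j_gene, cdr3_aa = cdr3_aa,
             carriers_a = ca, n_a = na, carriers_b = cb, n_b = nb,
             odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Per-sequence presence scan within a candidate family
#'
#' Runs [fisherPresence()] for every distinct clonotype of a candidate
#' family (by default; set `all_sequences = TRUE` to scan every sequence of
#' the chain, at a much larger multiplicity burden) and adjusts p-values
#' with Benjamini-Hochberg across the scanned sequences.
#'
#' @param cohort_a,cohort_b lists of [Repertoire-class] objects.
#' @param v_gene,j_gene,cdr3_length the candidate family; ignored when
#'   `all_sequences = TRUE`.
#' @param chain chain to scan (default `"TRA"`).
#' @param all_sequences scan every distinct sequence of the chain instead of
#'   one family.
#' @return data.frame of [fisherPresence()] rows plus `q_value`, sorted by
#'   `q_value` then decreasing carrier excess.
#' @export
sequencePresenceScan <- function(cohort_a, cohort_b, v_gene = NULL,
                                 j_gene = NULL, cdr3_length = NULL,
                                 chain = "TRA", all_sequences = FALSE) {
  pick <- function(rep) {
    cl <- clonotypes(rep)
    cl <- cl[cl$chain == chain, , drop = FALSE]
    if (!all_sequences)
      cl <- cl[cl$v_gene == v_gene & cl$j_gene == j_gene &
               nchar(cl$cdr3_aa) == cdr3_length, , drop = FALSE]
    cl[, c("v_gene", "j_gene", "cdr3_aa")]
  }
  seqs <- unique(data.table::rbindlist(lapply(c(cohort_a, cohort_b), pick)))
  if (!nrow(seqs)) {
    return(data.frame(v_gene = character(), j_gene = character(),
                      cdr3_aa = character(), carriers_a = integer(),
                      n_a = integer(), carriers_b = integer(),
                      n_b = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric()))
  }
  res <- data.table::rbindlist(lapply(seq_len(nrow(seqs)), function(i)
    fisherPresence(seqs$v_gene[i], seqs$j_gene[i], seqs$cdr3_aa[i],
                   cohort_a, cohort_b, chain = chain)))
  res <- data.table::setDF(res)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res[order(res$q_value, -(res$carriers_a - res$carriers_b), res$cdr3_aa), ]
}

#' Collect the distinct junctions of one family across samples
#'
#' Pools the unique CDR3 junctions of a (V, J, length) family over a set of
#' repertoires, with the number of carrying subjects as a weight. Used to
#' feed [buildPFM()] / [deriveConsensus()] after a family scan.
#'
#' @param reps list of [Repertoire-class] objects.
#' @param v_gene,j_gene,cdr3_length the family key.
#' @param chain chain (default `"TRA"`).
#' @return data.frame with columns `cdr3_aa` and `n_subjects`.
#' @export
familySequences <- function(reps, v_gene, j_gene, cdr3_length, chain = "TRA") {
  rows <- data.table::rbindlist(lapply(reps, function(rep) {
    cl <- clonotypes(rep)
    cl <- cl[cl$chain == chain & cl$v_gene == v_gene & cl$j_gene == j_gene &
             nchar(cl$cdr3_aa) == cdr3_length, , drop = FALSE]
    if (!nrow(cl)) return(NULL)
    data.frame(cdr3_aa = unique(cl$cdr3_aa), subject = subjectID(rep))
  }))
  if (!nrow(rows)) return(data.frame(cdr3_aa = character(), n_subjects = integer()))
  dt <- data.table::as.data.table(rows)[, .(n_subjects = length(unique(subject))),
                                        by = cdr3_aa]
  data.table::setorder(dt, -n_subjects, cdr3_aa)
  data.table::setDF(dt)
}
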