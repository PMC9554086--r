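#' Per-individual burden of a clonotype class
#'
#' Counts the distinct clonotypes of one invariant T class in a repertoire
#' and sums their relative frequencies (the cumulative abundance). The log10
#' cumulative abundance uses the figure convention that an abundance of 0 is
#' represented as -6; the threshold flag is strict ("more than" the
#' threshold), with 2.5% of the repertoire as the default cut-off.
#'
#' @param rep a [Repertoire-class] object.
#' @param label class label to count (default `"CAIT"`).
#' @param rules classification rules (default [defaultRules()]).
#' @param threshold abundance threshold in (0, 1); default 0.025.
#' @return one-row data.frame: `sample_id`, `subject_id`, `cohort`,
#'   `tissue`, `fraction`, `label`, `n_clonotypes`, `cum_abundance`,
#'   `log_abundance`, `above_threshold`.
#' @examples
#' \dontrun{
#' burden(rep, "CAIT")$cum_abundance
#' }
#' @export
burden <- function(rep, label = "CAIT", rules = defaultRules(),
                   threshold = 0.025) {
  labels <- classifyClonotypes(rep, rules)
  cl <- clonotypes(rep)
  hit <- labels == label
  cum <- sum(cl$frequency[hit])
  data.frame(
    sample_id = sampleID(rep), subject_id = subjectID(rep),
    cohort = cohort(rep), tissue = tissue(rep), fraction = cellFraction(rep),
    label = label,
    n_clonotypes = sum(hit),
    cum_abundance = cum,
    log_abundance = if (cum > 0) log10(cum) else -6,
    above_threshold = cum > threshold,
    stringsAsFactors = FALSE)
}

#' @describeIn burden burden records for a list of repertoires (one row per
#'   sample).
#' @param reps list of [Repertoire-class] objects.
#' @export
burdenTable <- function(reps, label = "CAIT", rules = defaultRules(),
                        threshold = 0.025) {
  data.table::setDF(data.table::rbindlist(
    lapply(reps, burden, label = label, rules = rules, threshold = threshold)))
}

#' Compare cumulative abundance between cohorts
#'
#' Two-sided Mann-Whitney U tests on per-individual cumulative abundance for
#' each requested cohort pair, followed by Benjamini-Hochberg adjustment
#' across the pairs. Small samples with no ties use the exact U
#' distribution; small tied samples use an exact midrank permutation test;
#' larger samples use the normal approximation with tie midranks and
#' continuity correction.
#'
#' @param records data.frame of burden records (from [burdenTable()]).
#' @param pairs list of length-2 character vectors of cohort labels; default
#'   all pairs of cohorts present in `records`.
#' @param value column to compare (default `"cum_abundance"`).
#' @return data.frame with one row per pair: `cohort_a`, `cohort_b`, `n_a`,
#'   `n_b`, `p_value`, `q_value`.
#' @export
compareCohorts <- function(records, pairs = NULL, value = "cum_abundance") {
  if (is.null(pairs)) {
    cohorts <- sort(unique(records$cohort))
    if (length(cohorts) < 2L) stop("need at least two cohorts to compare")
    pairs <- combn(cohorts, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    x <- records[records$cohort == pr[1], value]
    y <- records[records$cohort == pr[2], value]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("cohort pair %s vs %s has fewer than 2 records per side",
                   pr[1], pr[2]))
    data.frame(cohort_a = pr[1], cohort_b = pr[2],
               n_a = length(x), n_b = length(y),
               p_value = .mwTest(x, y))
  })
  res <- data.table::setDF(data.table::rbindlist(rows))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res
}

.truncate1 <- function(x) floor(x * 10 + 1e-9) / 10

#' Per-cohort carrier and above-threshold summary
#'
#' For each cohort: the number of individuals carrying at least one labelled
#' clonotype and the number whose cumulative abundance exceeds the
#' threshold, with percentages reported under both conventions in use for
#' such summaries -- rounded to the nearest integer and truncated to one
#' decimal place.
#'
#' @param records data.frame of burden records (from [burdenTable()]).
#' @return data.frame with one row per cohort: `cohort`, `n`, `carriers`,
#'   `pct_carriers`, `pct_carriers_1dp`, `above_threshold`, `pct_above`,
#'   `pct_above_1dp`.
#' @examples
#' recs <- data.frame(cohort = rep("CD", 4), n_clonotypes = c(1, 2, 0, 0),
#'                    cum_abundance = c(0.03, 0.01, 0, 0),
#'                    above_threshold = c(TRUE, FALSE, FALSE, FALSE))
#' cohortSummary(recs)
#' @export
cohortSummary <- function(records) {
  dt <- data.table::as.data.table(records)
  out <- dt[, .(
    n = .N,
    carriers = sum(n_clonotypes >= 1L),
    above_threshold = sum(above_threshold)
  ), by = cohort]
  out[, `:=`(
    pct_carriers     = round(100 * carriers / n),
    pct_carriers_1dp = .truncate1(100 * carriers / n),
    pct_above        = round(100 * above_threshold / n),
    pct_above_1dp    = .truncate1(100 * above_threshold / n)
  )]
  data.table::setcolorder(out, c("cohort", "n", "carriers", "pct_carriers",
                                 "pct_carriers_1dp", "above_threshold",
                                 "pct_above", "pct_above_1dp"))
  data.table::setDF(out)
}
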