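.twoCaitRep <- function(counts_cait, total = 1000, sample_id = "s1",
                        cohort = "CD") {
  cait_cdr3 <- c("CVVNLASGGSYIPTF", "CVVKRASGGSYIPTF")[seq_along(counts_cait)]
  makeRep(v = c(rep("TRAV12-1", length(counts_cait)), "TRAV2"),
          j = c(rep("TRAJ6", length(counts_cait)), "TRAJ4"),
          cdr3 = c(cait_cdr3, "CAASFGNEKLTF"),
          count = c(counts_cait, total - sum(counts_cait)),
          sample_id = sample_id, cohort = cohort)
}

test_that("burden counts labelled clonotypes and sums their frequencies", {
  rep <- .twoCaitRep(c(10, 20))
  rec <- burden(rep, "CAIT")
  expect_equal(rec$n_clonotypes, 2L)
  expect_equal(rec$cum_abundance, 0.03, tolerance = 1e-12)
  expect_true(rec$above_threshold)
  expect_equal(rec$log_abundance, log10(0.03))
})

test_that("zero burden maps to -6 on the log scale", {
  rep <- repWithClonotype(0, "s0")
  rec <- burden(rep, "CAIT")
  expect_equal(rec$n_clonotypes, 0L)
  expect_equal(rec$cum_abundance, 0)
  expect_equal(rec$log_abundance, -6)
  expect_false(rec$above_threshold)
})

test_that("the abundance threshold is strict", {
  rep <- .twoCaitRep(25)  # exactly 2.5% of 1000
  rec <- burden(rep, "CAIT")
  expect_equal(rec$cum_abundance, 0.025, tolerance = 1e-12)
  expect_false(rec$above_threshold)
  rec2 <- burden(.twoCaitRep(26), "CAIT")
  expect_true(rec2$above_threshold)
})

test_that("cumulative abundance is additive and monotone", {
  one <- burden(.twoCaitRep(10), "CAIT")$cum_abundance
  two <- burden(.twoCaitRep(c(10, 20)), "CAIT")$cum_abundance
  expect_gt(two, one)
  expect_equal(two, 0.01 + 0.02, tolerance = 1e-12)
})

test_that("compareCohorts gives p = 1 for identical cohorts", {
  recs <- data.frame(cohort = rep(c("CD", "HC"), each = 3),
                     cum_abundance = rep(c(0.1, 0.2, 0.3), 2))
  res <- compareCohorts(recs)
  expect_equal(res$p_value, 1)
})

test_that("complete separation with ties matches the exact permutation value", {
  recs <- data.frame(cohort = rep(c("CD", "HC"), each = 10),
                     cum_abundance = c(rep(0.05, 10), rep(0, 10)))
  res <- compareCohorts(recs, pairs = list(c("CD", "HC")))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("compareCohorts is invariant to monotone transforms", {
  set.seed(23)
  recs <- data.frame(cohort = rep(c("CD", "HC"), each = 12),
                     cum_abundance = c(runif(12, 0, 0.1), runif(12, 0, 0.02)))
  p1 <- compareCohorts(recs, pairs = list(c("CD", "HC")))$p_value
  recs$cum_abundance <- sqrt(recs$cum_abundance)
  p2 <- compareCohorts(recs, pairs = list(c("CD", "HC")))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("compareCohorts rejects undersized cohorts and adjusts across pairs", {
  recs <- data.frame(cohort = c("CD", "HC", "HC"), cum_abundance = c(1, 2, 3))
  expect_error(compareCohorts(recs, pairs = list(c("CD", "HC"))),
               "fewer than 2")
  set.seed(3)
  recs2 <- data.frame(cohort = rep(c("CD", "UC", "HC"), each = 5),
                      cum_abundance = runif(15))
  res <- compareCohorts(recs2)
  expect_equal(nrow(res), 3L)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("a planted abundance difference is detected", {
  cfg <- smallCfg(seed = 11, n = 30L, clones = 400L)
  study <- genCohortStudy(cfg)
  recs <- burdenTable(study$repertoires)
  res <- compareCohorts(recs, pairs = list(c("CD", "HC")))
  expect_lt(res$q_value, 0.05)
  expect_gt(mean(recs$cum_abundance[recs$cohort == "CD"]),
            mean(recs$cum_abundance[recs$cohort == "HC"]))
})

test_that("the mirrored MAIT analysis shows depletion in CD", {
  cfg <- smallCfg(seed = 29, n = 30L, clones = 400L,
                  spikes = list(caitSpike(), maitSpike()))
  study <- genCohortStudy(cfg)
  recs <- burdenTable(study$repertoires, label = "MAIT")
  res <- compareCohorts(recs, pairs = list(c("CD", "HC")))
  expect_lt(res$q_value, 0.05)
  expect_lt(mean(recs$cum_abundance[recs$cohort == "CD"]),
            mean(recs$cum_abundance[recs$cohort == "HC"]))
})

test_that("cohortSummary reports both rounding conventions", {
  mkRecs <- function(cohort, n, carriers, above) {
    data.frame(cohort = cohort,
               n_clonotypes = c(rep(1L, carriers), rep(0L, n - carriers)),
               above_threshold = c(rep(TRUE, above), rep(FALSE, n - above)))
  }
  recs <- mkRecs("CD", 109, 49, 32)
  s <- cohortSummary(recs)
  expect_equal(s$pct_carriers, 45)       # 49/109, nearest integer
  expect_equal(s$pct_above_1dp, 29.3)    # 32/109, truncated to one decimal
  empty <- cohortSummary(mkRecs("HC", 20, 0, 0))
  expect_equal(empty$pct_carriers, 0)
  expect_equal(empty$pct_above_1dp, 0)
})
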