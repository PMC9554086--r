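test_that("familyTable groups frequencies by (V, J, CDR3 length)", {
  rep <- makeRep(v = c("TRAV12-1", "TRAV1-2"), j = c("TRAJ6", "TRAJ33"),
                 cdr3 = c("CVVNLASGGSYIPTF", "CAVKDSNYQLIW"),
                 count = c(25, 75))
  ft <- familyTable(rep)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$frequency[ft$v_gene == "TRAV12-1"], 0.25)
  expect_equal(ft$frequency[ft$v_gene == "TRAV1-2"], 0.75)
  expect_equal(ft$cdr3_length, c(12L, 15L))
  # empty family query
  expect_equal(sum(ft$frequency[ft$v_gene == "TRAV10"]), 0)
})

test_that("familyTable matches an independent groupby and sums to 1", {
  cfg <- smallCfg(seed = 1, n = 1L, clones = 300L)
  set.seed(1)
  rep <- genRepertoire(cfg, "CD", sample_id = "ft1")
  ft <- familyTable(rep)
  expect_equal(sum(ft$frequency), 1, tolerance = 1e-6)
  # brute-force oracle: tapply over pasted keys
  cl <- clonotypes(rep)
  key <- paste(cl$v_gene, cl$j_gene, nchar(cl$cdr3_aa))
  oracle <- tapply(cl$frequency, key, sum)
  got <- setNames(ft$frequency, paste(ft$v_gene, ft$j_gene, ft$cdr3_length))
  expect_equal(sort(names(got)), sort(names(oracle)))
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle), tolerance = 1e-12)
})

test_that("scanFamilies on two identical cohorts finds nothing", {
  cohort <- carrierCohort(2, 4, cohort = "CD")
  scan <- scanFamilies(cohort, cohort)
  expect_true(all(scan$q_value == 1))
  expect_true(all(abs(scan$mean_freq_a - scan$mean_freq_b) < 1e-12))
})

test_that("scanFamilies is symmetric under cohort swap", {
  set.seed(5)
  a <- carrierCohort(3, 5, cohort = "CD", prefix = "a")
  b <- carrierCohort(1, 5, cohort = "HC", prefix = "b")
  fwd <- scanFamilies(a, b)
  rev <- scanFamilies(b, a)
  key <- function(d) paste(d$v_gene, d$j_gene, d$cdr3_length)
  m <- match(key(fwd), key(rev))
  expect_equal(fwd$p_value, rev$p_value[m], tolerance = 1e-12)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio[m], tolerance = 1e-9)
})

test_that("scanFamilies requires at least two samples per cohort", {
  a <- carrierCohort(1, 1, cohort = "CD")
  b <- carrierCohort(0, 4, cohort = "HC")
  expect_error(scanFamilies(a, b), "at least 2")
})

test_that("scanFamilies recovers a planted family in a small study", {
  cfg <- smallCfg(seed = 7, n = 30L, clones = 500L)
  study <- genCohortStudy(cfg)
  co <- vapply(study$repertoires, cohort, character(1))
  scan <- scanFamilies(study$repertoires[co == "CD"],
                       study$repertoires[co == "HC"])
  planted <- scan$v_gene == "TRAV12-1" & scan$j_gene == "TRAJ6" &
    scan$cdr3_length == 15
  expect_true(any(planted))
  # at this reduced scale the planted family should carry the single
  # smallest raw p-value and an enrichment-direction effect; genome-wide
  # q-value significance needs the full study size
  expect_equal(scan$p_value[planted], min(scan$p_value))
  expect_lt(scan$p_value[planted], 0.05)
  expect_gt(scan$log2_ratio[planted], 0)
  expect_gt(scan$n_carriers_a[planted], scan$n_carriers_b[planted])
})

test_that("fisherPresence builds the carrier table and Fisher p", {
  # 5/10 vs 5/10: identical margins -> p = 1
  a <- carrierCohort(5, 10, cohort = "CD", prefix = "a")
  b <- carrierCohort(5, 10, cohort = "HC", prefix = "b")
  res <- fisherPresence("TRAV12-1", "TRAJ6", "CVVNLASGGSYIPTF", a, b)
  expect_equal(res$carriers_a, 5)
  expect_equal(res$carriers_b, 5)
  expect_equal(res$p_value, 1)

  # 8/10 vs 1/10 equals the hypergeometric enumeration oracle
  a2 <- carrierCohort(8, 10, cohort = "CD", prefix = "c")
  b2 <- carrierCohort(1, 10, cohort = "HC", prefix = "d")
  res2 <- fisherPresence("TRAV12-1", "TRAJ6", "CVVNLASGGSYIPTF", a2, b2)
  expect_equal(res2$p_value, fisherOracle(8, 10, 1, 10), tolerance = 1e-12)

  # clonotype absent everywhere
  res3 <- fisherPresence("TRAV41", "TRAJ54", "CAVXXXXNQFYF", a, b)
  expect_equal(res3$carriers_a + res3$carriers_b, 0)
  expect_equal(res3$p_value, 1)
})

test_that("sequencePresenceScan flags a shared planted sequence", {
  a <- carrierCohort(8, 10, cohort = "CD", prefix = "a")
  b <- carrierCohort(0, 10, cohort = "HC", prefix = "b")
  res <- sequencePresenceScan(a, b, v_gene = "TRAV12-1", j_gene = "TRAJ6",
                              cdr3_length = 15)
  expect_equal(nrow(res), 1L)
  expect_equal(res$carriers_a, 8)
  expect_lt(res$q_value, 0.01)
  expect_true(res$q_value >= res$p_value)
})

test_that("BH q-values are monotone in p-value rank with min q >= min p", {
  set.seed(9)
  a <- carrierCohort(4, 6, cohort = "CD", prefix = "a")
  b <- carrierCohort(0, 6, cohort = "HC", prefix = "b")
  scan <- scanFamilies(a, b)
  o <- order(scan$p_value)
  expect_true(all(diff(scan$q_value[o]) >= -1e-12))
  expect_gte(min(scan$q_value), min(scan$p_value))
})

test_that("familySequences pools unique junctions with subject weights", {
  reps <- list(repWithClonotype(10, "s1", cohort = "CD"),
               repWithClonotype(5, "s2", cohort = "CD"),
               repWithClonotype(0, "s3", cohort = "CD"))
  fs <- familySequences(reps, "TRAV12-1", "TRAJ6", 15)
  expect_equal(fs$cdr3_aa, "CVVNLASGGSYIPTF")
  expect_equal(fs$n_subjects, 2L)
})
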