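test_that("matchMotif applies length and fixed-position rules", {
  pat <- caitMotif()
  expect_true(matchMotif("CVVNLASGGSYIPTF", pat))
  expect_true(matchMotif("CVVKRAQGGSYIPTF", pat))   # wildcards at 4, 5, 7
  expect_false(matchMotif("CVVNLTSGGSYIPTF", pat))  # position 6 must be A
  expect_false(matchMotif("CVVNLASGGSYIPT", pat))   # length 14 != 15
  expect_false(matchMotif("CVVNLASGGSYIPTW", pat))  # terminal F is fixed
})

test_that("matchMotif equals a brute-force per-position comparison", {
  bruteForce <- function(s, pat) {
    p <- pat@positions
    if (nchar(s) != length(p)) return(FALSE)
    for (i in seq_along(p)) {
      if (!is.na(p[i]) && substr(s, i, i) != p[i]) return(FALSE)
    }
    TRUE
  }
  set.seed(42)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pats <- list(caitMotif(), motifPattern("CA**S"), motifPattern("C*RDNYGQNFV*F"))
  for (i in seq_len(400)) {
    pat <- pats[[sample(length(pats), 1)]]
    L <- sample(5:20, 1)
    # half the draws share the pattern length so matches actually occur
    if (runif(1) < 0.5) L <- length(pat)
    s <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
    # sometimes mutate towards the pattern to exercise near-matches
    if (runif(1) < 0.5 && nchar(s) == length(pat)) {
      fixed <- which(!is.na(pat@positions))
      keep <- sample(fixed, sample(length(fixed), 1))
      for (k in keep) substr(s, k, k) <- pat@positions[k]
    }
    expect_identical(matchMotif(s, pat), bruteForce(s, pat))
  }
})

test_that("classifyClonotypes applies the default rule set", {
  df <- data.frame(
    chain = c("TRA", "TRA", "TRA", "TRA", "TRB"),
    v_gene = c("TRAV12-1", "TRAV1-2", "TRAV12-1", "TRAV10", "TRBV7-9"),
    j_gene = c("TRAJ6", "TRAJ33", "TRAJ6", "TRAJ18", "TRBJ1-1"),
    cdr3_aa = c("CVVNLASGGSYIPTF",  # CAIT
                "CAVKDSNYQLIW",     # MAIT (any length by default)
                "CVVNLASGGSYIPTW",  # terminal F mutated -> other
                "CVVSDRGSTLGRLYF",  # iNKT genes
                "CASSLAPGATNEKLFF"))
  expect_equal(classifyClonotypes(df),
               c("CAIT", "MAIT", "other", "iNKT", "other"))
})

test_that("classification labels are exclusive and exhaustive", {
  cfg <- smallCfg(seed = 31, n = 2L, clones = 300L,
                  spikes = list(caitSpike(), maitSpike()))
  study <- genCohortStudy(cfg)
  for (rep in study$repertoires) {
    lab <- classifyClonotypes(rep)
    expect_equal(length(lab), nrow(clonotypes(rep)))
    expect_true(all(lab %in% c("CAIT", "MAIT", "iNKT", "other")))
  }
})

test_that("classification is invariant to allele suffixes", {
  with_allele <- data.frame(chain = "TRA", v_gene = "TRAV12-1*01",
                            j_gene = "TRAJ6*02", cdr3_aa = "CVVNLASGGSYIPTF")
  without <- data.frame(chain = "TRA", v_gene = "TRAV12-1",
                        j_gene = "TRAJ6", cdr3_aa = "CVVNLASGGSYIPTF")
  expect_equal(classifyClonotypes(with_allele), classifyClonotypes(without))
})

test_that("the MAIT rule accepts the broad TRAJ set and an optional length", {
  df <- data.frame(chain = "TRA", v_gene = "TRAV1-2",
                   j_gene = c("TRAJ33", "TRAJ20", "TRAJ12", "TRAJ6"),
                   cdr3_aa = c("CAVKDSNYQLIW", "CAVRDNDYKLSF",
                               "CAVMDSSYKLIF", "CAVKDSNYQLIW"))
  expect_equal(classifyClonotypes(df), c("MAIT", "MAIT", "MAIT", "other"))
  narrow <- defaultRules(mait_length = 12)
  df2 <- data.frame(chain = "TRA", v_gene = "TRAV1-2", j_gene = "TRAJ33",
                    cdr3_aa = c("CAVKDSNYQLIW", "CAVKDDSNYQLIW"))
  expect_equal(classifyClonotypes(df2, narrow), c("MAIT", "other"))
})

test_that("classifyCell takes the highest-priority label over all alphas", {
  mixed <- makeCell("BC1",
    alpha = list(c("TRAV12-1", "TRAJ6", "CVVNLASGGSYIPTF"),
                 c("TRAV8-1", "TRAJ4", "CAVSDSGYALNF")))
  expect_equal(classifyCell(mixed), "CAIT")
  mait <- makeCell("BC2",
    alpha = list(c("TRAV1-2", "TRAJ33", "CAVKDSNYQLIW")),
    beta = list(c("TRBV7-9", "TRBJ1-1", "CASSLAPGATNEKLFF")))
  expect_equal(classifyCell(mait), "MAIT")
  beta_only <- makeCell("BC3",
    beta = list(c("TRBV7-9", "TRBJ1-1", "CASSLAPGATNEKLFF")))
  expect_true(is.na(classifyCell(beta_only)))
})

test_that("motifPattern renders back to its string form", {
  pat <- motifPattern("CVV**A*GGSYIPTF")
  expect_equal(as.character(pat), "CVV**A*GGSYIPTF")
  expect_equal(length(pat), 15L)
  expect_error(motifPattern("*****"), "fixed position")
})
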