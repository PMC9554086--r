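.tissueRep <- function(cait_count, total, tissue, subject = "p1") {
  repKind <- if (cait_count > 0) {
    makeRep(v = c("TRAV12-1", "TRAV2"), j = c("TRAJ6", "TRAJ4"),
            cdr3 = c("CVVNLASGGSYIPTF", "CAASFGNEKLTF"),
            count = c(cait_count, total - cait_count),
            sample_id = paste(subject, tissue, sep = "_"),
            subject_id = subject, cohort = "CD", tissue = tissue)
  } else {
    makeRep(v = "TRAV2", j = "TRAJ4", cdr3 = "CAASFGNEKLTF", count = total,
            sample_id = paste(subject, tissue, sep = "_"),
            subject_id = subject, cohort = "CD", tissue = tissue)
  }
  repKind
}

test_that("trackSubject builds the log10 abundance matrix with -6 for absence", {
  reps <- list(.tissueRep(10, 1000, "blood"),
               .tissueRep(1, 1000, "gut"),
               .tissueRep(0, 1000, "lymph_node"))
  m <- trackSubject(reps, "CAIT")
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(unname(m[1, ]), c(-2, -3, -6))
  expect_equal(rownames(m), "TRAV12-1|TRAJ6|CVVNLASGGSYIPTF")
})

test_that("trackSubject rejects mixed subjects and single samples", {
  a <- .tissueRep(10, 1000, "blood", subject = "p1")
  b <- .tissueRep(10, 1000, "gut", subject = "p2")
  expect_error(trackSubject(list(a, b), "CAIT"), "one subject")
  expect_error(trackSubject(list(a), "CAIT"), "at least 2")
})

test_that("trackSubject equals a brute-force per-sample lookup", {
  cfg <- smallCfg(seed = 5, clones = 300L,
                  spikes = list(caitSpike(prevalence = c(CD = 1))))
  mt <- genMultiTissue(cfg, n_subjects = c(CD = 3L))
  subjects <- split(mt$repertoires,
                    vapply(mt$repertoires, subjectID, character(1)))
  ran <- 0L
  for (reps in subjects) {
    m <- trackSubject(reps, "CAIT")
    if (!nrow(m)) next
    ran <- ran + 1L
    for (i in seq_along(reps)) {
      cl <- clonotypes(reps[[i]])
      lab <- classifyClonotypes(reps[[i]])
      for (key in rownames(m)) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        hit <- which(cl$v_gene == parts[1] & cl$j_gene == parts[2] &
                     cl$cdr3_aa == parts[3] & lab == "CAIT")
        expected <- if (length(hit)) log10(cl$frequency[hit]) else -6
        expect_equal(unname(m[key, i]), expected, tolerance = 1e-12)
      }
    }
  }
  expect_gt(ran, 0L)  # at least one carrier subject was exercised
})

test_that("track matrix re-sums to the burden cumulative abundance", {
  reps <- list(.tissueRep(10, 1000, "blood"), .tissueRep(3, 1000, "gut"))
  m <- trackSubject(reps, "CAIT")
  for (i in seq_along(reps)) {
    finite <- m[, i] > -6
    resum <- sum(10^m[finite, i])
    expect_equal(resum, burden(reps[[i]], "CAIT")$cum_abundance,
                 tolerance = 1e-9)
  }
})

test_that("sharingNetwork has one node per (sample, clonotype) and subject publicity", {
  a <- repWithClonotype(10, "s1", cohort = "CD")
  b <- repWithClonotype(20, "s2", cohort = "CD")
  net <- sharingNetwork(list(a, b), "CAIT")
  expect_equal(igraph::vcount(net$graph), 2L)
  expect_equal(net$publicity$n_subjects, 2L)
  expect_equal(net$publicity$clonotype, "TRAV12-1|TRAJ6|CVVNLASGGSYIPTF")

  empty <- sharingNetwork(list(repWithClonotype(0, "s3")), "CAIT")
  expect_equal(igraph::vcount(empty$graph), 0L)
  expect_equal(nrow(empty$publicity), 0L)
})

test_that("sharingNetwork node count equals the classifier hit count", {
  cfg <- smallCfg(seed = 9, n = 8L, clones = 300L)
  study <- genCohortStudy(cfg)
  net <- sharingNetwork(study$repertoires, "CAIT")
  hits <- sum(vapply(study$repertoires, function(r)
    sum(classifyClonotypes(r) == "CAIT"), numeric(1)))
  expect_equal(igraph::vcount(net$graph), hits)
})

test_that("publicity is invariant to per-sample clone-size scaling", {
  a <- repWithClonotype(10, "s1", cohort = "CD")
  scaled <- clonotypes(a)
  scaled$count <- scaled$count * 10
  a10 <- Repertoire(scaled, sample_id = "s1", cohort = "CD")
  b <- repWithClonotype(20, "s2", cohort = "CD")
  expect_equal(sharingNetwork(list(a, b), "CAIT")$publicity,
               sharingNetwork(list(a10, b), "CAIT")$publicity)
})

test_that("the sharing network serializes to GraphML", {
  net <- sharingNetwork(list(repWithClonotype(10, "s1", cohort = "CD")), "CAIT")
  path <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("betaPrivacy counts carrying subjects by exact match", {
  beta <- function(cdr3, sample_id, subject_id = sample_id) {
    makeRep(v = c("TRBV7-9", "TRBV2"), j = c("TRBJ1-1", "TRBJ2-1"),
            cdr3 = c(cdr3, "CASSEGQGYEQYF"), count = c(5, 95),
            chain = c("TRB", "TRB"), sample_id = sample_id,
            subject_id = subject_id)
  }
  bulk <- list(beta("CASSLAPGATNEKLFF", "b1"),
               beta("CASSLAPGATNEKLFF", "b2"),
               beta("CASSLAPGATNEKLFF", "b3a", "b3"),
               beta("CASSLAPGATNEKLFF", "b3b", "b3"),  # same subject twice
               beta("CASSDIFFERENTF", "b4"))
  chains <- data.frame(v_gene = c("TRBV7-9", "TRBV7-9"),
                       j_gene = c("TRBJ1-1", "TRBJ1-1"),
                       cdr3_aa = c("CASSLAPGATNEKLFF", "CASSNOVELNTEAFF"))
  res <- betaPrivacy(chains, bulk)
  expect_equal(res$n_subjects, c(3L, 0L))
})

test_that("betaPrivacy matches a brute-force scan on random chains", {
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- function(n) vapply(seq_len(n), function(i)
    paste0("CASS", paste(sample(aa, 8, replace = TRUE), collapse = ""), "F"),
    character(1))
  pool <- rnd(12)
  bulk <- lapply(1:6, function(i) {
    picks <- sample(pool, 4)
    makeRep(v = rep("TRBV7-9", 4), j = rep("TRBJ1-1", 4), cdr3 = picks,
            count = sample(5:50, 4), chain = rep("TRB", 4),
            sample_id = paste0("b", i))
  })
  query <- data.frame(v_gene = "TRBV7-9", j_gene = "TRBJ1-1",
                      cdr3_aa = pool)
  res <- betaPrivacy(query, bulk)
  oracle <- vapply(pool, function(s) {
    sum(vapply(bulk, function(r) s %in% clonotypes(r)$cdr3_aa, logical(1)))
  }, numeric(1))
  expect_equal(res$n_subjects, unname(as.integer(oracle)))
})
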