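# Shared fixtures and independent oracles used across the test suite.

# Build a repertoire from parallel vectors; counts default to equal.
makeRep <- function(v, j, cdr3, count = rep(1, length(v)),
                    chain = rep("TRA", length(v)),
                    sample_id = "s1", subject_id = sample_id,
                    cohort = "HC", tissue = "blood", fraction = "bulk") {
  Repertoire(data.frame(chain = chain, v_gene = v, j_gene = j,
                        cdr3_aa = cdr3, count = count),
             sample_id = sample_id, subject_id = subject_id,
             cohort = cohort, tissue = tissue, fraction = fraction)
}

# A background-only repertoire with one optional planted clonotype.
# `planted_count` of 0 omits the clonotype.
repWithClonotype <- function(planted_count, sample_id, cohort = "HC",
                             total = 1000) {
  v <- c("TRAV2", "TRAV3", "TRAV4")
  j <- c("TRAJ4", "TRAJ9", "TRAJ10")
  cdr3 <- c("CAASFGNEKLTF", "CAGGGSQGNLIF", "CALSEAGGTSYGKLTF")
  count <- c(total * 0.5, total * 0.3, total * 0.2 - planted_count)
  if (planted_count > 0) {
    v <- c(v, "TRAV12-1"); j <- c(j, "TRAJ6")
    cdr3 <- c(cdr3, "CVVNLASGGSYIPTF"); count <- c(count, planted_count)
  }
  makeRep(v, j, cdr3, count, sample_id = sample_id, cohort = cohort)
}

# cohort of n tiny repertoires, the first `carriers` of which contain the
# canonical CAIT clonotype
carrierCohort <- function(carriers, n, cohort = "HC", prefix = "s") {
  lapply(seq_len(n), function(i)
    repWithClonotype(if (i <= carriers) 10 else 0,
                     sample_id = paste0(prefix, i), cohort = cohort))
}

# Independent two-sided Fisher exact p: direct hypergeometric enumeration
# over all tables with the observed margins, summing the probabilities of
# tables no more likely than the observed one.
fisherOracle <- function(a, n_a, b, n_b) {
  k <- a + b
  support <- max(0, k - n_b):min(k, n_a)
  pr <- dhyper(support, n_a, n_b, k)
  sum(pr[pr <= dhyper(a, n_a, n_b, k) * (1 + 1e-7)])
}

# Independent exact two-sided Mann-Whitney p by full enumeration of the
# rank-sum distribution over all choose(n1+n2, n1) group assignments.
mwEnumOracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sums <- combn(length(r), n1, function(i) sum(r[i]))
  min(1, 2 * min(mean(sums <= w_obs + 1e-9), mean(sums >= w_obs - 1e-9)))
}

# Hand-rolled Benjamini-Hochberg adjustment.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q[q > 1] <- 1
  out <- numeric(n)
  out[o] <- q
  out
}

# Small, fast simulation config for unit tests.
smallCfg <- function(seed, n = 20L, clones = 400L, ...) {
  simConfig(seed = seed, n_per_cohort = c(CD = n, HC = n),
            clones_per_repertoire = clones, ...)
}

# Minimal CellRecord constructor for paired-chain tests.
makeCell <- function(barcode, alpha = NULL, beta = NULL, markers = numeric(0)) {
  empty <- data.frame(v_gene = character(), j_gene = character(),
                      cdr3_aa = character(), umis = numeric())
  toDF <- function(x) {
    if (is.null(x)) return(empty)
    df <- as.data.frame(do.call(rbind, lapply(x, function(ch)
      c(ch[1], ch[2], ch[3], if (length(ch) > 3) ch[4] else NA))),
      stringsAsFactors = FALSE)
    names(df) <- c("v_gene", "j_gene", "cdr3_aa", "umis")
    df$umis <- as.numeric(df$umis)
    df
  }
  new("CellRecord", barcode = barcode, alpha = toDF(alpha), beta = toDF(beta),
      markers = markers)
}

caitCell <- function(barcode, beta_v = "TRBV7-9", markers = numeric(0),
                     beta_cdr3 = "CASSLAPGATNEKLFF") {
  makeCell(barcode,
           alpha = list(c("TRAV12-1", "TRAJ6", "CVVNLASGGSYIPTF")),
           beta = list(c(beta_v, "TRBJ1-1", beta_cdr3)),
           markers = markers)
}
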