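# Synthetic repertoire generator: background repertoires with realistic
# V/J usage, CDR3 length spectra and heavy-tailed (Zipf) clone sizes, plus
# planted semi-invariant clonotype families whose carrier prevalence and
# cumulative abundance differ by cohort.

.defaultVUsage <- function() {
  genes <- c("TRAV1-1", "TRAV1-2", "TRAV2", "TRAV3", "TRAV4", "TRAV5",
             "TRAV6", "TRAV8-1", "TRAV8-2", "TRAV8-3", "TRAV8-6", "TRAV9-2",
             "TRAV10", "TRAV12-1", "TRAV12-2", "TRAV12-3", "TRAV13-1",
             "TRAV13-2", "TRAV14", "TRAV16", "TRAV17", "TRAV19", "TRAV20",
             "TRAV21", "TRAV22", "TRAV23", "TRAV24", "TRAV25", "TRAV26-1",
             "TRAV27", "TRAV29", "TRAV35", "TRAV38-1", "TRAV38-2", "TRAV41")
  w <- 0.9^seq_along(genes)
  names(w) <- genes
  w["TRAV1-2"]  <- 0.045
  w["TRAV10"]   <- 0.020
  w["TRAV12-1"] <- 0.020
  w / sum(w)
}

.defaultJUsage <- function() {
  genes <- c("TRAJ4", "TRAJ6", "TRAJ9", "TRAJ10", "TRAJ12", "TRAJ13",
             "TRAJ15", "TRAJ16", "TRAJ18", "TRAJ20", "TRAJ23", "TRAJ27",
             "TRAJ28", "TRAJ29", "TRAJ30", "TRAJ31", "TRAJ33", "TRAJ34",
             "TRAJ37", "TRAJ39", "TRAJ40", "TRAJ42", "TRAJ43", "TRAJ45",
             "TRAJ47", "TRAJ48", "TRAJ49", "TRAJ52", "TRAJ53", "TRAJ54")
  w <- rep(1, length(genes))
  names(w) <- genes
  w["TRAJ6"]  <- 0.6
  w["TRAJ33"] <- 1.6
  w["TRAJ18"] <- 0.9
  w / sum(w)
}

.defaultLengthDist <- function() {
  setNames(c(0.01, 0.03, 0.06, 0.10, 0.14, 0.16, 0.15, 0.12,
             0.09, 0.06, 0.04, 0.02, 0.02), as.character(8:20))
}

.defaultAADist <- function() {
  w <- rep(1, 20)
  names(w) <- AA_ALPHABET
  # mildly enriched small/flexible residues, as in real junctions
  w[c("G", "S", "A", "L", "N", "D")] <- c(2.0, 1.8, 1.5, 1.4, 1.3, 1.2)
  w / sum(w)
}

#' Generate CAIT-motif CDR3 junctions
#'
#' Draws 15-mer junctions matching the CAIT motif `CVV**A*GGSYIPTF`:
#' positions 1-3 and 8-15 are fixed (`CVV` / `GGSYIPTF`), position 6 is
#' fixed `A`, and positions 4, 5 and 7 are drawn from per-position residue
#' distributions. By default position 7 emits `S` with probability 0.6
#' (the motif position described as "mostly S") and positions 4 and 5 are
#' the most variable (modal residue probability 0.3).
#'
#' @param n number of junctions.
#' @param pos4,pos5,pos7 named probability vectors for the variable
#'   positions.
#' @return character vector of junctions; every draw matches [caitMotif()].
#' @export
genCaitCDR3 <- function(n,
                        pos4 = c(N = 0.30, K = 0.15, R = 0.15, L = 0.10,
                                 S = 0.10, G = 0.08, D = 0.07, A = 0.05),
                        pos5 = c(L = 0.30, R = 0.15, K = 0.12, A = 0.12,
                                 S = 0.11, G = 0.10, T = 0.10),
                        pos7 = c(S = 0.60, A = 0.12, T = 0.10, G = 0.10,
                                 N = 0.08)) {
  for (d in list(pos4, pos5, pos7))
    if (abs(sum(d) - 1) > 1e-9) stop("position distributions must sum to 1")
  p4 <- sample(names(pos4), n, replace = TRUE, prob = pos4)
  p5 <- sample(names(pos5), n, replace = TRUE, prob = pos5)
  p7 <- sample(names(pos7), n, replace = TRUE, prob = pos7)
  paste0("CVV", p4, p5, "A", p7, "GGSYIPTF")
}

#' Generate MAIT-like CDR3 junctions
#'
#' 12-mer junctions of the canonical MAIT alpha family
#' (`CAV.DSNYQLIW`, variable position 4).
#'
#' @param n number of junctions.
#' @param pos4 named probability vector for position 4.
#' @return character vector of junctions.
#' @export
genMaitCDR3 <- function(n, pos4 = c(M = 0.30, K = 0.20, R = 0.20,
                                    T = 0.15, S = 0.15)) {
  if (abs(sum(pos4) - 1) > 1e-9) stop("pos4 must sum to 1")
  paste0("CAV", sample(names(pos4), n, replace = TRUE, prob = pos4),
         "DSNYQLIW")
}

#' Default planted spikes
#'
#' `caitSpike()`: the CAIT family (TRAV12-1/TRAJ6, motif junctions from
#' [genCaitCDR3()]) planted with carrier prevalence 0.45 in CD and 0.05 in
#' controls, cumulative abundance log-normal with median 2.5%.
#' `maitSpike()`: a MAIT family (TRAV1-2/TRAJ33, [genMaitCDR3()]) with high
#' prevalence in every cohort but lower abundance in CD, mirroring the
#' depletion of MAIT clonotypes in CD blood.
#'
#' @param prevalence named per-cohort carrier probabilities.
#' @param abundance_meanlog named (or scalar) meanlog of the log-normal
#'   cumulative-abundance target.
#' @param abundance_sdlog sdlog of the same distribution.
#' @param n_clonotypes_lambda a carrier receives `1 + rpois(lambda)`
#'   distinct planted clonotypes.
#' @return A [SpikeSpec-class] object.
#' @export
caitSpike <- function(prevalence = c(CD = 0.45, HC = 0.05, UC = 0.05, CRC = 0.05),
                      abundance_meanlog = log(0.025),
                      abundance_sdlog = 1.0,
                      n_clonotypes_lambda = 2) {
  new("SpikeSpec", label = "CAIT", v_gene = "TRAV12-1", j_gene = "TRAJ6",
      cdr3_fun = genCaitCDR3, prevalence = prevalence,
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      n_clonotypes_lambda = n_clonotypes_lambda)
}

#' @rdname caitSpike
#' @export
maitSpike <- function(prevalence = c(CD = 0.85, HC = 0.95, UC = 0.95, CRC = 0.95),
                      abundance_meanlog = c(CD = log(0.006), HC = log(0.025),
                                            UC = log(0.025), CRC = log(0.025)),
                      abundance_sdlog = 0.8,
                      n_clonotypes_lambda = 1.5) {
  new("SpikeSpec", label = "MAIT", v_gene = "TRAV1-2", j_gene = "TRAJ33",
      cdr3_fun = genMaitCDR3, prevalence = prevalence,
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      n_clonotypes_lambda = n_clonotypes_lambda)
}

#' Synthetic study configuration
#'
#' Builds a validated [SimConfig-class]. Defaults emulate the structure of a
#' blood TCR-alpha case/control study: 100 CD and 100 healthy-control
#' samples of 2,000 clones each, Zipf clone-size exponent 1.5, a CAIT spike
#' planted at prevalence 0.45 (CD) vs 0.05 (controls) with log-normal
#' cumulative abundance (median 2.5%).
#'
#' @param seed integer base seed; every generator output is a deterministic
#'   function of (config, seed).
#' @param n_per_cohort named integer vector of samples per cohort.
#' @param clones_per_repertoire clones per sample.
#' @param zipf_exponent clone-size power-law exponent (> 1).
#' @param count_scale depth multiplier on the Zipf counts (smallest clone
#'   receives about this many counts).
#' @param v_usage,j_usage,cdr3_length_dist,background_aa_dist background
#'   distributions (named probability vectors).
#' @param spikes list of [SpikeSpec-class] objects; default `caitSpike()`.
#' @param tissue_sharing probability that a planted clonotype of a
#'   multi-tissue subject is shared into each non-blood tissue.
#' @param paired named list of paired single-cell scenario parameters;
#'   entries override the defaults (`n_cait_clonotypes = 200`,
#'   `expansion_lambda = 0.5`, `trbv_usage` with TRBV7-9 at 0.45,
#'   `n_mait_cells = 100`, `n_trav12_other = 80`, `n_background = 120`,
#'   `p_klrb1 = c(CAIT = 0.9, MAIT = 0.9, other = 0.2)`,
#'   `p_cd8 = c(CAIT = 0.8, MAIT = 0.85, other = 0.5)`, `expr_lambda = 2`).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1L,
                      n_per_cohort = c(CD = 100L, HC = 100L),
                      clones_per_repertoire = 2000L,
                      zipf_exponent = 1.5,
                      count_scale = 10,
                      v_usage = .defaultVUsage(),
                      j_usage = .defaultJUsage(),
                      cdr3_length_dist = .defaultLengthDist(),
                      background_aa_dist = .defaultAADist(),
                      spikes = list(caitSpike()),
                      tissue_sharing = 0.5,
                      paired = list()) {
  paired_defaults <- list(
    n_cait_clonotypes = 200L,
    expansion_lambda  = 0.5,
    trbv_usage = c("TRBV7-9" = 0.45, "TRBV2" = 0.08, "TRBV20-1" = 0.08,
                   "TRBV28" = 0.07, "TRBV5-1" = 0.07, "TRBV6-5" = 0.06,
                   "TRBV9" = 0.05, "TRBV19" = 0.05, "TRBV4-1" = 0.05,
                   "TRBV12-3" = 0.04),
    trbj_genes = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-3", "TRBJ2-7"),
    n_mait_cells   = 100L,
    n_trav12_other = 80L,
    n_background   = 120L,
    p_klrb1 = c(CAIT = 0.9, MAIT = 0.9, other = 0.2),
    p_cd8   = c(CAIT = 0.8, MAIT = 0.85, other = 0.5),
    expr_lambda = 2
  )
  unknown <- setdiff(names(paired), names(paired_defaults))
  if (length(unknown))
    stop("unknown paired config entries: ", paste(unknown, collapse = ", "))
  paired_defaults[names(paired)] <- paired
  new("SimConfig",
      seed = as.integer(seed),
      n_per_cohort = setNames(as.integer(n_per_cohort), names(n_per_cohort)),
      clones_per_repertoire = as.integer(clones_per_repertoire),
      zipf_exponent = zipf_exponent, count_scale = count_scale,
      v_usage = v_usage, j_usage = j_usage,
      cdr3_length_dist = cdr3_length_dist,
      background_aa_dist = background_aa_dist,
      spikes = spikes, tissue_sharing = tissue_sharing,
      paired = paired_defaults)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d; %s; %d clones/repertoire (Zipf %.2f); %d spike(s): %s\n",
              object@seed,
              paste(sprintf("%s=%d", names(object@n_per_cohort),
                            object@n_per_cohort), collapse = ", "),
              object@clones_per_repertoire, object@zipf_exponent,
              length(object@spikes),
              paste(vapply(object@spikes, function(s) s@label, character(1)),
                    collapse = ", ")))
  invisible(NULL)
})

# random background junctions: conserved C...F anchors, interior positions
# i.i.d. from the residue distribution
.randomJunctions <- function(n, lengths, aa_dist) {
  out <- character(n)
  for (L in unique(lengths)) {
    idx <- which(lengths == L)
    inner <- matrix(sample(names(aa_dist), length(idx) * (L - 2L),
                           replace = TRUE, prob = aa_dist),
                    nrow = length(idx))
    out[idx] <- paste0("C", do.call(paste0, as.data.frame(inner)), "F")
  }
  out
}

.spikeParam <- function(x, cohort) {
  if (!is.null(names(x)) && cohort %in% names(x)) unname(x[cohort])
  else unname(x[1])
}

# draw the planted clonotype set of one spike for one carrier: distinct
# junctions plus a cumulative-abundance target (log-normal, capped)
.drawSpikeSet <- function(spike, cohort, cap = 0.5) {
  n_sp <- 1L + rpois(1L, spike@n_clonotypes_lambda)
  cdr3 <- unique(spike@cdr3_fun(4L * n_sp))
  cdr3 <- cdr3[seq_len(min(n_sp, length(cdr3)))]
  meanlog <- .spikeParam(spike@abundance_meanlog, cohort)
  target <- rlnorm(1L, meanlog, spike@abundance_sdlog)
  for (i in seq_len(20L)) {
    if (target < cap) break
    target <- rlnorm(1L, meanlog, spike@abundance_sdlog)
  }
  target <- min(target, cap)
  list(clonotypes = data.frame(v_gene = spike@v_gene, j_gene = spike@j_gene,
                               cdr3_aa = cdr3, stringsAsFactors = FALSE),
       target = target)
}

# assemble one repertoire from the background model plus pre-drawn spike
# sets; background counts are renormalized so each spike's cumulative
# frequency matches its target within 1e-6
.assembleRepertoire <- function(cfg, spike_sets, sample_id, subject_id,
                                cohort, tissue, fraction) {
  n <- cfg@clones_per_repertoire
  v <- sample(names(cfg@v_usage), n, replace = TRUE, prob = cfg@v_usage)
  j <- sample(names(cfg@j_usage), n, replace = TRUE, prob = cfg@j_usage)
  lens <- as.integer(sample(names(cfg@cdr3_length_dist), n, replace = TRUE,
                            prob = cfg@cdr3_length_dist))
  cdr3 <- .randomJunctions(n, lens, cfg@background_aa_dist)
  counts <- round(cfg@count_scale * (n / seq_len(n))^cfg@zipf_exponent)
  bg <- data.table::data.table(v_gene = v, j_gene = j, cdr3_aa = cdr3,
                               count = counts)
  bg <- bg[, .(count = sum(count)), by = .(v_gene, j_gene, cdr3_aa)]
  spike_sets <- Filter(Negate(is.null), spike_sets)
  if (length(spike_sets)) {
    spike_keys <- unlist(lapply(spike_sets, function(s)
      .clonotypeKey(s$clonotypes$v_gene, s$clonotypes$j_gene,
                    s$clonotypes$cdr3_aa)))
    bg <- bg[!.clonotypeKey(v_gene, j_gene, cdr3_aa) %in% spike_keys]
    targets <- vapply(spike_sets, `[[`, numeric(1), "target")
    if (sum(targets) >= 0.9)
      stop("combined spike abundance targets are infeasible (>= 0.9)")
    B <- sum(bg$count)
    spiked <- lapply(seq_along(spike_sets), function(k) {
      s <- spike_sets[[k]]
      n_sp <- nrow(s$clonotypes)
      s_tot <- max(round(targets[k] * B / (1 - sum(targets))), n_sp)
      w <- rexp(n_sp) + 0.1
      cnt <- floor(s_tot * w / sum(w))
      cnt[cnt < 1L] <- 1L
      cnt[which.max(cnt)] <- cnt[which.max(cnt)] + (s_tot - sum(cnt))
      data.table::data.table(s$clonotypes, count = cnt)
    })
    bg <- data.table::rbindlist(c(list(bg), spiked))
  }
  Repertoire(data.frame(chain = "TRA", bg), sample_id = sample_id,
             subject_id = subject_id, cohort = cohort, tissue = tissue,
             fraction = fraction)
}

#' Generate one synthetic repertoire
#'
#' Draws a background repertoire (Zipf clone sizes, i.i.d. junction model
#' with conserved anchors) and, independently for each configured spike
#' with the cohort's carrier probability, plants a set of semi-invariant
#' clonotypes whose cumulative frequency matches a log-normal target within
#' 1e-6. Uses the current RNG state; see [genCohortStudy()] for seeded
#' whole-study generation.
#'
#' @param cfg a [SimConfig-class] object.
#' @param cohort cohort label (decides spike prevalence and abundance).
#' @param sample_id,subject_id,tissue,fraction sample metadata.
#' @return A [Repertoire-class] object.
#' @export
genRepertoire <- function(cfg, cohort, sample_id = "S1",
                          subject_id = sample_id, tissue = "blood",
                          fraction = "bulk") {
  spike_sets <- lapply(cfg@spikes, function(spike) {
    if (runif(1) < .spikeParam(spike@prevalence, cohort))
      .drawSpikeSet(spike, cohort)
    else NULL
  })
  .assembleRepertoire(cfg, spike_sets, sample_id, subject_id, cohort,
                      tissue, fraction)
}

#' Generate a whole cohort study
#'
#' Seeds the RNG from the config and generates every sample of every cohort
#' in `cfg@n_per_cohort` (blood, bulk fraction). Optionally writes one AIRR
#' TSV per sample plus a `metadata.tsv` to `dir`; identical (config, seed)
#' pairs produce byte-identical files.
#'
#' @param cfg a [SimConfig-class] object.
#' @param dir optional output directory.
#' @return list with `repertoires` (named list of [Repertoire-class]) and
#'   `metadata` (data.frame).
#' @export
genCohortStudy <- function(cfg, dir = NULL) {
  set.seed(cfg@seed)
  reps <- list()
  for (ch in names(cfg@n_per_cohort)) {
    for (i in seq_len(cfg@n_per_cohort[[ch]])) {
      sid <- sprintf("%s_%03d", ch, i)
      reps[[sid]] <- genRepertoire(cfg, cohort = ch, sample_id = sid,
                                   subject_id = sid)
    }
  }
  metadata <- data.frame(
    sample_id  = vapply(reps, sampleID, character(1)),
    subject_id = vapply(reps, subjectID, character(1)),
    cohort     = vapply(reps, cohort, character(1)),
    tissue     = vapply(reps, tissue, character(1)),
    fraction   = vapply(reps, cellFraction, character(1)),
    row.names  = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(reps)) writeAIRR(reps[[sid]], file.path(dir, paste0(sid, ".tsv")))
    data.table::fwrite(metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  }
  list(repertoires = reps, metadata = metadata)
}

#' Generate multi-tissue subjects
#'
#' For each subject, generates matched blood, gut and lymph-node
#' repertoires. Spike carrier status and the planted clonotype set are
#' drawn once per subject; the full set is placed in blood, and each
#' planted clonotype is shared into each non-blood tissue with probability
#' `cfg@tissue_sharing` (each tissue draws its own abundance target).
#'
#' @param cfg a [SimConfig-class] object.
#' @param n_subjects named integer vector, subjects per cohort.
#' @param dir optional output directory (AIRR files + metadata.tsv).
#' @return list with `repertoires` (named list) and `metadata` (data.frame).
#' @export
genMultiTissue <- function(cfg, n_subjects = c(CD = 6L, UC = 6L, CRC = 6L),
                           dir = NULL) {
  set.seed(cfg@seed + 1L)
  tissues <- .TISSUES
  reps <- list()
  for (ch in names(n_subjects)) {
    for (i in seq_len(n_subjects[[ch]])) {
      subject <- sprintf("%s_subj%02d", ch, i)
      carrier_sets <- lapply(cfg@spikes, function(spike) {
        if (runif(1) < .spikeParam(spike@prevalence, ch))
          .drawSpikeSet(spike, ch)
        else NULL
      })
      for (tis in tissues) {
        sets <- lapply(carrier_sets, function(s) {
          if (is.null(s)) return(NULL)
          keep <- if (tis == "blood") rep(TRUE, nrow(s$clonotypes))
                  else runif(nrow(s$clonotypes)) < cfg@tissue_sharing
          if (!any(keep)) return(NULL)
          target <- if (tis == "blood") s$target
                    else min(s$target * rlnorm(1, 0, 0.5), 0.5)
          list(clonotypes = s$clonotypes[keep, , drop = FALSE],
               target = target)
        })
        sid <- paste(subject, tis, sep = "_")
        reps[[sid]] <- .assembleRepertoire(cfg, sets, sid, subject, ch,
                                           tis, "bulk")
      }
    }
  }
  metadata <- data.frame(
    sample_id  = vapply(reps, sampleID, character(1)),
    subject_id = vapply(reps, subjectID, character(1)),
    cohort     = vapply(reps, cohort, character(1)),
    tissue     = vapply(reps, tissue, character(1)),
    fraction   = vapply(reps, cellFraction, character(1)),
    row.names  = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(reps)) writeAIRR(reps[[sid]], file.path(dir, paste0(sid, ".tsv")))
    data.table::fwrite(metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  }
  list(repertoires = reps, metadata = metadata)
}

.randomBetaCDR3 <- function(n, aa_dist) {
  paste0("CASS",
         vapply(seq_len(n), function(i)
           paste(sample(names(aa_dist), 8L, replace = TRUE, prob = aa_dist),
                 collapse = ""), character(1)),
         "F")
}

#' Generate a paired single-cell scenario
#'
#' Emits a 10x-style filtered-contig table plus a per-barcode marker table
#' with planted structure: CAIT clonotypes (TRAV12-1/TRAJ6 motif alphas)
#' paired with beta chains drawn from a configured TRBV usage (TRBV7-9
#' weight 0.45 by default), clonal expansion, MAIT cells, non-CAIT
#' TRAV12-1+ cells and background cells, and KLRB1/CD8A expression with
#' class-specific positive rates.
#'
#' @param cfg a [SimConfig-class] object (see the `paired` argument of
#'   [simConfig()]).
#' @param dir optional output directory (`contigs.csv`, `markers.tsv`).
#' @return list with `contigs` and `markers` data.frames, `cells`
#'   (list of [CellRecord-class]) and `truth` (the planted parameters and
#'   realized per-class cell counts).
#' @export
genPairedCells <- function(cfg, dir = NULL) {
  set.seed(cfg@seed + 2L)
  p <- cfg@paired
  trbv <- p$trbv_usage
  if (abs(sum(trbv) - 1) > 1e-9) stop("paired trbv_usage must sum to 1")
  aa <- cfg@background_aa_dist

  contig_rows <- list()
  class_of <- character(0)
  cell_i <- 0L
  addCell <- function(cls, alpha, beta) {
    cell_i <<- cell_i + 1L
    bc <- sprintf("CELL%05d-1", cell_i)
    rows <- data.frame(barcode = bc,
                       chain = c(rep("TRA", nrow(alpha)), rep("TRB", nrow(beta))),
                       v_gene = c(alpha$v, beta$v), j_gene = c(alpha$j, beta$j),
                       cdr3 = c(alpha$cdr3, beta$cdr3),
                       umis = c(alpha$umis, beta$umis))
    contig_rows[[length(contig_rows) + 1L]] <<- rows
    class_of[cell_i] <<- cls
  }

  # CAIT clonotypes with clonal expansion; beta V usage is the planted law
  n_clono <- p$n_cait_clonotypes
  beta_v <- sample(names(trbv), n_clono, replace = TRUE, prob = trbv)
  for (k in seq_len(n_clono)) {
    alpha <- data.frame(v = "TRAV12-1", j = "TRAJ6", cdr3 = genCaitCDR3(1),
                        umis = 1 + rpois(1, 10))
    beta <- data.frame(v = beta_v[k], j = sample(p$trbj_genes, 1),
                       cdr3 = .randomBetaCDR3(1, aa), umis = 1 + rpois(1, 10))
    for (rep_i in seq_len(1L + rpois(1, p$expansion_lambda)))
      addCell("CAIT", alpha, beta)
  }
  for (k in seq_len(p$n_mait_cells)) {
    alpha <- data.frame(v = "TRAV1-2", j = "TRAJ33", cdr3 = genMaitCDR3(1),
                        umis = 1 + rpois(1, 10))
    beta <- data.frame(v = sample(names(trbv), 1), j = sample(p$trbj_genes, 1),
                       cdr3 = .randomBetaCDR3(1, aa), umis = 1 + rpois(1, 10))
    addCell("MAIT", alpha, beta)
  }
  for (k in seq_len(p$n_trav12_other)) {
    # TRAV12-1+ cells whose junction does not carry the CAIT motif
    alpha <- data.frame(v = "TRAV12-1",
                        j = sample(setdiff(names(cfg@j_usage), "TRAJ6"), 1),
                        cdr3 = .randomJunctions(1, sample(12:16, 1), aa),
                        umis = 1 + rpois(1, 10))
    beta <- data.frame(v = sample(names(trbv), 1), j = sample(p$trbj_genes, 1),
                       cdr3 = .randomBetaCDR3(1, aa), umis = 1 + rpois(1, 10))
    addCell("other", alpha, beta)
  }
  for (k in seq_len(p$n_background)) {
    alpha <- data.frame(v = sample(setdiff(names(cfg@v_usage),
                                           c("TRAV12-1", "TRAV1-2", "TRAV10")), 1),
                        j = sample(names(cfg@j_usage), 1),
                        cdr3 = .randomJunctions(1, sample(10:17, 1), aa),
                        umis = 1 + rpois(1, 10))
    beta <- data.frame(v = sample(names(trbv), 1), j = sample(p$trbj_genes, 1),
                       cdr3 = .randomBetaCDR3(1, aa), umis = 1 + rpois(1, 10))
    addCell("other", alpha, beta)
  }

  contigs <- data.table::setDF(data.table::rbindlist(contig_rows))
  expr <- function(pos_prob) {
    pos <- runif(cell_i) < pos_prob[ifelse(class_of %in% names(pos_prob),
                                           class_of, "other")]
    ifelse(pos, 1 + rpois(cell_i, p$expr_lambda), 0)
  }
  barcodes <- sprintf("CELL%05d-1", seq_len(cell_i))
  markers <- data.frame(barcode = barcodes,
                        KLRB1 = expr(p$p_klrb1), CD8A = expr(p$p_cd8))
  truth <- list(trbv_usage = trbv, p_klrb1 = p$p_klrb1, p_cd8 = p$p_cd8,
                n_cells = table(class_of))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(contigs, file.path(dir, "contigs.csv"))
    data.table::fwrite(markers, file.path(dir, "markers.tsv"), sep = "\t")
  }
  list(contigs = contigs, markers = markers,
       cells = asCellRecords(contigs, markers), truth = truth)
}
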