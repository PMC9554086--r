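---
title: "Discovering semi-invariant T cell clonotypes with CAITscan"
author: "CAITscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering semi-invariant T cell clonotypes with CAITscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CAITscan)
```

## The problem

Most T cells carry a practically unique T-cell receptor (TCR), so
disease-associated clonotypes shared across patients are rare and hard to
find: any individual sequence is present in only a handful of repertoires.
Semi-invariant T cell populations are the exception. MAIT cells
(TRAV1-2 with TRAJ33/20/12) and iNKT cells (TRAV10 with TRAJ18) use nearly
fixed alpha chains, which makes them detectable across individuals from
bulk TCR sequencing alone. CAITscan implements a pipeline for discovering
and quantifying such populations from cohort-level repertoire data, built
around the Crohn-associated invariant T (CAIT) clonotypes: TRAV12-1/TRAJ6
alpha chains with the 15-residue junction motif `CVV**A*GGSYIPTF`
(wildcards at positions 4, 5 and 7), enriched in the blood of Crohn's
disease (CD) patients and mirrored by a depletion of the canonical
12-residue TRAV1-2/TRAJ33 MAIT family.

The pipeline has five stages, each exposed as ordinary functions:

1. **Family scan** (`scanFamilies`): clonotypes are grouped into families
   by (V gene, J gene, CDR3 amino-acid length). Per-sample within-repertoire
   family frequencies are compared between two cohorts with a two-sided
   Mann-Whitney U test (samples lacking a family contribute frequency 0),
   with Benjamini-Hochberg (BH) adjustment across all observed families.
2. **Per-sequence confirmation** (`sequencePresenceScan`): each distinct
   junction of a candidate family is tested with a two-sided Fisher exact
   test on the 2×2 carriers table (presence = count ≥ 1 in a sample).
3. **Motif derivation** (`buildPFM`, `deriveConsensus`): the unique
   junctions of the candidate family are stacked into a position frequency
   matrix; positions whose modal residue reaches a conservation threshold
   become fixed, the rest become wildcards.
4. **Classification and burden** (`classifyClonotypes`, `burden`): a
   rule-based classifier labels clonotypes (and single cells) as CAIT,
   MAIT, iNKT or other; per-individual burden is the number of labelled
   clonotypes and their cumulative relative abundance.
5. **Tracking and pairing** (`trackSubject`, `sharingNetwork`,
   `trbvUsage`, `fractionAmongV`): cross-tissue presence within subjects,
   subject-level publicity of clonotypes, beta-chain pairing bias and
   marker-gated cell fractions in paired single-cell data.

## Statistical choices

**Family test.** The scan uses the Mann-Whitney U test on per-sample
frequencies rather than a count-based test, because repertoire depth varies
by orders of magnitude between samples and the quantity of biological
interest is the within-repertoire fraction. Cohort-level family frequency
is summarized as the mean of per-sample frequencies (absent = 0), so large
repertoires cannot dominate. Families are ranked by BH-adjusted p-value,
with ties broken by larger absolute log2 mean-frequency ratio and then
lexicographically by family key, making the ranking deterministic. The
log2 ratio uses a 1e-12 pseudocount so that families private to one cohort
keep a finite, sortable effect size.

**Exactness.** `compareCohorts` uses the exact U distribution when both
groups are smaller than 50 and tie-free; with ties and at most 20 total
observations it enumerates all group relabelings on midranks (two-sided
p = min(1, 2·min(P(W ≤ w), P(W ≥ w)))); otherwise it falls back to the
normal approximation with midranks, tie correction and continuity
correction. A fully tied comparison is reported as p = 1. The family scan
always uses the approximation: cohorts there are large and zero-inflation
makes ties ubiquitous. Fisher's odds ratio is the conditional
maximum-likelihood estimate reported by `stats::fisher.test`. Both
primitives are validated in the test suite against independent brute-force
enumeration (hypergeometric sums for all 2×2 tables with margins up to 15;
full rank-sum enumeration for groups up to size 10), and BH against a
hand-rolled implementation.

**Burden conventions.** Cumulative abundance is the sum of the relative
frequencies of labelled clonotypes in one repertoire. Its log10 is floored
by convention: an abundance of exactly 0 is reported as −6, below the
resolution of any realistic repertoire. The "expanded carrier" flag is a
strict comparison (abundance *greater than* the threshold; default 0.025,
i.e. 2.5% of the repertoire). Summary percentages are emitted under two
conventions — rounded to the nearest integer and truncated to one decimal
place — because both appear in practice; tests pin each explicitly.

**Classifier.** Rules are applied in the fixed order CAIT, MAIT, iNKT;
their gene sets are disjoint, so precedence only matters defensively. The
CAIT rule requires TRAV12-1 + TRAJ6 + length 15 + the motif; requiring the
exact J gene is the conservative reading (the motif might in principle
occur with other J genes, but the rule set is configurable via
`classRule`). The MAIT rule is gene-based without a length constraint by
default, since the broad definition spans several junction lengths; the
narrow 12-mer family used for depletion scans is available via
`defaultRules(mait_length = 12)`. A cell is labelled by the
highest-priority match over all of its alpha chains; cells without an
alpha chain are unclassifiable (`NA`). All classification happens after
allele suffixes are stripped (`TRAV12-1*01` → `TRAV12-1`), and clonotype
identity is (chain, V, J, CDR3 amino acids) throughout — nucleotide
variants converge.

**Motif threshold.** `deriveConsensus` defaults to a conservation
threshold of 0.7. This value sits between fully conserved positions
(modal frequency near 1) and the "mostly but not always" positions such as
the serine at motif position 7 (around 0.6 in the populations this
pipeline targets), so the derived pattern keeps the fixed core and
wildcards the variable positions. The position frequency matrix is
unweighted over distinct clonotypes by default: a motif should describe
the sequence family, not its expansion. Modal ties break alphabetically.

## The synthetic-data generator

Cohort-scale repertoire collections with known ground truth do not exist,
so validation rests on `simConfig`/`genCohortStudy` and friends. A
generated repertoire has:

- **Zipf clone sizes**: clone ranks follow counts ∝ rank^(−s) with
  exponent s = 1.5 by default over 2,000 clones, giving the heavy-tailed
  size spectrum typical of bulk blood repertoires; the depth multiplier
  (`count_scale = 10`) puts total counts in the millions so that relative
  frequencies are resolved to ~1e-6.
- **Background junctions**: conserved C…F anchors around positionally
  i.i.d. interior residues drawn from a mildly glycine/serine-enriched
  alphabet, with a unimodal length distribution over 8–20 (mode 13–14)
  and realistic marginal V/J usage. This is deliberately *not* a
  recombination model: it exercises every statistic (grouping, ranking,
  multiplicity, presence testing) without modelling V(D)J biology.
- **Planted spikes**: with a per-cohort carrier probability (CAIT default
  0.45 in CD vs 0.05 in controls), a sample receives 1 + Poisson(2)
  distinct motif junctions whose cumulative frequency is renormalized to a
  log-normal target (median 2.5%, sdlog 1, capped at 50%) within 1e-6.
  A MAIT spike (`maitSpike`) plants the mirrored signal: near-ubiquitous
  carriers with *lower* abundance in CD.
- **Multi-tissue subjects**: carrier status and the planted clonotype set
  are drawn once per subject; each planted clonotype is shared into each
  non-blood tissue with probability `tissue_sharing` (default 0.5, so
  cross-tissue sharing is common but not universal).
- **Paired cells**: CAIT clonotypes pair with beta chains drawn from a
  configured TRBV usage (TRBV7-9 weight 0.45), with Poisson clonal
  expansion, plus MAIT, non-CAIT TRAV12-1⁺ and background cells; KLRB1 and
  CD8A are positive with class-specific rates (0.9 for invariant classes
  vs 0.2/0.5 for others).

Everything derives deterministically from (config, seed): the bulk-study,
multi-tissue and paired generators seed the RNG at offsets 0, 1 and 2 from
the configured seed so their draws do not alias.

What passing tests on this generator *do* show: the pipeline recovers a
planted family as the top-ranked hit, reconstructs the exact motif string,
and separates cohorts by burden, at study scale (100 + 100 samples of
2,000 clones, repeated over 20 seeds) — and the arithmetic of every stage
matches independent oracles. What they do *not* show: robustness to the
features the generator omits — sequencing error, V(D)J-driven convergent
recombination (which inflates background sharing of short junctions),
depth-dependent detection limits, and batch effects between cohorts. On
real data those factors mainly add noise and multiplicity, not bias in a
particular family's favour, but conclusions about sensitivity at low
prevalence should not be read off the simulation.

## Degenerate inputs and edge rules

- Reading an AIRR file keeps only junctions made of the 20 standard
  residues with length ≥ 5; duplicate (V, J, CDR3) rows merge by summing
  counts; a file with no surviving rows is an error, as is a missing
  required column (named in the message).
- A repertoire validates that frequencies equal count/total within 1e-9
  and sum to 1 within 1e-6, and that clonotype keys are unique.
- An empty family query returns frequency 0; a family scan requires ≥ 2
  samples per cohort; a clonotype absent from both cohorts gets Fisher
  p = 1.
- `fractionAmongV` with an empty gated denominator returns 0 with a
  warning and an `empty_denominator` flag rather than NaN; a gate naming a
  marker a cell lacks is an error, not silently FALSE.
- Cells with two beta chains contribute their dominant beta (by UMIs) to
  paired clonotypes when UMI counts exist; otherwise both pairings count.

## Validation problem sizes

The shipped test suite validates the end-to-end recovery claim at the
default study scale (20 seeds × 200 repertoires × 2,000 clones) and runs
unit and property tests on reduced sizes (typically 20–60 repertoires of
300–500 clones), where the planted family is checked for the smallest raw
p-value rather than genome-wide q-significance — with ~8,000 families
tested, BH-level significance genuinely requires the full cohort sizes,
which is itself an instructive property of the design.

## A worked run

```{r demo, eval = FALSE}
config <- system.file("extdata", "demo-config.yaml", package = "CAITscan")
res <- runPipeline(config, out_dir = tempfile("caitscan-demo"))
res$summary$top_family
res$summary$consensus_motif
```

## Known limitations

- The classifier is strictly rule-based; it cannot discover motif variants
  outside the configured V/J/length frame.
- Publicity and beta-privacy are exact string matches; one-mismatch
  neighbourhoods (convergence classes) are out of scope.
- The generator's i.i.d. junction model underestimates background sharing
  of short junctions, so publicity statistics on synthetic data are
  optimistic.
- The Mann-Whitney normal approximation in the family scan is standard
  but approximate for very small cohorts; for focused comparisons use
  `compareCohorts`, which switches to exact computation when feasible.
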