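---
title: "Comparative variant, codon-usage and codon-aversion analysis of two bacterial lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative variant, codon-usage and codon-aversion analysis of two bacterial lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camscan)
```

## The setting

`camscan` compares two closely related bacterial lineages — the motivating
system is the symbiotic cyanobacterium UCYN-A, whose A1 and A2 ecotypes are
represented by three and four sequenced strains — through the aligned coding
sequences of their single-copy orthologous genes. Three complementary layers
of signal are extracted from the same alignments:

1. **Sequence variants.** Each strain of one lineage is scanned against the
   majority-rule consensus of the other lineage: single-nucleotide
   differences (classified as transitions or transversions) and gap runs
   (classified as insertions or deletions, small `<= 40` bp or large
   `> 40` bp, frame-preserving or not).
2. **Codon usage.** Per gene and strain: relative synonymous codon usage
   (RSCU), Wright's effective number of codons (ENC), parity-rule-2 (PR2)
   third-position biases, stop-codon preference; per gene between lineages:
   significantly variable codons (SVCs) and an F-test-then-t-test comparison
   of ENC values.
3. **Codon aversion.** The codon aversion motif (CAM) of a gene in a strain
   is the set of sense codons that gene never uses (equivalently, codons
   with RSCU 0). Motifs are compared as canonical sorted sets; genes whose
   motifs separate the lineages, or individual strains, become diagnostic
   markers, and a greedy decision tree over genes turns the motif table
   into a strain-identification map.

Because real ortholog panels come without ground truth, the package's
fourth component is a **two-clade sequence evolver** that emits alignments
*together with* the complete log of planted events. Every scanner and
statistic in the package is validated against that log.

## The simulation model

`sim_config()` fixes the study conditions; `simulate_panel()` draws a
panel. The defaults describe the kind of data the pipeline targets:

* **Panel**: 40 genes, CDS lengths uniform over multiples of 3 in
  300–3300 nt, ancestral GC 0.34. The motivating genomes are strongly
  AT-rich (genic GC near 33–39%) and their ortholog CDSs span roughly this
  length range.
* **Topology**: `((A1,A2,A3),(B1,B2,B3,B4))`. Substitutions and INDELs are
  drawn independently on each of the nine branches. Stem branches run at
  `stem_mult = 10` times the tip rate (`sub_rate = 0.005`/site at tips), so
  within-clade identity (~99%) greatly exceeds between-clade identity
  (~90%), reproducing the qualitative identity gap between ecotypes. The
  published data give no calibrated branch lengths, so these values were
  chosen once to reproduce that gap and are not tuned further.
* **Substitutions** follow a K80-style kernel: a mutated site becomes a
  transition with probability `kappa/(kappa + 2)` and each transversion
  with probability `1/(kappa + 2)`, with no rate heterogeneity. The model
  measures only the transition/transversion balance, which is the single
  parameter the downstream ts/tv statistic can recover.
* **INDEL lengths**: a length is a multiple of three with probability
  `frame_mass = 0.85` (coding-region INDELs that survive selection are
  dominated by frame-preserving lengths; roughly 85% in the motivating
  data); small lengths are geometric (`p = 0.35`, capped at 40), and with
  probability `large_prob = 0.05` an event is large (41–120 bp).
  Insertions copy the adjacent upstream sequence (tandem-duplication
  style); placement avoids the first and last codon so start and stop
  remain intact.

### Ancestral-coordinate events and replay

All events target *ancestral* coordinates: substitutions and deletions hit
ancestral sites, insertions anchor after an ancestral site, and inserted
material never receives later events (no nested INDELs, no substitutions
inside insertions). This is a deliberate simplification with a large
payoff: the emitted alignment is a pure function of the ancestor plus the
event log (`replay_events()`), so the truth channel is exactly
reconstructable and the alignment needs no realigner — the scanners are
being tested, not an aligner. The cost is that some real mutational
histories (e.g. an insertion later partially deleted) cannot be expressed;
for validating scanners this sacrifices nothing.

Events can still *interfere* in the emitted alignment: two substitutions
at one site shadow each other, adjacent deletions merge into one gap run,
an insertion anchored inside another strain's deletion splits that
strain's run in two. `flag_interference()` marks such events, slightly
conservatively (a flagged event may occasionally still be recoverable, but
an unflagged event is always cleanly recoverable). The package's oracle
tests assert that the scanners recover 100% of unflagged events with exact
columns, lengths, polarities, sequences and carrier sets.

`plant_cam_difference()` modifies a panel after evolution: every
occurrence of a chosen codon in the target strains' copies of a gene is
synonymously recoded, leaving the protein untouched while forcing
RSCU = 0 — a known positive for the motif machinery. Planting rewrites
sequence outside the event log, so replay-based checks apply to panels
before planting.

## Statistical conventions

* **Eligibility.** Codon statistics use CDSs whose ungapped length is
  strictly greater than 300 nt, with the terminal codon set aside before
  counting (it is tallied separately by `stop_codon_tally()`). A length
  not divisible by three is a warning, not an error: ortholog panels
  contain incomplete and pseudogenised copies, and the pipeline carries
  them through flagged.
* **Genetic code.** The bacterial/plastid code (translation table 11)
  throughout: 61 sense codons; Leu/Ser/Arg six-fold, Ile three-fold. The
  single-codon families Met and Trp are excluded from RSCU preference,
  SVC and motif reporting (their RSCU is constant by construction) but
  contribute the constant 2 in the ENC formula.
* **ENC.** `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with
  `F = (n * sum(p^2) - 1)/(n - 1)` per family, averaged within each
  degeneracy class; families with `n <= 1` are excluded from their class
  mean, a class with no estimable family (or a non-positive mean, which
  tiny samples can produce) is imputed at its uniform expectation `1/k`
  and flagged, and the result is clipped to `[20, 61]`.
* **PR2.** By default third-position counts accumulate over the five
  four-fold degenerate families only, where the third position carries no
  amino-acid constraint; `fourfold_only = FALSE` restores the all-codon
  variant. Both are provided because the two published descriptions of
  the statistic differ on this point; the four-fold reading is the
  default since it is the one the biases are interpreted under.
* **Group RSCU.** SVCs compare RSCU computed on counts *pooled* across a
  lineage's strains rather than averaged per-strain values: pooling is
  robust for short genes and matches the consensus-sequence usage the
  comparison emulates. The boundary RSCU = 1 counts as unpreferred.
* **ENC group test.** A two-sided F-test at `alpha = 0.05` chooses between
  the pooled-variance and Welch t-tests. When both groups have zero
  variance the t statistic is degenerate; the implementation returns
  p = 1 for equal means and p = 0 otherwise, the limit of the pooled
  statistic. The null calibration of this two-stage procedure at the
  panel's group sizes (3 vs 4) is checked by simulation in the test
  suite.
* **Rounding.** Reported percentages and table values round half *up*
  (`round_half_up()`), matching how such tables are conventionally
  printed; base R's round-half-to-even would disagree in the last digit.
* **Consensus.** Majority rule per column with the gap as a votable
  symbol (so a lineage-wide deletion yields a gapped reference) and the
  fixed tie order `A < C < G < T < N < -`. The tie order is arbitrary but
  documented and deterministic; N votes but loses ties to real bases.
* **INDEL merging.** Records merge across strains only when start,
  length, polarity *and* sequence agree exactly — a conservative reading
  of "shared" that never conflates near-identical events. Both the merged
  record count and the carrier-expanded event count are recoverable from
  the output (`n_carriers`), since published INDEL tallies use sometimes
  one convention, sometimes the other.
* **INDEL divergence.** Summed event length over the *full* alignment
  column count, gap columns included — the ratio is defined on the
  alignment, not on any one sequence.

## The identification map

`build_identification_map()` grows a decision tree greedily: each node
picks the unused gene whose motif-equality classes split the node's
strains into the most blocks, breaking ties by fewest total motif codons
and then lexicographic gene id; genes still tied are recorded as
alternative pathways rather than discarded, because multiple valid
pathways genuinely exist and determinism has to come from the artifact.
With `lineage_first = TRUE` the root must use a group-diagnostic gene
when one exists, so the first split separates the lineages. Strains no
gene can separate end in a flagged non-separable leaf, and
`identify_strain()` never guesses: a novel motif returns the current
node's strain set as an explicit ambiguity set, a missing gene returns a
partial-descent candidate set.

Group diagnosticity is defined as *disjoint motif-value sets* between the
lineages — not merely different multisets — because disjointness is what
guarantees error-free classification of unseen members of either lineage.
A shared motif value (commonly the empty motif) defeats diagnosticity
even if the value distributions differ. On instances small enough for
exhaustive search, the greedy leaf partition provably coincides with the
partition by full motif-profile equality, and the test suite checks this.

## What the tests do and do not show

The synthetic panels emulate the statistical structure the analysis
assumes: two clean clades, independent per-branch events, no
recombination, no alignment error, no annotation error, i.i.d. base
composition. Passing the oracle tests therefore demonstrates that the
scanners and statistics are *correct implementations*; it does not
demonstrate robustness to misalignment, paralogy or assembly artefacts,
which the pipeline does not model (inputs are taken as pre-aligned,
curated ortholog matrices). Problem sizes in the suite — 50-gene panels
for scanner validation, 10^4 replicates for the test-calibration check,
10^3 random count tables for the codon identities — were chosen as the
smallest sizes at which the binomial tolerances quoted in the tests are
meaningful.

## A worked pass

```{r example}
cfg <- sim_config(n_genes = 6, len_range = c(600, 1200), seed = 11)
panel <- simulate_panel(cfg)

g <- panel$alignments[["g001"]]
cons_a <- build_consensus(g, panel$strains, "A")
snps <- call_snps(g, cons_a, lineage_strains(panel$strains, "B"))
head(snps, 3)
tstv_ratio(snps)$ratio

cds <- degap_and_validate(g$seqs[["B1"]], "g001", "B1")
e <- enc(count_codons(cds))
round(e$enc, 2)
```

The numbered scripts under `analysis/` run the same stages over a full
panel and write their tables under `results/`; `run_pipeline()` is the
single-call orchestrator behind them.
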