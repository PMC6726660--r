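---
title: "Structural determinants of CO2 sensing in beta connexins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural determinants of CO2 sensing in beta connexins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connexinCO2)
```

## The biology in brief

Beta connexins (Cx26, Cx30, Cx32) form hexameric hemichannels and, when two
hemichannels dock across adjacent cells, gap junctions. A subset of these
channels is directly gated by CO2: carbon dioxide carbamylates a lysine
(K125 in human Cx26 numbering) and the carbamylated side chain forms a salt
bridge to an arginine (R104) of the neighbouring subunit, biasing the
hemichannel open. Two residue-level determinants control whether a given
connexin responds to CO2:

1. **The carbamylation motif** — K125 and R104 homologs present, with no
   proline in the 123–124 window (prolines there would sterically prevent
   the carbamylated lysine from reaching its partner arginine).
2. **The C-terminal tail** — an extended cytoplasmic tail blocks CO2-evoked
   hemichannel *opening* even when the motif is intact, unless the tail is
   conformationally restricted by prolines (the Cx32 configuration).
   Amniote Cx26 lost the tail, which is what makes it a hemichannel CO2
   sensor at physiological partial pressures.

Gap-junction *closure* by CO2 tracks Cx26-like clade identity rather than
tail structure: long-tailed Cx26-like gap junctions close even though their
hemichannels are insensitive, while Cx32 gap junctions do not close at the
doses in the standard protocol (35/55/70 mmHg PCO2). The package therefore
keys the gap-junction half of its phenotype prediction on the clade
explicitly, not on the tail.

The package makes all of this computable: determinant annotation from
sequence, rule-based phenotype prediction, parsimony reconstruction of
trait history, codon-level fragility of the motif, and the quantification
rules of the dye-loading and dye-transfer assays that anchor the phenotype
calls.

## Reference-anchored coordinates

Every coordinate in the package is 1-based in the numbering of a bundled
reference protein. Residue numbering is assumed to count the initiator
methionine, which is how the conventional site names (K125, R104, P228...)
are used throughout the field.

* **Human Cx26** (GJB2, 226 residues) is the coordinate system for the
  Cx26-like clade. Anchor sites: K125, R104, window 123–124, tail boundary
  226 (its final residue).
* **Human Cx32** is shipped as a *synthetic composite*
  (`reference_cx32_human_synthetic.fasta`): a full-length Cx32-like protein
  assembled so that every literature-named coordinate sits at its published
  position — the four tail prolines at 228, 229, 242 and 268, the
  carbamylation-motif homologs at the same coordinates as in Cx26, and the
  cytoplasmic tail boundary at the column homologous to Cx26's C-terminus.
  It is not a verbatim database record, and code that depends on Cx32
  coordinates depends only on these documented anchors. Users with the
  authentic record can drop it in via the `references` arguments.

Queries are aligned to a reference with affine-gap pairwise alignment
(BLOSUM62, gap open 10, gap extend 1; a gap of length L costs
`open + L * ext`). The default mode is semi-global on the reference side:
the reference must align end-to-end but query overhangs are free, so a long
C-terminal tail is never penalised into a misalignment. The C-terminal tail
of a query is everything past the query column homologous to the reference
tail boundary; if the boundary falls in a gap the nearest aligned reference
position before it is used, so truncated constructs get tail length 0
rather than an error. This boundary is a *convention*, not a structural
claim — the true end of the fourth transmembrane helix is not an input
here — but it is the convention under which "truncated to a few amino
acids" and "extended tail" are operationalised, and all tail coordinates
the package reports are interpretable under it.

Tail classification: `short` when the tail has at most `short_threshold`
(default 15) residues — amniote Cx26 tails are a few residues long —
`extended` otherwise; an extended tail is `restricted` when it carries at
least `min_prolines` (default 2) prolines. Two introduced prolines sufficed
for experimental gain of function, hence the default; no proline spacing
requirement is imposed because none was tested. A single proline in the
123–124 motif window still yields `proline_modified` (flagged low
confidence): the steric argument was made for the two-proline lamprey
configuration and a one-proline window was never tested experimentally.

## The phenotype rule engine

`predict_phenotype()` applies four ordered rules (R1–R4, see its help page)
mapping (motif status, tail class, clade) to a hemichannel response —
`opens_moderate_pco2`, `opens_high_pco2_only`, `insensitive` — and a
gap-junction response — `closes`, `insensitive`, `untested_rule`. Three
design points deserve justification:

* The proline-restricted Cx26-like configuration is classified
  `opens_moderate_pco2` because the proline-gain lungfish mutant opened
  under the standard 55 mmHg protocol; it was never pushed to 70 mmHg, so
  the distinction from the Cx32-like high-PCO2 class rests on the protocol
  actually run. The `confidence` field separates tested from extrapolated
  cells of the rule table.
* A short-tailed Cx32 has never been observed; its gap-junction cell is
  `untested_rule` rather than a guess.
* Motif `absent` silences everything testable; the gap-junction column is
  `untested_rule` because motif-destroying mutants were characterised at
  the hemichannel, and closure assays on such mutants are not part of the
  anchoring data.

The engine is held, in the test suite and the acceptance script, to a
twelve-construct truth table (`construct_truth_table()`): wild-type Cx26 of
two reptiles, an amphibian, a lungfish and the short-tailed coelacanth
paralog; the tail-truncation and tail-swap constructs; Cx32 of human,
zebrafish and whale shark; the Cx32 all-Pro-to-Gly tail mutant; and the
lungfish G222P/G238P proline-gain mutant.

## Synthetic stand-ins

No sequence database is consulted at build, test or run time. The
non-human wild-type constructs are *synthetic stand-ins*
(`constructs_synthetic.fasta`): each is derived from a bundled reference by
a handful of conservative substitutions plus exactly the determinant
features documented for that construct — e.g. the lungfish-like Cx26
carries an extended proline-free tail with glycines at query positions 222
and 238, so that the documented G222P/G238P edits land inside its tail; the
amphibian-like Cx26 carries a 42-residue unrestricted tail that is also the
donor for the tail-swap construct. The stand-ins are faithful to the
determinants and, where the literature names coordinates, to those
coordinates; they are not the species' real sequences, and their FASTA
file says so. The four mutant constructs are *derived in code* from the
stand-ins with `apply_substitutions()` and sequence surgery, mirroring the
original mutagenesis (each edit is checked against the residue actually
present, so a coordinate slip is an error, not a silent wrong answer).

The same applies to the curated bookkeeping table (`curated_set()`: 53
sequences, 24 species, with the three coelacanth Cx26 paralogs) and the
53-tip tree with its tip trait table: the published accessions are carried
verbatim where the source states them, every other row is a figure-derived
annotation (`source = "figure"`) and replaceable by the user.

## Ancestral states

`fitch_reconstruct()` is minimum-change parsimony for a binary character,
implemented as unit-cost dynamic programming over states (an up pass for
subtree costs, a down pass for outside costs). This is exact on polytomies,
where the classical intersection/union shortcut is not; on binary trees it
reduces to Fitch counts, which the tests verify against exhaustive
enumeration of all internal labelings on every topology with up to six
tips, and against an independent Sankoff implementation. Per-node state
sets contain every state occurring in at least one most-parsimonious
labeling. Ambiguity is reported, never silently resolved: the `resolved`
column applies a stated convention (singletons resolve to themselves;
ambiguous nodes inherit the parent; an ambiguous root resolves to
presence) and is labelled as such. Branch lengths are ignored throughout —
the claims being reproduced are parsimony claims, not rate claims.

`dollo_reconstruct()` constrains the history to a single gain: the gain is
placed on the branch subtending the MRCA of all presence tips (the latest
single-origin placement, which also minimises losses) and each maximal
all-absent subtree below it receives one loss. Tips with unknown state
(`?`) are pruned with a warning in both methods. On the bundled tree the
motif trait yields a presence root for the gnathostome clades under both
methods, with exactly two Dollo losses — the non-mammalian amniote Cx30
clade and the actinopterygian Cx30.3 clade.

## Codon fragility

`min_codon_substitutions()` computes the minimum Hamming distance between
the codon sets of two amino acids under the standard genetic code (stop
codons excluded as endpoints and intermediates; no organism-specific
codes). K to R is distance 1 — the motif can be destroyed by a single base
change — which is why motif persistence over hundreds of millions of years
reads as selection. One numerical caveat the docs state explicitly: this
set-to-set minimum is *not* a metric. A two-step path may use different
codons of the intermediate amino acid on each leg, so the triangle
inequality can fail (C to E is 3, while C to G and G to E are each 1). The
matrix is verified against a brute-force oracle instead.

## Assay quantification

The dye-loading pipeline follows the published measurement rules: per-cell
mean ROI intensity minus the per-image background ROI; per replicate and
condition, the *median* corrected intensity; per replicate, the change
from the 35 mmHg control. Statistics run on per-replicate deltas — one
number per independent transfection — which is the guard against
pseudoreplication. Kruskal–Wallis is the omnibus test and Mann–Whitney the
pairwise test; pairwise significance flags are gated on the omnibus test.
The package's Mann–Whitney enumerates the permutation distribution exactly
(ties included) when both groups have at most eight values — base R's
`wilcox.test` declines exact p-values under ties — and falls back to a
tie-corrected normal approximation with continuity correction otherwise.

Box-plot summaries implement the whisker rule exactly as the source's
figure legends state it: whiskers reach the most extreme point within 1.5
IQR *of the median*. That is not Tukey's convention (fences at the
quartiles); the package implements the legend's rule as written and offers
the Tukey variant behind `anchor = "quartile"`. Quartiles use linear
interpolation of order statistics (`quantile` type 7), pinned for
reproducibility since the source does not specify a rule.

Dye-transfer timing: the call is the first sampled time (10 s grid) at
which acceptor fluorescence reaches 10% of the *background-corrected*
donor fluorescence at that time — whether the published 10% refers to
corrected or raw donor is not stated; corrected is assumed and flagged
here. A linearly interpolated crossing is reported as a refinement; the
grid call is primary, matching minute-resolution reporting. Censoring at
the last sample, monotonicity in the acceptor, and an error on an all-zero
donor are all contract-tested.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads,
and its defaults are the study conditions:

* **Traits**: root-to-tip Bernoulli gain/loss per branch, default 0.05
  changes per branch — low enough that parsimony is the right tool, which
  is the regime the reconstruction claims live in. True internal states
  are retained for recovery scoring.
* **Families**: each tip is the Cx26 scaffold with 2% background
  substitutions (never at the anchor sites, never creating prolines),
  K125R (or a window proline) for motif-loss tips, and an appended
  Poisson-length tail (mean 40 residues, 5% per-residue proline
  probability) for extended-tail tips. Construction is the ground truth,
  so annotation agreement (about 99% or better; residual disagreement is
  alignment edge cases at high substitution loads) measures the pipeline,
  not the simulator.
* **Assays**: intensity = per-image background (uniform 50–150 units) +
  baseline 20 + class/condition effect + Gaussian cell noise (sd 20), with
  40 cells per condition and 5 replicates; effect sizes default to +80
  units at 55 mmHg for the moderate-opening class, +15/+90 at 55/70 for
  the high-PCO2 class, and +150 for the zero-Ca2+ positive control.
  Transfer traces are a constant donor plateau and a logistic acceptor
  rise whose continuous-time threshold crossing is placed exactly at the
  injected delay; only the crossing time is contract-relevant. A
  CO2-closed gap junction holds the rise until the 120 s hypercapnic
  window ends.

What passing tests on synthetic data do **not** show: real dye-loading
distributions are right-skewed and occasionally bimodal rather than
Gaussian; real backgrounds drift within an image; real protein families
evolve with indels, rate variation and non-tail insertions that the
scaffold-plus-tail model omits. The generator is a statistical emulation
of the study design (effect structure, nesting, replicate counts), not of
microscopy.

## Calibration results the package itself computes

The test suite and `scripts/acceptance.R` recompute, at fixed problem
sizes chosen to keep the whole suite inside a couple of minutes: root-state
recovery on a 16-tip balanced tree at 0.05 changes/branch over 500
replicates (a replicate counts as recovered when the true root state is
among the most-parsimonious root states — the package reports ambiguity
rather than guessing, so scoring the tie-break convention would measure
the convention, not the method); the Kruskal–Wallis type-I error over
2,000 null draws of 3 × 5 replicate deltas; the no-significant-pair rate
over 300 full-pipeline null runs; and the power to detect the +80 unit
moderate-PCO2 effect with five replicates over 500 runs. No number is
asserted anywhere that these computations do not produce.

## Known limitations

* The Cx32 reference is a documented composite, not the database record.
* The tail boundary is a fixed homology convention; biological tail
  boundaries differ by a few residues between paralogs.
* The motif definition is the three-site core (K125/R104/window); the
  original structural work defines additional context residues that are
  not enumerated here, and the scan does not attempt them.
* Gap-junction predictions for engineered mutants are reported as
  `untested_rule` wherever the anchoring experiments did not measure them.
* Quantitative EC50 prediction and heteromeric channels are out of scope.
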