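---
title: "Detecting selective constraint on ITS secondary structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective constraint on ITS secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the approach

The internal transcribed spacers ITS1 and ITS2 of the nuclear ribosomal
cistron are excised during rRNA maturation, and correct processing depends on
the folded secondary structure of the precursor. If spacer folds matter
functionally, spacer sequences should evolve under selective constraint to
preserve them — even while primary sequence diverges strongly, as it does
among the subgenera of taxonomically complex plant genera.

`itsfold` operationalizes this question as a randomization test. For every
real spacer sequence it constructs one random sequence of exactly the same
length whose G+C count equals `round(gc * length)` — a composition-matched
null with no evolutionary history. Both cohorts are folded with the same
energy model and the per-sequence statistics are compared with rank tests:

* **LES** (lowest energy state): the free energy of the minimum-free-energy
  (MFE) structure, in kcal/mol. Constraint to fold predicts a lower
  (more negative) LES in real sequences than in matched random ones.
* **Number of structures**: how many distinct suboptimal foldings lie within
  an energy window of the MFE (window 10%, cap 20, minimum base-pair
  distance 3 between reported structures). A constrained sequence has a
  deeper, narrower folding landscape — fewer alternatives.
* **Hairpin count** and **paired nucleotides**, read off the MFE structure.

Group-against-group comparisons (Wilcoxon–Mann–Whitney between the two
spacers; Kruskal–Wallis among taxonomic groups) and alignment descriptive
statistics (variable and parsimony-informative sites, simple indel coding of
gaps) complete the pipeline.

## The folding model

The folder is a Zuker-style minimum-free-energy dynamic program over the
nearest-neighbour model, with an exterior recursion `W` and a pair-closed
recursion `V` covering hairpin loops, helix stacking, bulge and internal
loops (total unpaired size capped at 30 nt) and affine multibranch loops
(`a + b·branches + c·unpaired`; the closing helix is not counted as a
branch). Allowed pairs are AU, UA, GC, CG, GU, UG; DNA input is transcribed
(T→U) before folding, since the spacers act at the RNA level. The minimum
hairpin loop is 3 nt. An open chain has energy 0, so the LES is never
positive.

The parameter set (`inst/extdata/nn_params.txt`) is a simplified Turner-style
table: stacking free energies for all 36 pair steps (satisfying the
thermodynamic symmetry `stack(P,Q) = stack(rev Q, rev P)`), tabulated loop
penalties for sizes up to 30 with logarithmic extrapolation
(`E(n) = E(30) + 1.08·ln(n/30)` kcal/mol) beyond, and multiloop terms
`a = 3.4`, `b = 0.4`, `c = 0.1` kcal/mol at 37 °C. Deliberate
simplifications, stated rather than hidden: no dangling ends, no terminal
mismatches, no helix-end AU penalty, no special small-loop tables, and a
single-parameter bulge (a bulge of 1 interrupts its flanking stack).
Numerical agreement with any particular published folding program is
explicitly not a goal; the package's claims rest on *internal consistency*
(every reported energy equals an independent loop-decomposition evaluation of
the reported structure, `evaluate_energy()`, implemented separately from the
dynamic program) and on *rank-level* comparisons, which are robust to the
absolute energy scale.

Two independent checks guard the engine. A Nussinov base-pair-maximization
folder (`nussinov_maxpairs()`) provides a second dynamic program, and the
test suite verifies both engines against exhaustive enumeration of all valid
structures for a thousand short random sequences.

**Determinism.** Co-optimal structures are resolved by a fixed traceback
preference order — hairpin before stack before internal loops (by increasing
loop size) before multiloops; in the exterior, an unpaired base before a
paired one, then the smallest 5′ index. Identical input and model therefore
give byte-identical output on every run.

**Suboptimal enumeration.** Distinct low-energy structures are collected by
deterministic pair-penalty refolding: each round adds a small fixed penalty
(0.3 kcal/mol) to every base pair already seen and refolds; the candidate is
re-scored with the *unpenalized* model via `evaluate_energy()` and kept if it
lies within the energy window and differs from every kept structure by at
least the minimum base-pair distance. The defaults (10% window, 20
structures, distance 3) mirror the documented defaults of widely used folding
programs. The first structure is always the MFE fold; reported energies are
plain model evaluations. This scheme does not guarantee completeness of the
enumeration — it is a reproducible sampler of the low-energy landscape, which
is all the structure-count statistic requires.

## The null model

`matched_random_sequence()` matches length exactly and GC at the exact count
`round(gc·L)` (G versus C, and A versus T, split as evenly as possible, odd
remainders assigned by the seeded generator), with positions a uniform
permutation. The match is therefore within the rounding bound `0.5/L` by
construction, removing the uncontrolled tolerance a "similar GC" criterion
would leave. An i.i.d. mode and a stricter dinucleotide-preserving shuffle
(Altschul–Erickson walk on the dinucleotide multigraph) are available behind
flags; the shuffle is an extension beyond the basic composition null. Per-
record seeds are a stable hash of the master seed and record index, recorded
in the provenance table for audit.

## Statistical conventions

The Mann–Whitney U statistic is computed from joint midranks. p-values are
exact (full enumeration of the U null) when `n+m ≤ 25` without ties, seeded
Monte-Carlo permutation (10⁵ draws) when ties occur in a small sample, and
tie- plus continuity-corrected normal approximation otherwise. Kruskal–Wallis
uses the tie-corrected H with a χ² reference on k−1 degrees of freedom.
Raw p-values are reported (a Holm option exists but is off by default).
Descriptive summaries give mean, sample SD (n−1; zero when n = 1), min, max
and mode, with modal ties broken toward the smallest value. Group summary
tables round means and SDs to one decimal; per-sequence tables keep full
precision.

Alignment statistics follow the standard parsimony conventions: a column is
variable when at least two distinct unambiguous base states occur (gaps and
ambiguity codes are not states; T and U are one state), and parsimony-
informative when at least two states each occur at least twice. "Ambiguous
sites" are removed as (i) any column containing an ambiguity code and
(ii) user-masked column ranges — manual judgments of alignment ambiguity
cannot be automated and enter through the mask. Gap spans are converted to
binary characters by simple indel coding: a row scores 1 for its exact
maximal gap runs, 0 where none of its gaps overlap the character's span, and
missing where one of its gaps strictly contains the span; a gap that merely
staggers across a span boundary (overlap without containment) scores 0.
Indel characters are reported separately and never added to site counts.
All coordinates are 1-based closed intervals.

## The synthetic-data generator

Because the original sequence sets live in public archives and the analysis
should be testable without downloads, `synth_family()` generates ITS-like
families with a *known* degree of structural constraint, so the pipeline's
verdicts can be validated by parameter recovery.

An ancestor of the region's typical length (263 nt ITS1-like, 206 nt
ITS2-like; GC target 0.55) is assembled from:

* the complementary terminal motifs `5'-TCGAA` and `TTCGA-3'`, which pair
  with each other and close the whole fold (the closing helix contributes no
  hairpin loop of its own);
* `n_stems` (7 ITS1-like, 3 ITS2-like) reverse-complementary all-GC stem
  blocks of 8 bp, each closed by a 4-nt oligo-A hairpin loop — short and
  adenine-only so the loop cannot fold on its own or be captured easily by a
  competing helix;
* for ITS1-like sequences, the central conserved motif `AAGGAA`, kept
  unpaired;
* random spacer segments carrying the remaining GC budget at exact count.

The stem dimensions are a calibrated operating point, not a measurement: with
6-bp stems the planted fold is not thermodynamically dominant under this
energy model (the folded hairpin-count mode no longer recovers the planted
stem number), while 8-bp all-GC stems make the planted structure the MFE
attractor and leave the spacers with a realistic mixed composition. The
planted structure is returned alongside the sequence, with its evaluated
energy.

Tips evolve on a star phylogeny: each receives `Poisson(divergence·L)`
substitutions at uniform positions (multiple hits allowed, so realized
divergence saturates below the nominal rate). A substitution landing in a
planted stem co-mutates the partner base with probability
`compensatory_fraction` (c), drawing uniformly among bases that restore an
allowed pair, GU included — the mechanism of compensatory evolution that
preserves structure while sequence diverges. Motif positions are immutable
(a mutable-motif flag exists for sensitivity analysis). At the default
operating point (c = 0.9, divergence = 0.15 substitutions per site) the
constraint signature is reliably detected against matched nulls; at c = 0
with divergence 0.5 the signal degrades, as it should.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: indel evolution (families are emitted
unaligned but are trivially alignable), tree-shaped rather than star-shaped
divergence, concerted-evolution homogenization, base-composition
heterogeneity along the sequence beyond the planted blocks, and any
energy-model error relative to real RNA thermodynamics. The recovery tests
validate the *pipeline's statistical machinery*, not the biological claim.

## Numerical and degenerate-input choices

* Folding tie-breaks: fixed deterministic traceback order (above).
* Energy comparisons in the traceback use an absolute tolerance of 1e-7;
  suboptimal window and distance filters use 1e-9.
* Sequences shorter than `min_loop + 2` fold to the open chain, energy 0.
* Constant pooled data in a rank test yields p = 1 with a warning rather
  than an error; empty groups are errors.
* Single-group inputs skip Kruskal–Wallis with a logged warning; a missing
  region skips the between-region comparisons the same way.
* Deduplication keeps the first-encountered record of each
  (species, exact ungapped haplotype) pair; T and U are distinct unless
  `collapse_tu` is set. The terminal missing-data threshold defaults to 10
  positions — a declared choice where no standard number exists.
* Null-cohort seeds derive from `(master_seed, index)`; reordering the input
  changes per-record nulls but not cohort-level length/GC distributions.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data,
sized to finish quickly while keeping the comparisons meaningful: exhaustive-
enumeration oracles run on sequences of 5–14 nt (a thousand seeded draws);
parameter recovery uses 20 seeded replicates of 12 sequences per region at
full region lengths; the acceptance script's worked study is one ITS1-like
and one ITS2-like family of 12 sequences each plus their matched nulls,
folded with the default suboptimal settings.

## Known limitations

The energy parameters are a simplified set: absolute LES values are
comparable *within* this package but not with values printed by other
folding software (which also differ among themselves). The suboptimal
sampler undercounts structures relative to complete-enumeration algorithms,
so structure counts are comparable only within runs of this package.
Pseudoknots, base-pair probabilities and comparative (alignment-constrained)
folding are out of scope. The 5.8S boundary is assumed already resolved:
inputs are pre-delimited ITS1/ITS2 sequences.
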