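---
title: "Design and selection of mutant rRNA libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and selection of mutant rRNA libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swmdesign)
```

## The problem

Ribosomal RNA is hard to engineer: the peptidyl transferase center (PTC) of
the 23S rRNA is highly conserved, and even single point mutations there are
frequently lethal. Random mutagenesis cannot cover the combinatorial space,
and PCR-randomized libraries are biased by primer synthesis. A
structure-guided alternative is to *design* libraries computationally:
freeze the structural neighborhood around a set of designable residues,
exclude the wild-type identity at every designed position, score candidate
sequences with a conformational energy function by Monte Carlo sampling,
and build only the sequences the scores favor. Screened activities can then
be read back against the scores, and combinations of region-level variants
can be tested for epistasis.

swmdesign implements that pipeline end to end at desk scale. One deliberate
substitution is made and documented throughout: the all-atom conformational
score produced by a full structure-sampling program is replaced by a
pluggable `energy_model`. The packaged stand-in, `toy_energy()`, is a
base-pairing score, *not* a physics score; externally computed score tables
are ingested with `read_scorefile()` when real scores exist.

## Structural context

`select_sphere_neighborhood()` freezes the design context: all residues of
the input structure (RNA, protein, ions alike) with at least one heavy atom
within a distance sphere of any atom of a designed residue. Choices:

* **Radius**: default 25.0 Å — wide enough for several shells of indirect
  interactions around a helix.
* **Distance criterion**: residue-level inclusion by *any heavy atom*
  (hydrogens excluded on the candidate side). A centroid criterion would be
  cheaper but unstable for long residues; any-heavy-atom is the
  conservative structural convention. The boundary comparison is inclusive
  (`<=`), so the residue set at a given radius is reproducible.
* **Numbering**: author numbering from the deposited file is never
  rewritten; canonical 23S positions (2058, 2552, ...) survive all round
  trips, including the native/starting PDB split and the numbered FASTA
  output (`context_to_fasta()`, RNA lowercase, proteins uppercase).
* **Minimize-adjacent list**: `adjacent_min_res()` returns the
  primary-sequence flanks (n−1, n+1) of each designed residue — the
  residues that must be allowed to relax when a flexible designed region
  meets a rigid crystallographic context.

## Libraries and ambiguity codes

Designed positions are encoded "anything but wild type" with the IUPAC
codes b/d/h/v (`encode_anything_but_wt()`), so each position has a
three-base alphabet and an n-position library has 3^n members (6 561 for
the 8-nucleotide demo helix library). Enumeration is lexicographic
(a < c < g < u) for determinism; capped enumeration samples uniformly
without replacement under a seed. Variant ids follow the `REGION.k`
convention with k assigned in enumeration/selection order, and two-strand
variants print as `(strand1,strand2)`.

`build_combinations()` forms the Cartesian product over per-region menus of
{WT} + variants; with menus of 2, 2, 2 and 1 variants it yields
(1+2)³·(1+1) = 54 constructs including the all-wild-type control.
`apply_to_reference()` refuses to substitute when the reference base does
not match the recorded wild type — the cheap guard that catches numbering
drift before sequences are ordered.

## The energy model and Monte Carlo design

`toy_energy()` scores a variant as

* per paired position pair: −3.0 (Watson–Crick: au/ua/cg/gc),
  −1.5 (wobble: gu/ug), +1.0 (anything else);
* −0.5 for each intra-strand adjacent position pair whose members both sit
  in Watson–Crick pairs (helix continuity / stacking);
* unpaired positions contribute 0.

Units are arbitrary energy units, lower = more stable. The constants are
toolkit defaults (configurable via `weights`) chosen so that
Watson–Crick-rich, stacked variants score best; no numerical agreement with
any physics-based score is intended or checked. The fully paired
8-nucleotide demo wild type scores −15.0; the 2-Watson-Crick variant
`(cggu,gcgc)` scores −5.0.

`design_trajectory()` is a Metropolis walk over identity space: one
uniformly chosen position is mutated to a uniformly chosen allowed base per
cycle, downhill moves are always accepted, uphill moves with probability
exp(−Δ/T). Defaults: T = 1.0 energy unit, 1 000 cycles (2 000 recommended
for structurally complex regions). Backbone add/delete moves of a real
conformational sampler are abstracted into a Gaussian evaluation-noise
channel (σ, default 1.0 in simulation studies): every evaluation of a
sequence returns its true score plus `Normal(0, σ)` noise, which reproduces
the operationally important statistics — different sequences end up as a
trajectory's best frame at variable frequencies, and best scores across
trajectories are not directly comparable. `design_campaign()` runs
independent trajectories (derived per-trajectory seeds; production
campaigns use ≥10 000, desk studies 100–200) and aggregates best frames
with their sampling frequencies.

`forward_fold()` restores comparability: every candidate sequence gets an
*identical* budget of `n_models` models (default 400), each the best of
`n_cycles` (default 500) noisy evaluations of the fixed sequence, and the
minimum is reported. By default the 200 top-scoring campaign sequences are
re-scored this way. With σ = 0 forward folding degenerates to the
deterministic score, which the tests exploit as the noiseless limit.

Ties are broken lexicographically by sequence everywhere; all stochastic
operations are bit-reproducible given (seed, parameters), with child seeds
derived arithmetically so any 32-bit seed is safe.

## Selection protocols

* `select_spanning()` (default n = 50) picks evenly spaced score quantiles
  by the nearest-rank rule, always including both extremes; collisions step
  to the next unused rank. The even-quantile rule is a declared convention:
  "spanning the score range" does not itself fix a spacing, and quantiles
  are robust to score-scale distortions where even spacing *in score*
  would collapse onto dense regions.
* `select_top_fraction()` (defaults fraction = 0.30, n = 14) reads "best
  30%" as a fraction of the *ranked list* (ceiling rounding), not of the
  score range — the standard reading for rank-based selection.
* `sample_random_controls()` draws the negative-control arm over the full
  four-base alphabet (wild type allowed), because randomized primers do not
  exclude the wild-type base; the b/d/h/v exclusion applies only to the
  designed library.

## Screen analytics

`normalize_activity()` divides each construct's mean replicate maximum by
the wild-type mean (A_rel, dimensionless, WT = 1). Mean-of-replicates is
normalized rather than normalizing each replicate first; with a common
wild-type denominator the two readings coincide, and mean-of-replicates is
the simpler estimator. Negative raw values are clipped to zero with a
warning; replicate SD is carried through on the normalized scale for
reporting.

`correlate_score_activity()` uses the Pearson coefficient with the
two-sided t-test and an OLS line with a pointwise 95% confidence band —
the linear-fit-plus-band presentation standard for score–activity panels.

`epistasis_table()` quantifies combinatorial interactions against the
multiplicative expectation: for WT-relative ratios the independence
expectation of a combination is the product of its parts, so the deviation
D = observed − expected flags synergistic rescue (D > 0: e.g. two dead
parts yielding an active triple) or incompatibility (D < 0: two
above-wild-type parts abolishing activity together). D is a
toolkit-defined statistic and is labelled as such in outputs.

`viability_concordance()` asks how often constructs above an in vitro
activity threshold (default 1/3 of wild type) support life, returning the
fraction and the full 2×2 table.

## Conservation

Conservation of an alignment column is 100 × (modal unambiguous base
count)/(non-gap unambiguous count); gaps and IUPAC ambiguity letters are
excluded from both counts. The modal-base metric is the declared default
(it measures "how conserved is this position" independent of any one
genome); a reference-base variant (`method = "reference"`) is provided for
analyses pinned to the E. coli letter. Columns map to reference numbering
by walking the ungapped reference (`map_columns()`, with an offset so that
local alignments report canonical positions), and `region_summary()`
reports the unweighted mean plus strict-threshold exceedance counts.

## What the generators emulate — and what they do not

* `make_ideal_helix()` builds coarse three-pseudo-atom residues (P, C1',
  base centroid) on ideal A-form geometry (rise 2.81 Å, twist 32.7°/bp,
  ~10.4 Å paired C1'–C1', ~5.9 Å consecutive P–P). That is sufficient for
  every geometric operation in scope (sphere selection, pairing geometry,
  PDB round trips) but carries no tertiary contacts, no full atomic
  detail, and no resemblance to any deposited structure.
* `simulate_screen()` draws activities from the stated link
  A_rel = max(0, α + β·(score − score_ref) + ε), ε ~ Normal(0, σ), with
  replicate fluorescence around A_rel·wt_fluor and a wild-type row fixed
  at 1. Defaults are the study conditions used throughout: 50 constructs,
  3 replicates, negative link with planted correlation ρ = −0.6 (σ derived
  as |β|·sd(score)·sqrt(1/ρ² − 1)). For selection experiments the link is
  anchored at the wild-type score (α = 1 at score_ref) with σ = 0.15,
  a modest screen-noise level. The link is linear-with-clipping; real
  screens saturate and have batch structure the generator does not model.
* `simulate_viability()` uses P(alive | A_rel > 1/3) = 0.85 and
  P(alive | A_rel ≤ 1/3) = 0.10 — an imperfect but predictive screen, with
  exceptions in both directions, as in vivo outcomes typically show.
* `simulate_alignment()` plants each column's modal base at the target
  frequency by exact counts (so planted conservation is recovered up to
  rounding), spreads the remainder uniformly over the other three bases,
  and rejects targets ≤ 25% (unreachable for a modal base with uniform
  remainder). Real alignments have phylogenetic correlation between rows
  and between columns; the generator's rows are independent, so passing
  tests demonstrate the *metric*, not robustness to phylogenetic
  structure.

Because screens and alignments are simulated, tests against them validate
the pipeline's statistics under known ground truth; they do not reproduce
any particular experimental dataset's values.

## Numerical choices and degenerate inputs

* Radius 0 gives an empty neighborhood; a selection naming residues absent
  from the structure errors with the missing ids.
* Empty pairing maps score 0; invalid bases error with their position.
* Duplicate score-file tags merge keeping the minimum (best) score; empty
  score files return an empty table with a warning; non-numeric scores
  error with the line number.
* Constant score or activity vectors make the correlation error rather
  than return NA.
* A wild-type mean of zero is an error (normalization undefined).
* All-gap alignment columns report missing conservation rather than 0.

## Problem sizes in the tests and acceptance script

The shipped test suite and `scripts/acceptance.R` run the full pipeline at
desk scale, the package's chosen study sizes: campaigns of 150 trajectories
× 300 cycles over the 6 561-member demo library, forward folding at
100 cycles × 50 models, screens of 50 (correlation) and 200 (viability)
constructs with 3 replicates, and simulated alignments of 1 614 rows
(matching the scale of published curated 23S alignments). Exhaustive
enumeration (3^8 and smaller) backs every oracle comparison.

## Known limitations

* The stand-in energy sees only pairing and stacking of the designed
  positions; it cannot reward non-canonical motifs a structural score
  would (e.g. a favorable non-Watson-Crick pair stabilized by context), so
  its campaigns converge harder onto Watson-Crick-rich optima than a real
  conformational search.
* mmCIF is accepted on input only; output is fixed-width PDB v3.3.
* The epistasis statistic assumes WT-relative ratios multiply under
  independence; activities near the clipping floor weaken that reading.
* Conservation is computed per column; no attempt is made to re-align or
  to weight sequences phylogenetically.
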