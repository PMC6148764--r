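---
title: "Methods: structure-guided consensus design and variant characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-guided consensus design and variant characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consenz)
```

## Overview

`consenz` implements the desk side of a consensus-engineering campaign
for an enzyme target: curate a homolog alignment, call per-position
consensus residues, prune candidates against a structural model, design
NNK saturation libraries for the survivors, and fit the biochemical
models used to judge the resulting variants. This vignette documents
the models and the choices behind every default, in the order a
campaign uses them.

## Homolog curation and consensus calling

The consensus hypothesis is that the residue carried by most family
members at an alignment column contributes more to stability than rarer
residues, so target positions deviating from a strong consensus are
candidate stabilizing substitutions.

**Identity.** Percent identity between two aligned rows is
`100 × matches / denominator`. The field uses several denominators; we
default to columns where *both* rows are non-gap, which is symmetric
and insensitive to terminal gaps, and expose `"shorter"` and
`"alignment"` as alternatives through the `policy` argument. A pair
with no shared non-gap column has undefined identity and raises an
error rather than returning 0 or 100.

**Curation window.** Homologs are kept when their identity to the
target lies in [30 %, 90 %]: closer sequences carry almost no
independent information, more distant ones are unreliable to align.
Near-duplicates among the survivors (> 95 % pairwise identity to an
already-retained row) are removed by a single greedy pass in input
order. Greediness is a deliberate choice: no clustering objective is
specified by the method, and a greedy pass is deterministic,
idempotent, and produces a removal log in which every dropped row
cites the one rule and the one retained sequence that triggered it.

**Profiles and calls.** Column profiles count the 20 standard amino
acids; `X` and gaps are tallied separately and excluded from
frequencies, so frequencies always sum to 1 over observed standard
residues and a column of only gaps/`X` yields no call. The consensus is
the argmax frequency; ties are broken alphabetically and flagged in the
output rather than silently resolved. Calls are mapped to 1-based
positions of the ungapped target (the numbering used in mutation names
such as N130D); columns where the target is gapped carry no position.

**Candidate threshold.** `min_frequency` defaults to 0.5 — a residue
carried by an absolute majority of the family. In published consensus
tables, positions near 55 % are treated as actionable consensus while
ones near 10 % are not, and 0.5 is the smallest threshold that can
never produce two qualifying residues at one column. It is a tunable
argument, not a constant.

## Tree-based representative selection

When the homolog set is large or lopsided, a subset representing the
main branches of the family tree gives a less biased consensus.
Distances are `d = 1 − identity/100` (with an optional Poisson
multiple-hit correction `−ln(identity/100)` for more divergent sets),
and the tree is classical Saitou–Nei neighbor joining. Two determinism
rules make trees reproducible: Q-criterion ties are broken by the
smallest (row, column) index pair in the current matrix, and negative
branch lengths — an expected artifact of NJ on non-additive data — are
clamped to zero with the pre-clamp value recorded on the tree object.
On additive matrices the implementation is exact: every leaf-to-leaf
path length reproduces the input entry (the test suite checks this to
1e-9 against 4- and 5-leaf matrices, and checks topologies against an
exhaustive least-squares search over all unrooted topologies).

"Main branches" is informal in the field; we operationalize it as
cutting edges in ranked order — internal edges first, by decreasing
length, then pendant edges, ties by child node index — skipping cuts
that do not increase the number of leaf-bearing groups, until `k`
groups exist. For `k ≤ n − 2` this reduces to cutting the `k − 1`
longest internal edges; allowing pendant cuts afterwards lets `k = n`
mean "every leaf its own group". Each group's representative is its
medoid (minimum summed within-group distance), ties lexicographic.

## Structural candidate filtering

Three rejection rules prune the candidate list against a structural
model before any cloning. All thresholds are arguments of
`filter_config()`; the defaults are:

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `active_site_cutoff` | 5.0 | Å | exclusion shell around the catalytic machinery; strictly-less-than, so exactly 5.0 passes |
| `kd_threshold` | 0 | — | Kyte–Doolittle ≥ 0 counts as hydrophobic (A, C, I, L, M, F, V) |
| `surface_threshold` | 0.25 | rel. SASA | common surface convention, boundary inclusive |
| `core_threshold` | 0.10 | rel. SASA | common core convention, boundary inclusive |
| `probe_radius` | 1.4 | Å | water probe |
| `n_points` | 960 | — | ~1–2 % SASA accuracy (see below) |
| `hbond_cutoff` | 3.5 | Å | donor–acceptor heavy-atom distance |
| `salt_cutoff` | 4.0 | Å | side-chain N(+)–O(−) distance |

**Rule 1 (active-site proximity).** The active site must be supplied
explicitly (metal ions by element, liganding residues by number) — it
is biological knowledge, not something inferable from coordinates
alone. Distance is the all-atom minimum between the candidate residue
and the site, because the informal "within 5 Å of the active site"
criterion carries no atom qualifier; a Cα-only mode exists behind
`distance_mode = "ca"`.

**Rule 2 (hydrophobicity mismatch).** Proposals that would put a
hydrophobic residue on the surface or a hydrophilic one in the core are
rejected. Location comes from Shrake–Rupley SASA normalized by the
theoretical Gly-X-Gly maxima of Tien et al. (2013); intermediate
residues (0.10 < rel. SASA < 0.25) pass, since neither direction of
mismatch is established there. The SASA implementation uses a
deterministic golden-spiral point set, so results are exactly
reproducible; a single isolated atom recovers its closed-form sphere
area exactly, and two overlapping spheres agree with the analytic
spherical-cap formula within 2 % at 960 points.

**Rule 3 (interaction loss).** Mutant structures do not exist at
filtering time, so the rule is capability-based: for each hydrogen bond
or salt bridge the wild-type residue makes *through side-chain atoms*
(geometric criteria above, with the peptide-bond O(i)–N(i+1) pair
excluded as a bonded 1-3 contact), the proposed residue type must be
able to reproduce it — same charge class for salt bridges, a polar
side chain for hydrogen bonds. Backbone interactions survive any
substitution and never reject.

Every verdict carries the measured evidence (distance, relative SASA,
the specific lost interaction), rejections list their rules, and
verdicts are independent of candidate order. Residue-numbering
mismatches between sequence coordinates and the model's author
numbering are configured explicitly (`numbering_offset`) and wrong
wild-type residues fail loudly rather than silently filtering the
wrong position.

## NNK library design

NNK (N = A/C/G/T, K = G/T) is the standard saturation scheme: 32 codons
covering all 20 amino acids with one stop (TAG). Primer pairs follow
the QuikChange convention — the forward primer is the coding-strand
slice around the target codon with the codon replaced by the scheme
(default flank 15 nt per side, configurable), the reverse primer its
full IUPAC reverse complement (so the MNN on the reverse strand is the
same library). The attached melting-temperature estimate is the simple
GC formula `64.9 + 41(GC − 16.4)/L` with degenerate bases counted by
expected GC; it is a QC annotation, not a thermodynamic model.

Library coverage treats colonies as i.i.d. draws over the scheme's
codons (a per-codon weight vector is accepted when transformation bias
matters); stop-codon clones are wasted draws. The probability that `n`
colonies cover all 20 amino acids is computed by exact
inclusion–exclusion,

P(all seen) = Σ_{S ⊆ AA} (−1)^{|S|} (1 − p(S))^n,

with amino acids grouped by equal probability so the alternating sum
stays small and exact. `colonies_for_coverage()` inverts this by
binary search (the probability is monotone in `n`). The traditional
"at least 200 colonies" rule of thumb corresponds to a computable
confidence rather than a guarantee, and the package reports the
probability instead of asserting sufficiency.

## Characterization models

**Thermal inactivation.** Residual activity after incubation at the
stress temperature is fit as first-order decay by ordinary least
squares of ln Y on time — exactly the conventional `ln Y = −k_d X + b`,
with `t½ = ln 2 / k_d` so the identity `t½ × k_d = ln 2` holds for
every fit by construction. Points with Y ≤ 0 cannot enter a log fit and
are excluded with a warning; a non-decaying series yields `kd ≤ 0`, is
flagged, and reports an infinite half-life rather than a negative one.
A nonlinear exponential mode (`method = "nonlinear"`) exists for noisy
data where log-transformation over-weights late points.

**Melting.** The melt curve is fit as a two-state Boltzmann sigmoid
with linear native and denatured baselines; T_m is the transition
midpoint. No model is canonical for this fit, and the two-state sigmoid
is the minimal one with a defined midpoint. The fitter is
signal-agnostic (CD ellipticity at 222 nm, calorimetric, or any other
monotone-transition signal), and scan rate is treated as metadata, not
modeled. Initialization: T_m at the steepest numerical derivative,
baselines from the first and last quarters of the scan. Degenerate
inputs are rejected on two grounds: a sigmoid that fits no better than
a straight line by AIC, or a fitted transition amplitude below 0.1 % of
the signal range (a strictly linear curve can otherwise be "fit"
perfectly by a sigmoid of zero amplitude).

**Kinetics.** `v = Vmax·S/(Km + S)` by nonlinear least squares,
initialized from the Hanes–Woolf linearization (S/v vs S), which is
well-conditioned at both low and high substrate. `kcat = Vmax/[E]`
requires the enzyme molar concentration, which must be supplied by the
user — it cannot be recovered from rate data. Catalytic efficiency is
reported in L/(mmol·s): `kcat/Km × 1000` with kcat in 1/s and Km in
μmol/L. Fits with Km beyond the largest tested substrate concentration
are flagged non-saturating.

**Activity.** Beer–Lambert conversion of an absorbance slope:
`rate = slope/(ε·path)`, default ε = 25 000 L/(mol·cm) (conjugated
diene at 234 nm). One IU is interpreted as the enzyme producing
1 μmol/L product per minute in the assay — activity-unit definitions
quoted without a time base are conventionally per minute, and the
interpretation is stated here because it scales specific activity
directly.

**Comparison reports** follow variant-table conventions: folds
(half-life, specific activity, efficiency) to one decimal, ΔT_m to two
decimals, ΔT_opt as a plain difference, K_m as integer percent
*decrease* and k_cat as integer percent *increase*. Missing fields
propagate as missing, never as defaults; zero-valued wild-type
denominators are errors.

## What the synthetic generators emulate

The generators produce every input type under a fixed seed, and each
noiseless output is exactly inverted by its fitter — that pairing is
the backbone of the test suite.

* `simulate_homolog_family()` substitutes exactly
  `round((1 − id/100)·L)` positions per homolog, so realized identities
  equal their targets; a designated column can be forced to an exact
  consensus fraction. There are **no indels** (the family is its own
  alignment) and no phylogenetic correlation between sequences —
  substitutions are independent. Consequences: gap handling is
  exercised by hand-built alignments, not by this generator, and
  consensus frequencies in simulated families are binomial-like rather
  than clade-structured. Passing tests demonstrate correctness of the
  counting and calling machinery, not robustness to real alignment
  error.
* `make_toy_structure()` extends an ideal α-helix (φ = −57°, ψ = −47°,
  ω = 180°, standard bond geometry) with Cβ pseudo-side-chains by
  internal-coordinate (NeRF) construction, optionally placing a metal
  ion at a stated distance from a chosen residue. It reproduces the
  diagnostic helix observables (consecutive Cα–Cα ≈ 3.8 Å, backbone
  O(i)→N(i+4) hydrogen bonds ≈ 3.1 Å) but has no packed core: almost
  every residue is surface, so core-classification logic is tested
  through `classify_location()` directly. Polar side-chain atoms for
  interaction fixtures are appended with `add_atoms()`.
  `make_filter_demo()` combines these into a 14-candidate set in which
  exactly four candidates violate one rule each, so the full filter
  pipeline has a known answer (ten survivors).
* `simulate_decay()/simulate_melt()/simulate_rates()` return model
  values times `(1 + N(0, noise_sd))`, clamped positive — multiplicative
  noise matching the percent-style error bars of enzyme tables. The
  acceptance script and test suite use noise of 2–5 % and 200 seeded
  replicates per model; mean recovery within 5 % of truth is the
  pass criterion. Problem sizes throughout (families of ~20 sequences
  of 60–100 residues, helices of 8–20 residues, 16–71-point assay
  series) are chosen as the smallest sizes at which every behavior the
  tests assert is expressed.

## Known limitations

* Identity-based distances saturate for deep divergence; the Poisson
  correction helps but no rate-matrix model is provided.
* The interaction-loss rule is capability-based and geometric; it does
  not score interaction strength, model side-chain rearrangement, or
  predict compensating interactions a mutant might gain.
* SASA uses a fixed Bondi-style radius per element (no united-atom or
  per-atom-type radii) and structures are treated as rigid.
* Hydrogen-bond detection is heavy-atom-only (no explicit hydrogens or
  angular criteria), which over-counts marginal contacts such as
  i→i+3 helix pairs.
* The coverage model assumes colonies are independent draws; real
  libraries have transformation and growth bias beyond a static weight
  vector.
* Melting fits assume a two-state transition; multi-domain proteins
  with staged unfolding need a different model.
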