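---
title: "Methods: joint-annotation statistics, domain segmentation and template coverage"
author: "centroshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-annotation statistics, domain segmentation and template coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroshape)
```

# Scope and model

`centroshape` analyses the structural composition of a protein cohort —
typified by the human centrosomal proteome, which is unusually rich in
intrinsically disordered and coiled-coil regions — from per-residue
annotation tracks. The package does not run disorder, coiled-coil or
secondary-structure predictors; it imports their per-residue outputs
(or generates ground-truth tracks synthetically) and implements the
downstream statistics and decision procedures:

1. **Joint-annotation residue statistics.** For a set of proteins with
   aligned boolean disorder and coil tracks (and optionally an H/E/C
   secondary-structure track), residues are pooled over the whole set and
   tabulated over the joint categories. The central statistic is the
   log-ratio propensity
   $$\mathrm{Prop}(\mathrm{coil}\,\&\,\mathrm{dis}) =
     \ln P(\mathrm{coil}\,\&\,\mathrm{dis}) - \ln P(\mathrm{coil})
     - \ln P(\mathrm{dis}),$$
   which is 0 under independence and positive when the two annotations
   co-occur more often than chance.
2. **Putative-globular-domain segmentation.** Each sequence is partitioned
   by priority into SMART domains, coiled-coil stretches, disordered
   stretches and residual regions, and two decision rules call globular
   candidates (see below).
3. **Template selection and coverage.** Candidate homology templates are
   filtered by significance and identity, selected greedily by
   identical-residue count with an overlap allowance, and the resulting
   modeled coverage is cross-tabulated against the disorder/coil
   annotation.
4. **Interaction-network summaries.** Degree, local clustering and
   betweenness centrality of the undirected interaction graph.

# Conventions and parameters

All coordinates are 1-based inclusive; every file the package writes
states this in a header comment. Set-level fractions are
**residue-weighted** (pooled counts over all residues), because
proteome-composition statements of the form "x% of the residues" are
defined that way; per-protein length fractions are available separately
through `perProteinFractions()` for distribution plots.

The natural logarithm is used in the propensity. The base is a genuine
choice point: with the conventional centrosomal fractions (dual 12.4%,
coil-only 0.7%, disorder 57%) the natural log gives 0.51 and the control
fractions (3.3%, 0.7%, 39%) give 0.75, whereas base-10 would give 0.22
and 0.33. The package adopts ln and encodes both worked values as tests.
Likewise $P(\mathrm{coil})$ in the denominator is the full coil marginal
(dual plus coil-only): `0.124 / (0.131 × 0.57)` reproduces the expected
value, whereas using the coil-only fraction does not.

Decision thresholds (all configurable, defaults in parentheses, units =
residues unless stated):

| rule | default | strictness |
|---|---|---|
| annotation stretch run length | 20 | strict: runs must exceed 20 |
| dual-coverage protein count | 20% of length | strict |
| SMART condition-1 span | 30 | inclusive: at least 30 |
| condition-2 region length | 40 | strict: more than 40 |
| condition-2 Z score | 3 | strict |
| condition-2 disorder+coil content | 30% | strict: below 30% |
| identity discard for experimental interest | 40% | strict: above 40% |
| hit filter: true-positive probability | 95% | strict |
| hit filter: span | 30 | strict |
| hit filter: identity (HMM channel) | 20% | strict |
| hit filter: identity (high-identity channel) | 70% | strict |
| overlap allowance: new residues | 30 | inclusive: at least 30 |

The strict/inclusive reading of each bound follows the wording of the
underlying protocol ("more than", "at least", "below") and each boundary
is pinned by a dedicated test. The span filter ("more than 30") and the
overlap allowance ("at least 30") are deliberately kept as two
independent parameters even though both default to 30.

**Partition truncation.** The priority order is SMART > coil stretch >
disordered stretch > residual. The protocol states the priority but not
what happens when a higher-priority interval cuts into a stretch; the
package re-applies the strict run-length test to every surviving piece,
so a truncated remnant of 20 or fewer residues reverts to residual. This
keeps the definition of a "stretch" self-consistent under truncation.
Overlapping SMART rows are merged into their union (nested repeats are
common in SMART output) with a warning.

**Condition-2 disorder/coil content.** Whether "the sum of disordered and
coiled-coil residues" counts dually annotated residues once (union) or
twice (additive) is not decidable from the protocol wording; both modes
are implemented (`dcMode = "union"` is the default, `"sum"` available)
and the choice is recorded in the call output. The decision itself uses
the region's eligibility (strictly more than 40 residues), the alignment
Z score and the local disorder/coil fraction; the alignment's match
length is carried as evidence but not re-tested.

**Greedy template selection.** "Templates yielding the maximum number of
identical residues" is implemented as a descending greedy pass: hits are
ranked by identical residues (explicit counts take precedence; otherwise
round-half-up of identity × span), ties broken by longer span, then
template id, then query start — a total order, so the output is invariant
to input permutation. The first hit is accepted; each later hit is
accepted only if it contributes at least 30 query residues not yet
covered. Accepted fragments with identity ≥ 95% are flagged
`retrieve_only` (an existing structure would be downloaded rather than
modeled), and the 6-residue ceiling on template-free gaps bridged during
model building is recorded as metadata; no 3-D modeling is performed.

**Network conventions.** Betweenness is the unnormalized count over
unordered node pairs, endpoints excluded, with fractional credit among
multiple shortest paths, computed within connected components (pairs in
different components contribute nothing). The average clustering
coefficient is the mean of local coefficients with degree-<2 nodes
counted as 0 — one of the two standard conventions, chosen and logged.
Because the published average degree of the 354-edge/167-node centrosomal
interaction network (3.65) matches neither $2E/V$ over interacting nodes
(4.24) nor over all 361 proteins (1.96), `graphMetrics()` reports both
conventions and neither is treated as a reference value. The graph
machinery is delegated to igraph; the package's tests verify the
betweenness convention against an explicit enumeration of all shortest
paths on small graphs.

# Built-in stand-in predictors

To make the pipeline executable with no external tools, the package ships
two deterministic stand-ins, clearly flagged `source = "builtin"`; they
are *not* reimplementations of the published predictors whose outputs the
importers expect, and set-level reports always carry the track provenance
so builtin and imported tracks are never silently mixed.

* `coilScoreTrack()` scores a sliding window (default 21 residues) at all
  7 heptad registers as the geometric mean of position-weighted residue
  propensities; a residue takes the maximum score over covering
  placements and is called coil at score ≥ 1. The shipped propensity
  table favours L/I/V/M at core positions a/d and E/K/Q/R at edge
  positions e/g, so idealized leucine-zipper repeats score ≈ 2 while
  low-complexity non-coil sequence stays below 1. The table is chosen for
  deterministic testability, not fidelity to any published matrix, and
  score→probability calibration is deliberately omitted.
* `disorderIndexTrack()` evaluates the classical charge–hydropathy index
  $a\langle H\rangle - |\langle q\rangle| - b$ with $a = 2.785$,
  $b = 1.151$ and Kyte–Doolittle hydropathy rescaled to $[0,1]$;
  a residue is disordered when the index is negative. Whole-sequence mode
  (default) is permutation-invariant; windowed mode uses a centred,
  edge-shrunk window. `X` maps to the hydropathy midpoint and zero
  charge.

# The synthetic-data generator

`syntheticSpec()` + `sampleProteinSet()` generate cohorts whose defaults
are the study conditions: log-normal lengths with mean 796 residues
(599 for a control-like cohort) and log-scale SD 0.7 for the heavy right
tail; pooled residue fractions P(disorder) = 0.57, P(coil & disorder) =
0.124, P(coil & ¬disorder) = 0.007, P(disorder & helical) = 0.30; and
~15% of proteins whose dual fragments cover more than 20% of their
length. Sequences are assembled from five segment types (globular,
disordered loop, disordered helical, disordered coil, ordered coil) with
type-specific residue composition — heptad-patterned residues for coil
segments, disorder-promoting composition for disordered segments — and
mean segment lengths of 150/40/25/60/30 residues, giving tracks a
realistic run-length structure.

The generator is **quota-based**: each protein receives integer residue
budgets per segment type (dual-rich proteins draw their dual fraction
from U(0.22, 0.38); the remainder is rebalanced across the other
proteins), and a final correction pass moves single residues between
budgets and the globular reservoir until the pooled counts equal the
targets up to rounding. Targets are therefore recovered essentially
exactly — far inside the 3-binomial-SE recovery band used by the tests —
while per-protein fractions still vary realistically. Tracks come from
the generating labels, not from the built-in predictors, so statistics
tests are independent of predictor quality; running the predictors on the
generated sequences is a separate, deliberately harder exercise.

Template hits are placed preferentially on globular segments, with hit
probability and covered fraction calibrated at generation time against
the realized eligible segment mass so that the expected modeled fraction
is 57.2% of globular residues and 5.4% of disordered-or-coil residues
(jointly ≈ 27.6% overall). Identity is drawn from a bimodal mixture with
weights 99 (low mode, ≈ 25%) : 174 (high mode, ≈ 92%), so the identity
histogram of accepted fragments peaks below 30% and above 90%. All
generated hits pass the significance filters, mirroring a hit table that
already survived an upstream search. Graphs are uniform random
(`sample_gnm`) or preferential-attachment with exact node and edge
counts.

All randomness flows from the single `seed` of the spec: protein/track
generation, template hits and the graph use the seed plus fixed offsets
1, 2 and 3 respectively, and each sampler restores the caller's RNG
state, so the three samplers are independently reproducible in any call
order.

What the generator does *not* emulate: biophysically realistic sequence
design, homology to real structures, correlations between annotation
content and network position, and predictor noise (tracks are exact
labels). Passing recovery tests therefore validates the statistical
machinery, not the behaviour of external predictors on real proteomes.

# Numerical and degenerate-input choices

* `propensity()` refuses arguments outside (0, 1] rather than silently
  returning −Inf; pooled statistics report `NA` when a marginal is zero.
* Conditional fractions with empty denominators (e.g. helical content
  among disordered residues of a set with none) are reported as absent
  (`NA`), never as 0.
* Identical-residue counts round half up (`floor(x + 0.5)`), so a
  100-residue hit at 50.5% identity counts 51.
* Isoform length ties are broken by the lexicographically smallest
  protein id (radix order, locale-independent); the upstream convention
  mentions no ties, and determinism requires a rule.
* The bootstrap in `compareSets()` resamples proteins, not residues,
  because residues within a protein are correlated through its segmental
  annotation structure; the seed is mandatory and the result is
  bit-reproducible.
* Sequences shorter than the coil window give an all-false track with a
  warning rather than an error, so cohort-level runs do not abort on
  short peptides.

# Problem sizes used by the test-suite

Unit tests run on cohorts of 5–150 generated proteins; the recovery
checks use one cohort of 500 proteins at mean length 796 (~390k pooled
residues), the segmentation oracle 1000 random layouts of 60–300
residues, the greedy-selection oracle 500 random hit sets, and the
betweenness oracle 200 random graphs of at most 8 nodes, where explicit
enumeration of all shortest paths is feasible. These sizes make every
oracle comparison exact or rounding-limited while keeping a full test run
under a minute of compute.

# Known limitations

* External predictors and alignment tools are out of scope; imported
  tracks are trusted after 1:1 alignment checks against the sequence.
* The supplementary sequence sets of the original study are not bundled;
  the mean-length acceptance check runs only when those FASTA files are
  placed under `inst/extdata/`.
* Homology models themselves (coordinates, energies, stereochemistry) are
  out of scope; the package accounts only for which residues *could* be
  modeled.
* The segmentation and selection procedures are deterministic re-statements
  of a published experimental-design protocol; where its text is ambiguous
  (truncation rule, union vs additive counting, tie-breaking) the choice
  is documented here and kept configurable where it matters.
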