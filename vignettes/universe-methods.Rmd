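---
title: "Methods: building and scoring consensus interval universes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and scoring consensus interval universes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniflex)
```

This vignette documents the models behind `uniflex`, the conventions and
numerical choices it commits to, and what its synthetic tests do and do not
demonstrate.

## Coordinates and the flexible interval

All coordinates are 0-based, half-open (BED). A flexible consensus region is
stored as four coordinates `start <= core_start <= core_end <= end`: the
flexible start interval is `[start, core_start)`, the core
`[core_start, core_end)`, the flexible end interval `[core_end, end)`. A
fixed region is the degenerate case `core_start == start`,
`core_end == end` (empty boundary intervals), which makes the fixed case an
exact embedding into the flexible one — round-tripping through the
extended-BED writer preserves all four coordinates bit-exactly. An empty
core (`core_start == core_end`) is structurally allowed; among the
builders, CCF refuses to emit regions that never reach the core cutoff
(a region without a core is undefined), while the path-based builders can
produce empty cores when a start run directly abuts an end run.

Strand is ignored throughout.

## Signal tracks

`compute_tracks()` summarizes a collection by three per-base counts:
starts *s(i)*, coverage *c(i)*, ends *e(i)*. Two conventions matter:

* **Per-set merging.** Each region set is merged first, including touching
  intervals (`[a,b) + [b,c) -> [a,c)`), so one experiment contributes at
  most 1 to any track position and abutting fragments count as one region
  for boundary purposes. A consequence worth knowing: the count of sets
  ending at position *i* and the count starting at *i + 1* can never sum to
  more than *n*, which is why the path-based builders never split a
  uniformly covered stretch into two abutting regions (the split can at
  best tie, and ties resolve toward background).
* **Ends at the last covered base.** *e(i)* counts sets whose region's last
  covered base is *i* (the exclusive end minus one). This keeps all three
  tracks supported on covered bases — a position can simultaneously be
  covered and be an end — which the likelihood model's label definitions
  assume. It also yields the balance identity
  `c(i) - c(i-1) = s(i) - e(i-1)` used as a self-check in the tests.

Tracks are stored run-length encoded (maximal runs of constant
`(s, c, e)`), with dense per-chromosome materialization on demand
(`track_vectors()`). Exactness is contractual; the representation is not.
The sweep is event-sorted, so memory scales with the number of interval
boundaries, not genome size; the decoders materialize one chromosome at a
time.

## The coverage-cutoff family

With total base coverage `S_c` and genome size `g`, the optimal cutoff is
the smallest integer satisfying `x >= S_c / g`, clamped into `[1, n]`:
`x* = clamp(ceiling(S_c / g), 1, n)`. Taking the smallest admissible value
maximizes recall among admissible cutoffs. `cc_universe()` keeps maximal
runs with `c(i) >= x`; `x = 1` reproduces the union and `x = n` the
intersection exactly (both identities are tested against independently
built universes).

`ccf_universe()` needs a lower and an upper cutoff. When not supplied, the
package uses a Poisson-style one-standard-deviation band around `x*`:
`x_lower = max(1, x* - ceiling(sqrt(x*)))`,
`x_upper = min(n, x* + ceiling(sqrt(x*)))`. This band is a design choice of
this package — the underlying idea (a confidence interval around the
optimal cutoff) does not pin down a formula — and both cutoffs are
overridable everywhere they appear.

## The label model and the maximum-likelihood path

Each track probability is a smoothed frequency
`p_t(i) = (t(i) + alpha) / (n + 2 alpha)` with pseudocount
`alpha > 0` (default 1: add-one smoothing keeps every score finite and is
the obvious default when nothing is known about the collection). A label
asserts a subset of tracks "on": S asserts starts and coverage, C coverage,
E ends and coverage, B nothing — start and end positions are themselves
covered under the end convention above. The label score is the Bernoulli
log-likelihood over the three tracks.

`lh_universe()` maximizes the summed label score over all paths consistent
with the grammar `B* (S+ C* E+)* B*` (transitions B→{B,S}, S→{S,C,E},
C→{C,E}, E→{E,B,S}; a chromosome must begin in B or S and end in B or E).
Chromosomes are decoded independently. The dynamic program is exact; its
score is tested for equality against exhaustive enumeration of all valid
labelings on small genomes. Equal-score ties are broken toward B, then S,
C, E — deterministic output, biased against spurious regions. Decoded S
runs become flexible start intervals, C runs cores, E runs end intervals.
A single covered base cannot satisfy `S+ ... E+` and falls back to
background; the shortest emittable region is 2 bp (an S directly followed
by an E).

One behavioral property deserves emphasis: labeling a position S rather
than C pays `logit p_start(i)`, which is negative unless more than half the
sets start at that exact base. The optimal path therefore emits *narrow*
boundary runs — typically 1–3 bp at realistic jitter — located near the
mode of the start/end counts, not runs spanning the full observed spread of
boundaries. Decoded flexible intervals should be read as "most likely
boundary position(s)", not as tolerance bands containing every plausible
boundary. The width-recovery tests in the package quantify this: with no
boundary jitter the true boundaries are recovered exactly; with jitter the
decoded intervals sit within a few bases of the truth but do not reliably
contain it.

## The HMM

`hmm_universe()` keeps the same four states but replaces data-derived
scores with a tunable model: row-stochastic transitions restricted to the
grammar above, and per-track Binomial(n, θ) emissions. Defaults:
self-transitions 0.9 for B and C (long stretches) and 0.5 for S and E
(short boundary runs), remaining mass split evenly over the allowed moves;
θ = 0.5 for the tracks a state asserts and 0.02 otherwise — a weakly
informative "half the sets agree" prior rather than a fitted value. All of
it is user-tunable via `hmm_params()`, and validation rejects
structurally-required transitions with zero probability (they would make
the grammar undecodable). The initial distribution follows the background
row (B with 0.9, S with 0.1); decoding is exact Viterbi (tested against
brute-force path enumeration) with the same tie-break as the LH builder.

By default the HMM is fit-free: the point of the model is tunability and
cross-collection consistency, not training. `refine = TRUE` runs hard
(Viterbi) EM on the emissions — decode, re-estimate each θ as the mean
observed track fraction within the decoded state (with a small pseudocount
and clamping to (0,1)), repeat until the path stabilizes. Hard EM was
chosen over Baum–Welch deliberately: it is simple, monotone in practice at
these problem sizes, and sufficient for adapting θ to a collection; users
wanting full posterior training should export the tracks and use a
dedicated HMM package.

## Fit metrics

**F10.** Confusion counts are base-level: TP = bases in both universe and
query, FP = universe only, FN = query only. For a flexible universe the
full outer span counts as covered — the flexible interval asserts the
region may extend that far, and penalizing it as FP would double-count the
uncertainty it encodes. F10 is the F-beta score with β = 10; edge cases are
pinned down as: F10 = 0 when TP = 0, recall = 1 against an empty query
(vacuous), precision = 0 for an empty universe. Collection score = mean
over sets.

**RBD.** Boundaries are type-matched (query starts compare only to
universe starts, ends to ends); unmatched pairing would reward merged
regions. Distances are medians per direction; the combined score is the
weighted harmonic mean of the closenesses `1/(1 + d)` — so `d = 0` maps to
1 with no division by zero — with default weights 10 (query→universe) : 1
(universe→query), mirroring the recall-over-precision asymmetry; the
weights are configurable. For flexible universes a query boundary inside
the (closed) boundary interval scores 0; otherwise the distance to the
interval's nearest edge. When one side has no boundary on a chromosome,
the other side's boundaries there get the maximal coordinate observed on
that chromosome — a finite worst case rather than an error, chosen so a
universe missing one chromosome is penalized but comparable. RBD is
invariant under translating all inputs, and the flexible variant can never
be worse than the fixed one on the same universe (the interval contains
the fixed point).

**Likelihood.** A fixed region labels its first base S, last base E,
interior C (width-1: S only; width-2: S then E — the grammar makes the
core optional but not the boundaries); everything else is background. The
reported `delta` subtracts the all-background likelihood, so the empty
universe scores exactly 0 by construction, not by convention. The flexible
variant scores the whole outer span on the coverage track and replaces
each single-base boundary term with
`log(min(1 - 1e-12, sum of p_t over the boundary interval))`; the cap
keeps the aggregated probability a probability. Under this rule, widening
a boundary interval within a fixed outer span can only increase the score,
and the flexible score dominates the fixed score for the same universe —
both directions are asserted in the tests. Natural log throughout.

`assess_universe()` orchestrates any subset of the metrics and returns an
object with `tidy()` (per-set table), `glance()` (one-row summary) and
`autoplot()` methods; `write_report()` serializes JSON and TSV at six
decimals.

## The synthetic generator

`simulate_collection()` emulates the failure modes a consensus method must
survive: boundary shift (rounded Gaussian jitter per boundary, truncated so
`start < end` stays on the chromosome), dropped regions (per-set Bernoulli
dropout), and extraneous regions (Poisson count per set, uniform placement,
widths from the locus distribution). True loci are placed with gaps of at
least `8 * jitter_sd` so jittered observations cannot bridge loci. Defaults
— 10 sets, 50 loci on a 100 kb genome, width 300 ± 50, jitter 5, dropout
0.2, noise 2/set — describe a small but realistic peak collection: tens of
percent coverage heterogeneity across sets, boundary disagreement of ±1 sd
per experiment, and a noise floor low enough that true loci dominate.
Ground truth is returned as a flexible universe whose boundary intervals
span ±2 jitter sd around each true boundary.

What the generator does *not* model: signal-strength variation (all loci
are equally likely to be observed), correlated dropout (cell-type
structure), width heterogeneity between loci classes, chromosome-scale
coverage gradients, and mappability holes. Passing tests on these fixtures
therefore demonstrate algorithmic correctness and the documented
qualitative behaviors, not performance on any particular real collection.

Test problem sizes are deliberately small — oracle-equivalence checks run
on genomes of 4–12 bp (where exhaustive enumeration is feasible) up to
1 kb (per-base brute force), and end-to-end checks on 30–100 kb genomes
with 100 seeded replicates — chosen so the full suite exercises every code
path in minutes while keeping the brute-force oracles exact.

## Known limitations

* Decoded LH/HMM boundary intervals are narrow (see above); they locate
  boundaries well but are not containment intervals for the underlying
  boundary distribution.
* The default HMM parameterization is a qualitative prior; on collections
  with very high coverage heterogeneity it can over-segment, which is what
  `refine = TRUE` and manual `hmm_params()` tuning are for.
* Tokenization is plain interval overlap against outer spans; no
  flexibility-aware tokenizer is provided yet.
* No bigWig/bigBed/tabix support; files are plain BED/bedGraph text.
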