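---
title: "From isolated vertebrae to body size, paleotemperature and trees: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From isolated vertebrae to body size, paleotemperature and trees: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosnake)
```

This vignette is the package's account of its science: what each model
assumes, which parameters matter, how the numerics are pinned down, and
what the simulation-based tests do and do not demonstrate.

## 1. Vertebral morphometrics

Most extinct madtsoiid snakes are known exclusively from precloacal
vertebrae, so all downstream inference starts from linear measurements
(mm) and angles (degrees) of isolated or articulated vertebrae. The
package stores measurements exactly as read — missing values are
representable and propagate as missing, never as zero — and computes the
descriptive ratio suite (`coW/coH`, `cnW/cnH`, `ncW/ncH`, `zsW/zsH`,
facet proportions, `nsH/tvH`, `prW/cL`, `poW/cL`) only where both
operands were recorded.

Trunk-position classification follows the standard anatomical criteria
in priority order: a hypapophysis marks the anterior trunk (ATV); a
chisel-shaped posterior process of the hemal keel marks the mid-trunk
(MTV); otherwise the neural-arch-width criterion applies — a vertebra
whose width exceeds its centrum length (`width/cL > 1`) lies anterior to
the posterior trunk and is treated as MTV, while `width/cL <= 1` is
labelled posterior trunk. The literature cites this criterion without
fixing the operand, so the width proxy defaults to the
trans-prezygapophyseal width `prW` and can be switched to `poW`; the
boundary case `width/cL = 1` is deliberately *not* anterior (strict
inequality). Scope is precloacal only: the cloacal/caudal class exists
in the vocabulary but is never assigned.

Reported ratios and metre renderings use half-up (commercial) rounding
at a caller-chosen precision, matching how such values are printed in
descriptive work; stored values are never rounded.

## 2. Body-length allometry

Total body length (TBL) is estimated from zygapophyseal widths under
two regression forms, both operating in millimetres on both axes:

* `LINEAR`: `TBL = a·width + b`, appropriate where the calibration
  measurements are approximately normally distributed on the raw scale;
* `LOG10LOG10`: `log10(TBL) = a·log10(width) + b`, the standard
  normalizing transform for power-law allometry.

Three published predictive equations ship as built-ins (`A60`, `A65` on
`poW`; `C` on `prW`). The units contract was verified internally: the
log-log model evaluated at the largest recorded `prW` of 111.4 mm yields
about 15,218 mm ≈ 15.2 m, which is the scale on which these equations
are used. Metres are a rendering (half-up, one decimal), never the
computation scale.

Fitting uses ordinary least squares (`stats::lm`) after the appropriate
transform; reported statistics are r², the two-sided slope *t*-test
(n − 2 df), and a residual prediction error expressed on the response
scale — for the log-log form the one-sigma multiplicative error
evaluated at the geometric-mean response, a deliberate convention since
a log-scale sigma has no single additive mm equivalent. Prediction
intervals are the standard OLS intervals, symmetric on the fitted scale
and back-transformed for log-log models; they require the fitted design,
so built-in models (which carry coefficients only) do not provide them.

Key assumptions to keep in mind: the built-in calibrations come from
extant boines and a broad extant-snake sample, whereas no
intracolumnar-variation model exists for madtsoiids, so estimates from
vertebrae whose exact column position is unknown inherit that
uncertainty; and the regressions are applied to the *largest* mid-trunk
vertebrae, so the estimate is of maximum size in the collection, not
mean size.

## 3. Metabolic-scaling paleothermometry

A poikilotherm's maximum attainable body length is limited by ambient
temperature through mass-specific metabolic rate. Anchored on a modern
analogue of maximum length `TBL_M` living at mean annual temperature
`MAT`, a fossil maximum length `TBL_v` implies

\[
\mathrm{MAPT} = \mathrm{MAT} + 3\,\alpha\,10\,^{\circ}\mathrm{C}\,
\frac{\log_{10}(TBL_v/TBL_M)}{\log_{10} Q_{10}}
\]

with defaults `MAT = 26.5` °C, `TBL_M = 10.05` m (reticulated python,
the longest extant snake), `Q10 = 2.6` (pythonid mass-specific metabolic
rate ratio per 10 °C) and metabolic scaling exponent `α = 0.17`. Because
`3·0.17·10 = 5.1` exactly and `log10(2.6) ≈ 0.415`, the conventional
simplified form replaces the coefficient pair with `5.1 / 0.41`.

The package's default is the **exact** form (it uses `log10(2.6)` rather
than the truncated 0.41); the simplified form is provided because that
is how the equation is usually printed, and reports always show both
with their difference. Over 5–20 m the two agree within 0.05 °C.
Chaining the 15.2 m maximum estimate through the simplified form gives
28.74 °C (28.7 at one decimal); published roundings of this chain are
sometimes 0.1 °C lower (28.6 °C), a discrepancy attributable to
intermediate rounding of the inputs, which the package documents rather
than reproduces — values here are computed at full precision and rounded
only for display. Both forms satisfy `MAPT(TBL_M) = MAT` identically,
are strictly increasing and log-linear in `TBL_v` (doubling the length
adds a constant increment), which the tests assert as properties.

The model's assumptions are strong: a single modern analogue calibrates
the curve, phylogenetic distance between the analogue and an extinct
clade is ignored, and only the endpoints of the body-length range are
propagated (no formal uncertainty propagation) — matching how the method
is used in practice.

## 4. Morphological maximum parsimony

### Matrix model and I/O

Character-taxon matrices hold integer states 0–9 per cell, polymorphic
cells as state sets, `?` (missing) and `-` (inapplicable), per-character
ordering (`UNORDERED`/`ORDERED`), activity and integer weights. Both TNT
`xread` (with `ccode` for ordering/activity/weights, 0-based indices)
and NEXUS `CHARACTERS` (with `SYMBOLS`/`MISSING`/`GAP` honored) are read
and written; the NEXUS reader is deliberately minimal and targets
standard (morphological) matrices. Missing and inapplicable cells are
*optimized identically* as full ambiguity over the character's observed
states — the pragmatic TNT-like convention — while the distinction is
preserved in I/O. Characters default to unordered, weight 1, active,
unless the input file says otherwise.

### Tree length

Unordered characters use Fitch optimization on a bitmask encoding,
vectorized across characters; ordered characters use the
bounded-interval (Farris) pass. Tree length is a property of the
unrooted topology, asserted by tests under re-rooting and taxon
permutation. Two independent implementations guard the engine: Sankoff
dynamic programming with explicit step matrices (uniform and linear
costs) must agree on every tested instance, and so must `phangorn`'s
Fitch length.

### Heuristic search

The search replicates the traditional protocol: each replicate builds a
Wagner tree by greedy stepwise addition in a random taxon order, then
hill-climbs through tree-bisection-reconnection (TBR) rearrangements,
accepting the first strictly shorter neighbor (first-found tie-break)
until a local optimum, and finally collects up to `trees_per_rep`
equally short trees from the plateau. Defaults are 50 replicates, 10
trees per replicate, a 10,000-tree memory. The global pool is
deduplicated by bipartition set and filtered to the overall minimum.

Rearrangements are *scored, not built*: parsimony length is invariant
under re-rooting, so each bisected half is scored once (one postorder
and one preorder pass yield, for every edge, the state set of the half
re-rooted on that edge) and a candidate reconnection costs
`L1 + L2 + join(S1[a], S2[b])`. Only accepted trees are constructed.
The tests cross-check this scoring against an explicitly constructed
neighborhood, and the whole search against an exhaustive-enumeration
oracle (all 945 seven-taxon topologies). All randomness derives from a
single integer seed (replicate seeds are drawn from it), making runs
bit-reproducible.

### Ensemble indices and Bremer support

`CI = Σw·m / L` and `RI = (ΣwG − L) / (ΣwG − Σwm)`, with `m` each
character's minimum conceivable steps (observed states − 1, or the
observed range for ordered characters) and `G` its maximum (star-tree)
steps (scored taxa − modal state frequency; the distance-minimizing
center for ordered). All-missing characters contribute zero everywhere;
`RI` is reported as `NA` with an explanation when no character varies
beyond its minimum. By default all variable characters — including
autapomorphies — enter the sums, the common TNT reporting convention;
`informative_only = TRUE` restricts every sum, including the length, to
parsimony-informative characters, since published index values do not
always state which convention was used.

Bremer decay is computed from a pool of near-optimal trees: the search
pool is extended by TBR-visiting trees up to `best + margin` steps
(default margin 20), and each clade of the 50% majority-rule reference
tree is scored by the shortest pool tree lacking it. Clades never
contradicted within the margin report `">= margin"`. Because the pool
samples rather than exhausts tree space, these decay values are lower
bounds — the same caveat that applies to script-based decay estimation
generally. A six-taxon fixture with known decay (verified by exhaustive
enumeration) pins the estimator in the tests.

### Consensus

Strict consensus keeps bipartitions present in all trees;
majority-rule keeps those in strictly more than the threshold fraction
(ties at exactly 50% are excluded), annotated with percentage
frequencies as node labels. Greedy completion by compatible minority
clades is deliberately not performed. Consensus topologies are verified
against `ape::consensus` on random tree pools.

## 5. Time-calibrated trees

Stratigraphic calibration uses the simplest reproducible rule: each tip
sits at its first appearance datum (FAD, Ma), each internal node at the
oldest FAD among its descendants (minimum-age calibration), with an
optional uniform padding added at the root only. Zero-length internal
edges are permitted; a tip's ghost lineage is its parent's age minus its
FAD. This mirrors the common practice of plotting ranges against a
calibrated timescale — it is a *minimum* age model, and true divergences
are necessarily older. The FAD–LAD bar is carried as metadata for
rendering; ages are computed from FADs alone.

## 6. What the simulators emulate — and what they do not

Every pipeline input has a seeded generator with known ground truth:

* `sim_tree`: Yule (pure-birth) topologies with unit-depth branches.
* `sim_matrix`: characters evolve by a symmetric k-state Markov (Mk)
  process; `change_rate` is the expected number of changes per character
  per total tree depth, with Poisson change counts per branch. Uniform
  missingness knocks out exactly `floor(missing_frac · cells)` cells; a
  `block_missing` option blanks the first half of the characters for
  chosen taxa, emulating vertebra-only fossils unscorable for cranial
  characters. There is no rate heterogeneity by default and no
  correlation between characters.
* `sim_allometric`: log-uniform widths with the configured regression
  and log-normal (or additive Gaussian) noise; the default n = 21
  matches the size of the extant calibration datasets behind the
  built-in equations.
* `sim_vertebral_series`: a 22-vertebra precloacal column (the
  confidently precloacal portion of a 27-vertebra collection), sizes
  following a smooth intracolumnar profile scaled to cL 37.5–62.7 mm and
  prW 62.4–111.4 mm, the anterior quarter flagged with hypapophyses,
  `prW/cL > 1` throughout.
* `sim_strat_ranges`: uniform FADs with exponential durations.

Passing tests on these generators shows the *algorithms* are correct
under their stated models; it does not validate the models against real
madtsoiid data, whose missingness is structured, whose characters are
correlated (size, body form), and whose measurement error is not
multiplicative white noise.

## 7. Numerical choices and problem sizes

* Half-up rounding everywhere a value is displayed; full precision
  internally. All logarithms base 10 in the paleothermometry, as the
  equations are printed.
* Search determinism: one seed; replicate seeds drawn from it;
  first-found acceptance among equal-length candidates; deterministic
  edge enumeration order.
* Property tests run at sizes chosen to keep the full suite under a
  minute while still exercising the estimators: the search oracle at 7
  taxa × 20 characters over 100 seeds (exhaustive enumeration is
  feasible there), tree recovery at 10 taxa × 200 characters with
  `change_rate = 0.3` (pilot runs put full-recovery near 90% at that
  rate; higher rates saturate the characters with homoplasy),
  allometric coefficient recovery over 200 seeded fits, and the
  analysis-scale search demonstration at 22 taxa × 120 characters.
* The `change_rate = 0.3` default for "moderate" signal, the 2%
  measurement noise in the allometric generator, and the 25% ATV
  fraction of the vertebral series were fixed once from domain
  plausibility and pilot behavior, before being frozen into the tests.

## 8. Known limitations

* The search is a hill-climber with plateau collection: no ratchet, no
  sectorial searches, no implied weighting. On highly homoplastic
  matrices it can (like any heuristic) stop short of the global optimum;
  the replicate structure is the mitigation.
* Bremer values are pool-based lower bounds, not constrained-search
  decay indices.
* States are limited to 0–9 per character (bitmask encoding supports
  more, but the I/O formats as written do not).
* The paleothermometer propagates no uncertainty beyond evaluating the
  equation at the body-length endpoints.
* Published index values for the real supplementary matrices depend on
  ordering/weight conventions recorded only in those files; the reader
  honors `ccode`, but reproduction requires the files themselves (see
  `inst/extdata/README.md`).
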