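---
title: "Inferring optimal growth temperatures from elongation-factor GDP binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring optimal growth temperatures from elongation-factor GDP binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogtrace)
```

## The measurement and the model

The temperature optimum of GDP binding by a translation elongation factor
(EF-1A/EF-Tu) tracks the optimal growth temperature (OGT) of its source
organism. A binding assay measures bound Mant-GDP fluorescence at a grid
of incubation temperatures — typically 0–100 °C in 10 °C steps with three
independent replicates, 33 datapoints — producing a bell-shaped profile
whose peak temperature is the quantity of interest.

The profile is fit to a skewed Gaussian-like curve

$$F'(t) = F_0 + (F^* - F_0)\,
  e^{-\left(\frac{t - t^*}{s(t)}\right)^2},
\qquad
s(t) = s_L + \frac{s_R - s_L}{1 + e^{-(t - t^*)/w}} .$$

The width $s(t)$ interpolates logistically between a left width $s_L$
(governing the cold flank) and a right width $s_R$ (the hot flank),
switching around the peak over a scale of $w$ °C. This captures the
asymmetry real binding curves show — activity typically collapses faster
above the optimum than below it — with only one extra parameter relative
to a symmetric Gaussian.

Parameters and their meaning:

| parameter | units | role | default / treatment |
|---|---|---|---|
| $F_0$ | a.u. | baseline fluorescence | fitted; initialised at the minimum replicate mean |
| $F^*$ | a.u. | peak fluorescence | fitted; constrained $F^* \ge F_0$ |
| $t^*$ | °C | peak (binding optimum) | fitted; initialised at the maximum-mean temperature |
| $s_L, s_R$ | °C | flank widths | fitted on the log scale; initialised at 10 °C |
| $w$ | °C | width-transition rate | fixed at 5 °C, configurable, never optimised |

Treating $w$ as a constant reflects that it is a shape convention, not an
identifiable quantity on an 11-point grid. Replicates enter the least
squares as individual residuals, not per-temperature means: with three
replicates the fit sees 33 datapoints and the residual scatter carries
the replicate noise the bootstrap later resamples.

## Numerical strategy of the fit

`fit_peak()` minimises the residual sum of squares with derivative-free
Nelder–Mead on a reparameterised space chosen so the model invariants
hold by construction rather than by penalty:

* widths enter as $\log s_L, \log s_R$ (positivity),
* the amplitude enters as $F^* = F_0 + e^{g}$ (peak above baseline).

Three safeguards deal with the optimiser's known failure modes on sparse
grids:

1. **Deterministic multi-start.** The peak location is restarted from
   offsets {0, ±5, ±10} °C around the maximum-mean temperature and the
   lowest-SSE solution kept. The offsets are deterministic on purpose:
   fitting consumes no random numbers, so bootstrap streams cannot be
   perturbed by optimiser internals.
2. **Polish restarts.** Nelder–Mead can report convergence on a collapsed
   simplex; the winning solution is re-submitted as a fresh starting
   point (up to four times, stopping when the SSE stops improving by a
   relative $10^{-9}$). In testing against an independent fine-grid
   profiling oracle this step is what closes the last few tenths of a
   degree.
3. **Identifiability flag.** A fit is declared non-identifiable when the
   fitted amplitude $F^* - F_0$ falls below three times the pooled
   within-temperature replicate standard deviation (with a $10^{-5}$
   relative floor so an exactly constant profile is always caught). A
   flat profile has no peak; reporting its $t^*$ would be noise.

Degenerate inputs are rejected up front: fewer than 6 datapoints or 3
distinct temperatures refuse to fit, and a requested `fit_range` that
empties the profile is an error rather than a silent no-op.

## Bootstrap confidence intervals

`bootstrap_peak_ci()` implements the case bootstrap within temperature:
for each temperature independently, the observed replicates are resampled
with replacement (three-out-of-three for the standard design), the model
is refit, and the 90% interval is formed from the 5th and 95th
percentiles of the bootstrap $t^*$ distribution (order-statistic
percentile with linear interpolation, the index-$1 + p(n-1)$ convention;
at 1000 replicates the choice of convention moves the bounds by under
0.1 percentile).

Design choices worth stating:

* the **point estimate is always the full-data fit**, never a bootstrap
  summary, and no constraint forces it inside the interval — with an
  asymmetric model and three replicates the percentile interval can sit
  asymmetrically around, and occasionally beside, the point estimate;
* **all resampling indices are pre-drawn** from the root seed before any
  refitting, so results are bit-reproducible and independent of
  execution order;
* bootstrap refits are **warm-started at the full-data solution** with a
  single start — the resampled surfaces are small perturbations of the
  original, and the warm start stabilises refits that would otherwise
  wander between local minima;
* refits that fail to converge or lose identifiability are **dropped and
  counted**; more than 10% failures aborts with a quality error instead
  of returning a silently biased interval.

The percentile bootstrap with three replicates per temperature is only
approximately calibrated: the package's own simulation at the standard
design and 2% relative noise (200 simulated assays) checks that the
empirical coverage of the nominal 90% interval lies in the 80–97% band,
and the test suite asserts exactly that band, not a point value.

## Thermal stability and fit restriction

The ThermoFluor melt profile is reduced by one rule: the grid temperature
of highest replicate-mean dye fluorescence marks the transition to
complete unfolding, and the protein is treated as stable from the lowest
assayed temperature up to **one grid step below** the transition
(`stable_max = t_transition - grid_step`, the grid step being the minimal
spacing of the assayed temperatures). Ties at the maximum resolve to the
lowest tied temperature, the conservative choice. The upper bound is
therefore resolution-limited — an approximate upper limit, not a melting
midpoint — and no sigmoid $T_m$ fit is attempted, because only the argmax
is consumed downstream.

Binding fits may use either the full grid or the stable range;
`restrict_to_stable()` implements the latter, and the pipeline applies it
whenever a melt profile is available. Restricting is the defensible
default — binding measured on an unfolded protein is not a binding
optimum — but both paths are exposed because the choice is a judgement
call for borderline transitions.

## From binding optimum to OGT

The binding optimum is used directly as the OGT proxy; no regression
adjustment is applied by default. An optional linear calibration
(`infer_ogt(..., calibration = )`) maps the estimate through a
least-squares line fitted to a table of organisms with known OGT; it is
off by default because the proxy's raw agreement is the point being
tested, not assumed.

Lifestyle classes are a step function of OGT with cut points at 45 °C
(mesophile / moderate thermophile) and 80 °C (moderate thermophile /
hyperthermophile). The literature draws these lines loosely; these
values were chosen once so that all conventional assignments for
organisms between 20 and 85 °C come out as expected, and they are
configurable where a study needs different conventions.

The bundled calibration table ships in two versions because its source
prints two slightly different sets of binding optima for the same four
organisms, and the Pearson correlation computed from either (≈ 0.889 and
≈ 0.967 by the product-moment formula) differs from the correlation the
source quotes (0.9906). The package documents the discrepancy and
computes the formula value; it does not attempt to reproduce the quoted
number, and the test suite pins this down as a known issue rather than a
target.

## Consensus of ancestral reconstructions

Different ASR engines reconstruct slightly different ancestral sequences.
`consensus_sequence()` automates the curation of disagreeing alignment
columns deterministically: unanimous columns pass through; otherwise the
majority state wins (gap is a votable state); vote ties are broken by the
highest posterior probability among the tied states (a state's PP being
the maximum over the methods carrying it; gaps carry no PP and so lose PP
tie-breaks to any residue); residual ties fall back to lexicographic
order so the result is independent of input order. An optional reference
sequence — the neighbouring sequence in the alignment — can instead
resolve disagreements wherever its state is among those observed. The
consensus PP of a column is the maximum PP among methods carrying the
chosen state (the closest order statistic available from the inputs
alone), the mean PP averages non-gap consensus columns, and a
disagreement report lists every curated column for manual review.

## Trees and trajectories

Phylogenies move as newick with labelled internal nodes. OGT estimates
attach to nodes by label; annotations export both as extended-newick
comment tags (`[&ogt=...,lifestyle=...]`) and as a plain TSV sidecar, the
sidecar being authoritative because comment dialects vary across
toolchains. The trajectory table links each annotated node to its
**nearest annotated ancestor** — not every internal node carries a
measured protein, and skipping bare intermediates keeps the OGT deltas
well-defined; they telescope exactly along any annotated path. No
Brownian-motion or other comparative-methods interpolation fills in
unmeasured nodes: only measured or fitted values are painted.

## What the synthetic data does and does not emulate

The generators exist so every stage is testable with known ground truth:

* `simulate_binding_profile()` draws datapoints from the peak model plus
  additive homoscedastic Gaussian noise (truncated at zero), default
  2% of peak intensity on the 0–100 °C / 10 °C / 3-replicate design.
  Real assays add structure this omits: temperature-dependent variance,
  replicate batch effects, probe bleaching, and deviations from the
  assumed peak shape itself.
* `simulate_thermofluor()` produces a unimodal melt curve (logistic rise,
  linear post-peak decay) whose mean argmax sits on the grid point
  nearest the requested transition; since only the argmax is consumed,
  the flank shapes are cosmetic.
* `simulate_asr_set()` plants independent per-site substitution errors at
  each method's rate and draws PPs from Beta(20, 2) at correct sites and
  Beta(4, 4) at erroneous ones — a caricature in which errors are
  independent across methods and sites, which real ASR errors are not
  (they correlate through the shared tree and alignment).
* `simulate_trait_tree()` evolves OGT by independent Gaussian steps
  (default SD 3 °C per branch, small enough that simulated optima stay
  well inside the assay grid) on a random topology, purely as an
  end-to-end harness; it is not a claim about how growth temperature
  actually evolves.

Passing tests on these generators therefore demonstrates that the
machinery is correct under its stated model, not that the model captures
every feature of bench data.

## Problem sizes used by the test suite

The suite verifies parameter recovery with 100 simulated assays per
published optimum (mean fitted $t^*$ within 0.5 °C of truth at 2%
noise), bootstrap coverage with 200 simulated assays at 200 bootstrap
replicates each (the coverage property of the percentile interval does
not depend on the replicate count at this precision; the analysis default
remains 1000), oracle agreement on 20 random instances against a 0.1 °C
grid-profiling oracle restricted to ±15 °C around the empirical peak
(outside which the profiled SSE is monotonically worse for unimodal
data), and consensus gain over 50 seeded triplets.

## Known limitations

* The stable-range upper bound inherits the melt grid's resolution.
* The percentile bootstrap under-covers slightly with three replicates;
  BCa or studentised variants are out of scope.
* The OGT proxy is an identity map; organisms whose elongation factors
  run systematically warm or cold relative to their growth optimum (as
  resurrected ancestral proteins, being slightly hyperstable, may) carry
  that bias into the OGT estimate.
* Consensus PPs are derived from the input methods' PPs; no engine is
  re-run to assign final posteriors to the consensus sequence.
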