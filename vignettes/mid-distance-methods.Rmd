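---
title: "Identifying metabolites from parallel 13C tracing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying metabolites from parallel 13C tracing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midtrace)
```

## The problem

Untargeted LC-MS metabolomics detects thousands of peaks per sample, but
most cannot be assigned to a known compound: m/z and retention time are
not specific enough, and MS2 spectral libraries only cover compounds
someone has already purified. When cells are grown on a ^13^C-labeled
nutrient, however, every metabolite synthesized from that nutrient
acquires a mass isotopomer distribution (MID) — the vector of fractional
abundances of its M+0 ... M+n isotopomers — that reflects its
biosynthetic route. Biochemically related metabolites therefore have
related MIDs, and an unknown peak can be identified by its MID
similarity to known peaks. `midtrace` implements this idea end to end:
a convolution-based MID distance, the preprocessing that makes raw MID
tables usable, a simulation framework for validating the distance on
networks with known ground truth, and neighbor-guided candidate
annotation.

## The MID distance

If B is formed from A by a carbon-preserving reaction, their MIDs are
nearly identical. If B is formed by condensation A + C -> B, the MID of
B is (at steady state, and approximately otherwise) the convolution of
the MIDs of A and C:

$$(x^A \times x^C)_k = \sum_{i+j=k} x^A_i\, x^C_j,$$

the distribution of the sum of two independent labeled-carbon counts.
The catch is that C is usually unknown, so the distance between peaks A
(m carbons) and B (n carbons, m < n) minimizes over all *convolutants* —
every peak in the data set with n − m carbons:

$$d(A,B) = \min_C \sum_e \left\lVert x^{A,e} \times x^{C,e} - x^{B,e} \right\rVert,$$

summing Euclidean norms over all labeling experiments `e`. Using many
parallel tracers is what gives the distance its specificity: two peaks
must match under every labeling pattern simultaneously.

Decisions where the formulation leaves latitude:

* **Equal carbon counts (m = n).** The convolutant formula is defined
  for m < n; for m = n we use the direct multi-experiment Euclidean
  distance, which is the limit of the formula under the unique 0-carbon
  convolutant `[1]`.
* **Missing convolutant.** If no peak with n − m carbons exists, the
  pair is assigned the largest distance observed across all defined
  pairs (computed as a second pass) and flagged, so evaluation code can
  exclude such sentinel pairs.
* **Missing experiments.** An experiment term enters the sum only when
  A, B *and* C all have an MID there; a candidate sharing no experiment
  with the pair is skipped entirely (an empty sum would be a spurious
  zero). Each reported distance carries the number of contributing
  experiments so low-support values can be filtered downstream. We do
  not normalize by the number of experiments: distances from deeper
  panels are larger, which is intentional — they carry more evidence.
* **Ties among convolutants** are broken by lowest peak id, making the
  output deterministic.
* **Uncorrected MIDs.** Distances are computed on MIDs *not* corrected
  for natural ^13^C; correction is a deconvolution that amplifies noise
  and introduces correlated artefacts. Correction is still applied (a)
  when *displaying* MIDs, and (b) inside filters, where thresholds refer
  to corrected fractions. Passing a corrected table to the distance
  functions triggers a warning.

The distance is symmetric and non-negative but deliberately *not* a
metric: minimizing over convolutants violates the triangle inequality.
Nothing in the package assumes metricity.

### Enrichment

The ^13^C enrichment of an MID is the carbon-weighted labeled fraction
$\sum_{i\ge 1} i\,x_i / n$ — 0 when unlabeled, 1 when fully labeled.
An alternative reading, the plain labeled-isotopomer fraction
$\sum_{i \ge 1} x_i / n$, is available via `per_isotopomer = TRUE` for
sensitivity analyses; the weighted form is the standard definition of
fractional enrichment and is used everywhere by default.

## Preprocessing

Raw MID tables carry two classes of artefact handled in a fixed order:

1. **Enrichment filter** (`enrichment_filter()`): peaks never reaching
   ≥ 10% corrected enrichment in any labeled experiment are unlabeled
   material (medium components, contaminants) and are removed. The
   boundary is inclusive, and unlabeled-control experiments are excluded
   from the maximum.
2. **False-isotopomer filter** (`false_isotopomer_filter()`): a mass
   isotopomer (other than M+0) whose corrected fraction exceeds 0.03 in
   strictly more than 10 experiments is almost certainly a co-eluting
   foreign peak, not labeling — real labeling patterns differ across
   tracers. The offending MI is zeroed in all experiments on the stored
   uncorrected fractions and the MIDs renormalized. Because
   renormalization can push another MI over the threshold, the rule is
   iterated to a fixed point within one call, which makes the filter
   idempotent. All experiments present (including unlabeled controls)
   enter the count by default; `count_experiments` restricts it.

Boundary semantics are encoded exactly as stated: "at least 10%" is ≥,
"higher than 0.03" is >, "more than 10 experiments" is > 10.

Natural-abundance correction itself (`correct_natural_abundance()`)
considers carbon only: with j labeled carbons fixed, the remaining
n − j positions carry natural ^13^C independently, giving a
lower-triangular binomial mixing matrix that is inverted exactly by
forward substitution; negative components (possible with noisy data) are
clipped and the result renormalized. Non-carbon isotopes (^15^N, ^18^O,
^34^S) are assumed to have been handled by upstream peak assignment —
a documented limitation.

Coeluting in-source fragments and adducts are grouped by
`group_coeluting_artefacts()`: single linkage over pairs within an
retention-time window (default 5 s) *and* below an MID-distance cutoff
(default 0.3). Both defaults are package choices (config-overridable):
the rt window matches typical chromatographic peak widths, and 0.3 is
well below the distance scale at which unrelated metabolites appear.
Crucially, coelution alone is not enough — a coeluting peak with
distinct labeling is a genuine different metabolite and stays separate.

## Simulating labeling on atom-mapped networks

To validate the distance where ground truth is known, the package
simulates isotope propagation through atom-mapped metabolic networks.
Reactions are written in a plain-text atom-transition dialect
(`v1: acoa (ab) + oaa (cd) -> cit (abcd)`); reversible reactions are two
opposing irreversible ones, fluxes are non-negative and must balance at
every non-substrate metabolite.

The network is decomposed into elementary metabolite units (EMUs) —
atom subsets whose labeling balances independently — by backward tracing
from the target metabolites. Condensations produce convolution EMU
reactions whose sources are strictly smaller, so the system is solvable
size block by size block. The nonstationary dynamics for an EMU X of a
metabolite with pool size p are

$$\frac{dX}{dt} = \frac{1}{p}\Big(\sum_{in} v\, y_{src} - v_{out} X\Big)$$

per mass isotopomer. All blocks are integrated together with a
stiff-capable solver (`deSolve::ode`, lsoda, rtol 1e-8 / atol 1e-10)
from fully unlabeled initial conditions, on a 200-point log-spaced grid
spanning well past the slowest pool's turnover; larger EMU sizes never
feed back into smaller ones, so joint integration equals block-wise
integration. The steady state is solved directly as one linear system
per size block. Both paths are verified against brute-force positional
isotopomer enumeration (the full 2^n state space) in the test suite.

Choices worth knowing:

* **Pool sizes** default to 1 for every metabolite; only pool/flux
  ratios shape the transients, and absolute pool sizes are rarely known.
* **Tracer purity** defaults to 1 and natural abundance is *not* added
  to simulated data — the simulation study is about the distance, not
  instrument realism. A flag applies the forward correction model when
  realism is wanted.
* **Pre-steady-state sampling.** Batch labeling experiments rarely reach
  isotopic steady state, and the transient regime is also what makes
  consecutive chain intermediates distinguishable at all (at steady
  state a carbon-preserving chain has identical MIDs everywhere).
  `sample_pre_steady_state()` samples at a fraction (default 0.5) of the
  detected steady-state time — the earliest grid time where the maximum
  MID change rate drops below 1e-6 per time unit.

## Biochemical relatedness: the gold standard

Pathway membership is too subjective to score a distance against, so
the gold standard is the *carbon contribution*: to measure how much of
B's carbon comes from A, A is turned into a network substrate with a
fully labeled MID (all fluxes untouched, so the flux state matches the
MID simulation), the steady-state EMU system is solved, and the
enrichment of B is read off. The symmetric relatedness
f(A,B) is the larger of the two directional contributions, and pairs
with f > 1/2 (strict) are "biochemically related". One modified-network
solve per source metabolite yields the whole matrix — O(#metabolites)
solves, not O(#pairs).

## The evaluation fixture

`make_network("eval_panel")` is the default simulation study: 25
metabolites in six substrate chains (carbon counts 1–4, lengths 2–5)
plus one condensation (`A3 + B2 -> F1 -> F2`, 3 + 2 carbons), five
uniformly labeled tracers (one per main substrate), sampling at half the
steady-state time, and noise levels {0, 0.005, 0.01, 0.02}. Design
rationale:

* Every metabolite has exactly one consuming reaction, so unit fluxes
  balance by construction and every reaction is active at the same
  magnitude; all pools then turn over at equal rates, the regime in
  which transient MIDs order chain members cleanly.
* Carbon counts 1–5 all occur (the 1-carbon chain is deliberately left
  untraced — not every nutrient is available as a tracer), so a
  convolutant exists for every carbon-count difference and no pair is
  lost to the sentinel.
* The condensation creates the scientifically interesting asymmetry:
  the 3-carbon donor contributes f = 0.6 (> 1/2, related) while the
  2-carbon donor contributes f = 0.4 (unrelated by the strict
  threshold), yet both sit at identical MID distance to the product —
  a deliberate hard case for precision.
* Decoy peaks with random MIDs can be injected to stress false-positive
  behavior; they are labeled unrelated to everything.

The noise model is additive Gaussian on each MI fraction, clipped at 0
and renormalized — the simplest model consistent with "sampling noise"
on fractional abundances; this is an assumption, not a measured noise
model. Measurement noise from real instruments is multiplicative at
high intensity and count-limited at low intensity, neither of which the
generator emulates, so passing tests demonstrate correctness of the
method's machinery and its behavior under idealized noise, not
instrument-level performance.

Problem sizes in the test suite were chosen for seconds-scale runs: the
25-metabolite panel for parameter recovery, networks of ≤ 12 total
carbons wherever the positional-isotopomer oracle (exponential state
space) is enumerated, 10 replicates per noise level, 100 permutations
for the null AUPR.

## Annotation

`match_mz()` matches observed peak m/z against the neutral monoisotopic
masses of candidate compounds under five adducts (M+H, M−H, M+NH4,
M+H−H2O, M−H−H2O; charge sign restricted by peak polarity) within a
symmetric 10 ppm tolerance, and requires the candidate formula's carbon
count to equal the peak's MID carbon count. `neighbor_support()` then
(1) rejects candidates whose formula has fewer carbons than the maximum
labeled-carbon count observed in any tracer (largest corrected MI above
a 0.01 floor), and (2) scores survivors by structure-class tag overlap
with the k nearest previously known peaks in MID-distance space.
User-supplied tags ("hexose", "dipeptide", ...) replace subjective
structural-similarity judgment with something reproducible and
auditable; a chemical-similarity engine is out of scope. Ranking is by
score, then by the rank of the nearest known neighbor achieving that
score (closer neighbors are stronger evidence), then by compound id —
fully deterministic. Calls below the score threshold are reported as
"undetermined" for human review rather than forced.

## Precision-recall conventions

The threshold sweep runs over the unique distance values ascending;
pairs at or below the threshold are predicted related. AUPR integrates
precision over recall by trapezoids, with an initial point at recall 0
carrying the precision of the smallest threshold. Missing-convolutant
(sentinel) pairs carry no ranking information and are excluded from the
sweep and reported separately; `include_sentinel = TRUE` ranks them
last instead. Greedy tracer selection recomputes distances from scratch
on each candidate experiment subset (no incremental approximation) and
breaks ties by experiment name.

## Known limitations

* A small MID distance does not prove relatedness: with many peaks,
  some convolutant makes the convolution match by chance, particularly
  for pairs of very different size or weak labeling.
* Isobaric compounds with near-identical biosynthesis (e.g. hexose
  isomers) are not distinguishable by MIDs.
* The correction model is carbon-only, and the annotation step trusts
  upstream formula/carbon-count assignment.
* The CLI and file formats target small-to-medium tables (hundreds to a
  few thousand peaks); the pairwise search is quadratic in peaks times
  the convolutant set size.
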