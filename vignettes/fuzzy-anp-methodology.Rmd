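---
title: "Fuzzy ANP priorities: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy ANP priorities: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanp)
```

## The problem

When a health system must ration a scarce resource — the motivating case is
allocating drugs in short supply across provinces — decision makers weigh
competing paradigms (efficiency, equity and access, effectiveness) and the
need indicators beneath them (population size, bed occupancy, prescription
volume, disease burden, ...). These criteria are interdependent, so a
hierarchy is too rigid: the Analytic Network Process (ANP) represents them
as clusters of elements connected by influence edges and extracts global
priorities from the stationary behaviour of a supermatrix. Because expert
judgments of the form "how much more important is *i* than *j*?" are
imprecise, each judgment is carried as a triangular fuzzy number (TFN)
rather than a crisp ratio; this is the fuzzy ANP.

This vignette records the package's model, the defaults and why they were
chosen, the numerical decisions, and what the synthetic validation does and
does not establish.

## Judgments and aggregation

A TFN $(l, m, u)$, $0 < l \le m \le u$, holds the smallest plausible,
most plausible, and largest plausible value of a judgment ratio. Elicited
9-point scores are fuzzified as $s \mapsto (\max(s-\delta,1),\, s,\,
\min(s+\delta,9))$ with spread $\delta = 1$ by default and score 1 kept
crisp. The source study cites a TFN scale without printing it; this mapping
is the most common convention, and the spread is configurable
(`fuzzy_scale()`).

Each comparison question yields a reciprocal matrix of TFNs per expert
($a_{ji} = a_{ij}^{-1}$ componentwise with bounds reversed). A panel is
aggregated cell by cell with the componentwise geometric mean
(`aggregate_panel()`). The study does not state its aggregation rule, but
its printed aggregate matrix is reciprocal to within transcription
precision, which the geometric mean preserves exactly and the arithmetic
mean does not — that reciprocity, plus standard group-AHP practice, fixes
the choice. All experts are weighted equally; the study reports no
differential weighting. Incomplete matrices are rejected rather than
imputed, since no incomplete-judgment procedure is documented for the
source application.

## From matrices to weights

Two fuzzy derivations and one crisp derivation are exposed:

* **Buckley fuzzy geometric mean** (default). Row means
  $r_i = (\prod_j a_{ij})^{1/n}$, fuzzy weights
  $w_i = r_i \otimes (\sum_k r_k)^{-1}$, defuzzified by the Liou–Wang
  total integral $I_\alpha = \alpha\frac{m+u}{2} + (1-\alpha)\frac{l+m}{2}$
  and normalised. At the default optimism level $\alpha = 0.5$ the integral
  reduces to $(l + 2m + u)/4$.
* **Chang extent analysis** (`chang_extent_weights()`). Synthetic extents
  $S_i = \sum_j a_{ij} \otimes (\sum_{ij} a_{ij})^{-1}$ compared through
  degrees of possibility $V(S_i \ge S_j)$; an element whose extent lies
  wholly below another's receives weight exactly zero.
* **Principal eigenvector** (`principal_eigenvector()`), power iteration on
  a crisp matrix (used on the modal values of an aggregate), with
  $\lambda_{\max}$ estimated from the mean Rayleigh ratio.

The package defaults to Buckley + total integral because that combination
reproduces the published worked example exactly: running the bundled
aggregate paradigm matrix through it returns certain weights
0.168 / 0.428 / 0.413 and normal weights 0.166 / 0.424 / 0.409 at three
decimals (`reproduce_paradigm_weights()` asserts this). The source text
names extent analysis as its method, but extent analysis provably cannot
have produced those numbers: on the same input the efficiency extent does
not overlap the others, so its weight is exactly 0 (the test suite asserts
this reconstruction finding). Extent analysis is therefore retained as a
documented alternative, not the default, and its zeroing behaviour is
surfaced rather than smoothed over.

Which defuzzifier produced the published "certain weight" column is
likewise unstated in the source; $(l+2m+u)/4$ is the empirical resolution
(it matches all three printed values), and $\alpha$ stays configurable.

## Consistency

For a crisp reciprocal matrix, $CI = (\lambda_{\max} - n)/(n - 1)$ and
$CR = CI / RI(n)$ with Saaty's classic random indices
(RI(3) = 0.58, ..., configurable); judgments are accepted when $CR < 0.1$,
and `run_pipeline()` enforces that gate (overridable with `force = TRUE`).
Orders 1–2 are consistent by construction. A fuzzy matrix is checked
through two crisp reductions (`fuzzy_cr_variants()`): modal values
(`CRm`) and geometric means of the bounds $\sqrt{l_{ij} u_{ij}}$ (`CRg`).

On the bundled aggregate these evaluate to `CRm` ≈ 0.017 and `CRg` ≈ 0.020
— both comfortably accepted, but not equal to the 0.021 / 0.063 annotated
on the published table. No standard eigenvalue-based ratio of the printed
matrix yields those annotations (they may average per-expert ratios that
were never published). The package reports what it computes and does not
attempt to match the annotated pair; only the weight columns, which do
reconstruct exactly, are asserted.

## Network synthesis

`anp_network()` declares clusters, elements, a goal, and dependency edges
(element-, cluster-, or goal-sourced). `assemble_supermatrix()` places each
local priority vector in the block its edge governs;
`weight_supermatrix()` scales blocks by cluster-level weights and
normalises columns (equal cluster weights when no cluster comparisons are
supplied — the common ANP-tool default); `limit_supermatrix()` takes the
matrix to its limiting power; `synthesize_priorities()` reads off overall,
cluster, and within-cluster priorities with stable ranks.

Numerical decisions in the limit step:

* Powers are taken by **repeated squaring** (tolerance `1e-9`, at most 64
  squarings — the $2^{64}$-th power), mathematically equivalent to raising
  to an arbitrarily high odd power but with a deterministic stop. Column
  stochasticity is re-verified at every squaring, not assumed.
* **Cyclic** (non-primitive) structure never settles under plain powering;
  after the squaring orbit stalls, a short orbit search detects the period
  $p$ and returns the Cesàro average of one cycle, the standard limiting
  object for periodic chains.
* **Strict hierarchies** have nilpotent supermatrices — every power
  eventually vanishes — so the limit is taken as the column-normalised
  cumulative influence $A + A^2 + \cdots$, which reproduces the classical
  top-down weight products of AHP. This keeps hierarchies first-class
  citizens of the same pipeline.
* Zero columns (elements that influence nothing) are left zero by default;
  `sink_policy = "uniform"` substitutes a uniform column for users who
  prefer the alternative convention of some ANP tools.
* Synthesis uses the goal column of the limit when a goal exists (for a
  hierarchy it is the only informative column); otherwise the nonzero limit
  columns are checked for agreement within tolerance and averaged.

A structural caveat worth knowing: in a network where some cluster receives
influence only from the goal (a transient state of the chain), that
cluster's stationary mass — hence its overall priority — is legitimately
zero. The bundled reconstruction of the study's network has this property
for the efficiency cluster, because only one inter-cluster arrow is
documented; the full questionnaire behind the original study implies a
richer edge set that was never published. The bundled network is therefore
labelled a plausible reconstruction, and the study's final weights are
shipped as a reference fixture (`allocation_reference_weights()`), not as
a recomputation target.

## Synthetic validation

`simulate_panel()` generates expert panels from known ground truth: the
consistent matrix $a_{ij} = w_i / w_j$ is perturbed multiplicatively on the
upper triangle with lognormal noise $\exp(\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$, completed to exact reciprocity,
optionally snapped to the 9-point scale, and fuzzified with spread
$\delta$. Judgments beyond the scale ceiling clip to 9, as they would on a
real questionnaire. The lognormal model is the standard random-judgment
model compatible with the CR framework; one root seed derives per-expert
(and per-question) child seeds, so every run is exactly reproducible.

Defaults mirror the study's design: 14 experts, a three-element top-level
comparison, $\delta = 1$, and $\sigma = 0.2$ — a noise level at which
essentially all simulated 3×3 experts clear the $CR < 0.1$ gate, matching
the study's report that all its panels were consistent.

What the validation shows: with $\sigma = 0$ and $\delta = 0$ the full
pipeline (panel → aggregation → weights → supermatrix → limit → synthesis)
returns the ground truth to machine precision at every level; limit columns
agree with an independent dense eigen-solve to `1e-8` on random primitive
stochastic matrices; aggregation preserves reciprocity exactly across
thousands of random panels; recovery error grows with $\sigma$ and shrinks
with panel size. What it does not show: real experts are not lognormal
perturbations of a common truth — they disagree systematically, anchor, and
satisfice — so passing synthetic recovery bounds numerical and algorithmic
error, not elicitation error. Problem sizes in the shipped tests (3–8
elements, panels of 1–50, a few hundred Monte-Carlo replicates) match the
scale of the motivating application, where comparison matrices rarely
exceed order 9.

## Known limitations

* Trapezoidal and interval type-2 fuzzy numbers are out of scope; only
  TFNs are supported.
* No fuzzy consistency index defined directly on fuzzy matrices; fuzzy
  matrices are checked through their crisp reductions.
* Incomplete comparison matrices are errors, not estimation problems.
* Extent analysis is reported as specified by its literature, including
  its zero-weight behaviour; users who need strictly positive weights
  should use the Buckley derivation.
* The bundled network's dependency list is a reconstruction; conclusions
  about the original study should rest on its published aggregate matrix
  (which this package reproduces) rather than on the reconstructed edges.
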