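---
title: "Methods: 2D/3D-QSAR modelling of nitrogen-mustard compounds"
author: "mustardQSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D/3D-QSAR modelling of nitrogen-mustard compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mustardQSAR)
```

# The modelling problem

Dipeptide-alkylated nitrogen mustards are alkylating agents of interest as
anti-osteosarcoma chemotherapeutics. Given a small series of such compounds
with measured IC50 values (micromolar), the package builds three
complementary quantitative structure–activity relationship (QSAR) models:

1. a **linear 2D model**: ordinary least squares on a forward-selected
   subset of molecular descriptors ("heuristic method" style selection);
2. a **non-linear 2D model**: symbolic regression by gene expression
   programming (GEP) over the same descriptors;
3. a **3D model**: CoMSIA-type Gaussian similarity-index fields around the
   rigidly aligned series, regressed by partial least squares (PLS).

All models fit the transformed activity rather than IC50 itself.

## Activity transform

`pic50Transform()` maps IC50 (µM) to `offset − log10(IC50)` with a default
offset of 6. The offset is the µM→M conversion folded into a constant, so a
1 µM inhibitor scores 6.0 and more potent compounds score higher. Because
the offset only shifts the intercept of any downstream model, the package
uses a single configurable offset for both the 2D and the 3D halves of the
pipeline; model ranks and every dimensionless statistic (R², Q², R²ext) are
unaffected by its value.

The bundled table (`table1CompoundSet()`) carries the 22-compound
nitrogen-mustard series with IC50 from 1.7 µM (compound I1, the most
potent) to 19 µM, and an 18/4 train/test split. Splits are always taken
from the input file or drawn with an explicit seed (`assignSplit()`) —
never from system state — so every partition is reproducible.

# Heuristic descriptor selection

`fitOLS()` reports the statistics selection is driven by: R², the overall F
statistic, per-coefficient t statistics, the residual variance
`s² = RSS/(n−p−1)`, and a leave-one-out cross-validated R² computed through
the PRESS identity (algebraically identical to n refits; the test suite
verifies equality with an explicit refit loop to 1e−10).

`heuristicSearch()` is a beam-width forward selection:

* **candidate pool** — descriptors whose single-descriptor F is at least
  `fFloor` (default 1); weaker columns cannot help any model of interest
  and pruning them keeps the search small;
* **extension rule** — a descriptor may join a model only if its pairwise
  Pearson |r| with every included descriptor stays below
  `collinearityMax = 0.8`, the conventional multicollinearity cap for
  descriptor models;
* **beam** — the 10 best models of each size are extended, which protects
  against the greedy trap of a strong single descriptor shadowing a better
  pair (on small instances the best two-descriptor model matches exhaustive
  pair search in the tests);
* **ranking** — R² first; ties broken by the larger minimum |t| (the model
  whose weakest term is better supported), then by descriptor name order,
  so results are deterministic;
* **size choice** — the trace records R², cross-validated R² and s² for
  sizes 1…`maxSize` (default 7). The default chosen size is the last size
  before the cross-validated-R² gain drops below `delta = 0.02`; the
  published workflow this emulates chose its model size by inspecting the
  same per-size curves, so the trace is kept and the choice can be
  overridden (`chosenModel(trace, size)`).

When no admissible extension exists (small pool, collinearity cap) the
trace truncates with a warning rather than an error: the models found so
far are still valid.

Descriptors themselves are mostly **import-only**: quantum-chemical
descriptors such as minimum electrophilic reactivity indices require a
semi-empirical engine that is out of scope, and no published values exist
to validate a reimplementation against. `computeGraphDescriptors()` covers
the two connectivity-derivable descriptors used alongside them (nitrogen
count NN; average carbon valency AVC, with implicit hydrogens resolved from
standard valences). `assembleDescriptors()` merges sources, drops columns
with missing values or variance below 1e−8 (a stated stand-in for the
unspecified pre-screening of descriptor packages), and logs every removal;
screening is idempotent.

# Gene expression programming

GEP represents a model as a fixed-length linear genome in **Karva
notation**: each gene has a head of length `h` (functions or terminals) and
a tail of length `h·(maxArity−1)+1` (terminals only), which guarantees any
gene decodes to a complete expression tree. Decoding is breadth-first
(`decodeKarva()`); unused trailing symbols are silent, which is what makes
point mutation structurally safe. The function set is the published
operator table: `+ − * /`, `Ln`, `sin`.

Choices the source workflow left unstated, fixed here at canonical GEP
values and all exposed in `GEPConfig`:

| parameter | default | note |
|---|---|---|
| head length h | 8 | tail 9, gene length 17 |
| genes per chromosome | 3 | linked by `+` |
| population | 50 | |
| generations | ≤ 200 | early stop at fitness `≥ 0.999999` |
| mutation | 0.044 per symbol | head→any, tail→terminal |
| inversion / IS / RIS / gene transposition | 0.1 each | |
| one-/two-point recombination | 0.3 each | |
| gene recombination | 0.1 | |
| selection | roulette wheel + single cloned elite | |

**Invalid-math policy.** Division by |denominator| < 1e−12, `Ln` of a
non-positive argument, or any non-finite intermediate yields an invalid
marker (`NA`), and a chromosome that is invalid on any training row scores
fitness 0. No "protected" operators are used: protected division rewards
expressions that exploit the protection constant, which distorts the search
space; invalidation is simpler to reason about and to test. Fitness is the
coefficient of determination of the raw predictions floored at 0, so
roulette weights stay non-negative.

Elitism makes best-so-far fitness non-decreasing, and the whole run is a
pure function of `GEPConfig@seed` (the tests require bit-identical
repeats). Recovery is validated on a catalog of targets expressible in the
function set — `sin(x0)+x1`, `x0·x1+sin(x2)`, `x0/x1+Ln(x2)` — generated at
zero noise with singularities excluded by the sampling domains; the
acceptance suite requires at least one of five seeded runs per target to
reach train R² ≥ 0.95 and held-out R² ≥ 0.9.

# CoMSIA fields and PLS

## Fields

The similarity-index field of field type `k` at lattice point `q` is the
Gaussian-attenuated sum over atoms

$$A_{k}(q) = -\sum_a w_{probe}\, w_{a,k}\, e^{-\alpha r_{aq}^2},$$

with unit probe weight, the conventional negative sign, and attenuation
factor α = 0.3 (the only documented field setting, together with the 2 Å
grid spacing and the 4 Å margin around the aligned set). Five fields are
computed: steric (atom property = vdW radius cubed), electrostatic (partial
charge), hydrophobic (coarse atom-level contribution), and hydrogen-bond
donor/acceptor flags. These per-atom property assignments are the package's
own (the source workflow used undocumented vendor defaults); every property
is overridable per atom in both the JSON interchange format and SDF
(`COMSIA_W_*` tags), and the synthetic molecules bypass chemistry entirely
by carrying explicit properties on pseudo-atoms.

Alignment is rigid Kabsch superposition (`kabschAlign()`; proper rotation,
det +1) onto a template. The template default is the **most active
compound** (lowest IC50): the motivating study describes its template
compound both as most active and as "highest IC50", which conflict — the
package resolves the inconsistency in favour of the standard 3D-QSAR
practice of aligning to the most potent analogue, and lets the user pass
any template id.

The lattice covers the joint bounding box of the aligned set expanded by
the margin; a single atom with 2 Å spacing and 4 Å margin gives 5×5×5 = 125
points. Field values are exactly invariant under joint rigid motion of
molecule and lattice, and refining the grid leaves values at shared points
unchanged — both are tested.

## Column pretreatment and PLS

Lattice columns with standard deviation below 1e−6 are dropped (the
minimum-sigma analogue), and each field block is scaled to unit total
variance (CoMFA-standard-style block scaling) so that no field dominates
through numeric range alone; autoscaling individual columns would instead
inflate remote, barely-varying lattice points. Whether the original
workflow used block scaling or autoscaling is unknowable from its report;
block scaling is the package's documented choice.

`plsFit()` is NIPALS for a single response with internal centering.
Reported statistics follow the usual 3D-QSAR conventions: `SEE =
sqrt(RSS/(n−c−1))` and `F = (r²/c)/((1−r²)/(n−c−1))` with `c` components.
`plsLooOnc()` selects the optimal number of components (ONC) as the
maximizer of the leave-one-out `Q² = 1 − PRESS/SS`, capped at 10, smaller
count on ties; folds are exact refits, and the Q² at the ONC is verified
against the package's independent brute-force `looCv()` loop to 1e−10. At
full rank NIPALS reproduces OLS predictions, which the tests use as a
closed-form oracle.

Contour analysis scores each retained column as `coefficient × column
standard deviation`; per-field contribution fractions are normalized sums
of |score|, and favorable/unfavorable contour levels sit at the 80th
percentile of positive and the 20th percentile of negative scores within
each field.

# Validation

* `r2Ext()` implements the external-validation statistic
  `1 − Σ(yᵢ−ŷᵢ)² / Σ(yᵢ−ȳtr)²` against the training-set mean, with the
  robustness flag strict (`> 0.5`).
* `looCv()` is the deliberately naive refit-every-fold oracle shared by all
  modules.
* "average error" is implemented as mean absolute error on the transformed
  activity scale (`maeError()`); the source of the term does not define it,
  and MAE is the reading consistent with the magnitudes it reports.
* Test-set agreement is serialized both as Pearson r and r², because
  "correlation coefficient" is used ambiguously for either.

# Synthetic data: what it does and does not emulate

The generators (`genDescriptorTable()`, `genSymbolicDataset()`,
`genAlignedMolecules()`) are first-class, tested code. They emulate the
*statistical* structure each stage assumes — a sparse linear signal in a
standard-normal descriptor matrix (optionally with an equicorrelated
block), a symbolic target over bounded domains, a pre-aligned rigid
scaffold with one variable substitution site driving activity through a
single field — with Gaussian noise specified as a fraction of the signal's
standard deviation, which makes recovery thresholds scale-free. Activities
are centered near 5 on the transformed scale so inverse-transformed
pseudo-IC50 values stay in a plausible micromolar range.

They do **not** emulate real nitrogen-mustard chemistry: no conformational
flexibility, no correlated physico-chemical property structure, no
alignment error, and pseudo-atoms instead of elements. Passing recovery
tests therefore demonstrates that the estimators find the structure they
are designed to find at realistic noise — not that a 22-compound series
identifies a six-descriptor model uniquely, and not that the original
study's printed coefficients are reproduced (its descriptor values and 3D
structures were never published, which is also why those printed statistics
are out of the package's validation scope).

Problem sizes used by the test and acceptance suites — n = 60, p = 30 with
25 seeds for subset recovery; populations of 50 over ≤ 200 generations with
5 seeds per symbolic target; 20 molecules × 10 seeds for 3D recovery — are
chosen as the smallest sizes at which the recovery statistics are stable,
so the whole suite runs in well under a minute on one core.

# Numerical choices and degenerate inputs

* OLS rejects rank-deficient designs naming a dependent column; saturated
  fits (n = p+1) are allowed for LOO folds, with inferential statistics
  reported as `NA`.
* `fitOLS`'s LOO uses the PRESS identity; `plsLooOnc` uses explicit fold
  refits; both are tested against the independent `looCv()` loop.
* A constant response makes NIPALS stop extracting components; the model
  then predicts the constant.
* Division guard 1e−12; quantile-based contour levels use type-7 quantiles
  (R default); ONC ties go to the smaller count; heuristic-search ties
  break by minimum |t| then name order.
* JSON reports are written without timestamps and at full precision, so a
  rerun with the same config and seed is byte-identical.

# Known limitations

* Quantum-chemical descriptors cannot be computed — import-only by design.
* No geometry optimization, conformer generation or docking; molecules are
  used as supplied and aligned rigidly.
* The SDF property rules (vdW radii, coarse hydrophobicity, donor/acceptor
  flags) are intentionally simple; for serious use supply curated per-atom
  properties via tags or the JSON format.
* The GEP engine targets small descriptor counts (tens); it evaluates
  chromosomes by interpreted tree walks and is not tuned for large p.
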