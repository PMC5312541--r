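---
title: "Methods: how signalbias simulates, degrades and tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how signalbias simulates, degrades and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalbias)
```

`signalbias` is a simulation laboratory for one question: when Blomberg's
*K* and Pagel's λ are computed on degraded phylogenies — polytomic
chronograms and evenly interpolated pseudo-chronograms — instead of the
true chronograms, how do the statistics and their significance tests
shift? This vignette documents the models, the numerical choices, and the
places where the design was genuinely open.

## 1. The tree model

`sim_pure_birth(n_tips, birth_rate = 1, seed)` simulates a constant-rate
pure-birth (Yule) process forward in time, conditioned on the number of
extant tips. Two lineages start at the root; the waiting time to the next
birth is exponential with rate `birth_rate` times the current lineage
count; the splitting lineage is uniform. The simulation stops at the
birth event that creates the `n_tips`-th lineage and then extends all
lineages by one further exponential waiting time with rate
`n_tips * birth_rate` (*simple-stop* conditioning), so terminal branches
are strictly positive and the tree is exactly ultrametric. Heights are
not rescaled; with `birth_rate = 1` the expected height of an *n*-tip
tree is of order log *n* time units. Other conditioning schemes (e.g.
stopping at a fixed height, or averaging over the full tip-count
distribution) perturb the distributions of tree height and of shape
statistics slightly; the package treats the conditioning as part of the
study conditions and keeps Monte-Carlo tolerances wide enough to absorb
that choice.

Node ages are the canonical representation throughout: branch lengths are
always derived as `age(parent) - age(child)`, so the two can never drift
apart. `as_chronogram()` *rejects* (never repairs) trees violating the
invariants — single root, tips contemporaneous within `1e-8` of the tree
height, non-negative branches, strictly positive terminal branches.

## 2. The two degradations

**Polytomic chronograms** (`collapse_nodes`). A fraction of internal
non-root nodes is deleted and their children re-attached to the parent,
extending branch lengths so every surviving node keeps its exact age; the
output is ultrametric with the same height and tips. Two eligibility
rules are provided: `"shallow"` restricts collapsing to nodes in the
tipward half of the tree (age < H/2), emulating the dense terminal
polytomies of taxonomy-grafted supertrees; `"all"` makes every internal
non-root node eligible. The phrase "above half of the height" could in
principle be read rootward; the tipward reading is the default because
terminal polytomies are the pattern the degradation is meant to emulate,
and the `shallow_side` argument exposes the alternative. Counts are
rounded half-away-from-zero (`round_half_away`) so runs are reproducible
across platforms; the root is never eligible.

**Pseudo-chronograms** (`select_fixed_nodes` + `bladj_calibrate`). The
constraint selector divides `[0, H]` into 5 equal time slices, computes
the target count `m = round(fraction × #internal non-root nodes)`, and
allocates per-slice quotas proportionally by largest-remainder rounding,
raised to one per non-empty slice; if that minimum is unsatisfiable
(m below the number of non-empty slices) the m largest slices get one
node each. The root is always fixed at its true age, preserving the
height.

The calibrator then spaces every undated node evenly between dated
anchors. For an undated node *v* with nearest fixed ancestor *A*
(*d_A* edges up, age *t_A*) and the fixed node or tip *B* at the end of
the **longest undated chain** below *v* (*d_B* edges, age *t_B*, ties
broken towards the smallest age),

$$\mathrm{age}(v) = t_A - d_A\,\frac{t_A - t_B}{d_A + d_B}.$$

Choosing *B* along the longest chain (rather than the nearest anchor) is
what makes a chain of undated nodes between two anchors come out at
evenly spaced ages — a 3-edge chain below a root fixed at 10 gets ages
20/3 and 10/3 — which is the defining behaviour of even-placement
calibration and produces the characteristic *low branch-length
variability* of pseudo-chronograms. A nearest-anchor rule would instead
pull nodes towards their closest dated descendant and leave chains
unevenly spaced. A final monotonicity pass enforces
`age(parent) ≥ age(child) + ε` with `ε = 1e-9·H`, clamping undated nodes
only (fixed nodes keep their exact ages; mutually incompatible fixed ages
are an error naming the offending node). The number of clamped nodes is
reported as an attribute; with constraint ages drawn from the true tree
clamping is rare.

**The combination** (`make_polytomic_pseudochronogram`) applies shallow
collapsing to the pseudo-chronogram; constraint-bearing nodes are never
collapsed. The experiment driver crosses every fix fraction with every
shallow collapse fraction when `combined = TRUE`, since the source
procedure does not pin down a particular pairing.

## 3. Trait simulation

Traits are multivariate normal draws with mean `root_value` (default 0)
and covariance `sigma2 * lambda_rescale(vcv_matrix(tree), lambda_sim)`
(default σ² = 1): `lambda_rescale` multiplies the off-diagonal of the
Brownian VCV by the signal level. Sampling through the covariance (rather
than simulating increments along a λ-rescaled tree) is distributionally
identical for ultrametric trees, exact for polytomies, and directly
testable against the analytic moments. The factorization is Cholesky with
a fallback to an eigendecomposition with eigenvalues clipped at `1e-12`
(message emitted) for near-singular inputs. Traits are simulated **once
per true tree** and reused unchanged on all degraded versions — the trait
is a property of the true history, only the analyst's tree changes.

Seed discipline: one master seed per experiment; every stochastic stage
(tree, traits, collapse draw, constraint draw, permutations) derives a
child seed through a documented counter scheme (`child_seed`), so any
single replicate can be regenerated in isolation and reruns are
bit-identical.

## 4. The signal statistics

Both statistics are computed from the VCV in a single spectral basis per
tree (`signal_basis`): for ultrametric trees `diag(C) = H`, so
`C_λ = λC + (1-λ)H·I` shares the eigenvectors of `C`, and one symmetric
eigendecomposition serves all λ values and all permutations. This is
functionally invisible (dense linear algebra gives the same numbers) but
reduces a thousand-tree run from hours to minutes.

*Blomberg's K* uses the VCV formulation given in the README. The
randomization test permutes trait values across tips and uses the
GLS mean squared error as the statistic (smaller = more signal), with the
add-one correction `p = (1 + #{MSE_perm ≤ MSE_obs})/(1 + n_perm)` so p is
never 0. On binary trees the MSE is identical to the variance of
standardized independent contrasts (unit-tested against `ape::pic` to
1e-8); the VCV form extends it to polytomic trees, where contrasts would
require arbitrary zero-length resolution. Permuting K itself is exposed
via `stat = "k"`; the two orderings are near-equivalent and the MSE form
is the default because it matches the contrast-based description of the
test.

*Pagel's λ* maximizes the profiled likelihood (GLS mean and ML variance
σ̂² = Q/n with divisor *n*, a convention that shifts lnL by a constant
relative to REML) over λ ∈ [0, 1] by Brent search (tolerance `1e-6`)
seeded from a 21-point grid; boundary maxima are reported as exactly 0
or 1. The search is capped at 1 because the rescaling definition of λ
used here caps at 1. The LRT compares against λ = 0 with
`D = 2(lnL̂ - lnL0)` clamped at 0 on χ²₁; because the null sits on the
boundary the test is conservative-to-nominal.

## 5. The paired bias analysis

`classify_bias` implements the dual-α screen: type I iff
`p_true > 0.05` and `p_degraded < 0.01`; type II iff `p_true < 0.01` and
`p_degraded > 0.05`. `bias_frequencies` tabulates frequencies per design
cell with **all pairs in the cell** as the denominator — the frequency of
the joint event, so type I and type II rates are directly comparable
across cells; `conditional = TRUE` switches to denominators restricted to
pairs eligible for the respective bias, for readers who prefer
conditional rates. Raw p-values are stored at full precision and
classification happens at analysis time, so the α levels can be changed
without recomputation. Tree-shape stratification takes the ≤10th and
≥90th percentile tails (linear-interpolation percentiles, inclusive
comparisons) of the gamma or Colless distribution within each tree-size
category; Colless is computed on the binary true chronograms only.

## 6. Problem sizes and what the tests show

The package defaults and the shipped analyses run at desk scale: 100
trees per size for the factorial runs (1000 for the single-treatment
50-tip run, where λ fits on 50×50 matrices are cheap), 200 replicates for
the calibration and recovery checks, 999 permutations for single fits and
199 where thousands of permutation tests are batched (the smallest
attainable p, 1/200, still resolves the 0.01 screen). These sizes were
chosen so the whole suite runs in minutes on one CPU while keeping
Monte-Carlo error well below the effect sizes of interest; the full-scale
design (1000 trees per set, trees up to 1000 tips) is supported by
raising `n_trees` and `tree_sizes` in `experiment_config()`.

What passing tests do show: the permutation test is exact for
exchangeable traits (rejection within 2 points of nominal); K is centred
at 1 under Brownian motion; λ̂ recovers its simulated value; the
degradations preserve exactly what they claim to preserve; calibration
flattens branch lengths; and the paired analysis reproduces the
directional headline (λ robust, K pushed towards false positives by
pseudo-branch lengths). What they do **not** show: anything about real
phylogenies. Pure-birth trees lack extinction, rate variation and
sampling biases; real supertree polytomies are phylogenetically
clustered, not uniform draws; and real calibration ages carry error,
whereas the simulated constraints are exact. The degradation–statistic
interactions measured here should transfer qualitatively, not the
absolute frequencies.

## 7. Known limitations

- Only ultrametric trees are supported; non-ultrametric inputs are
  rejected rather than analysed.
- λ > 1 (signal stronger than Brownian motion) is outside the parameter
  space, so traits more conserved than BM are reported as λ̂ = 1.
- The even-placement calibrator reproduces the *behaviour* of
  even-age interpolation, not any specific software byte-for-byte; its
  tie-break (longest chain, then smallest age) is documented above and
  logged through the clamp counter.
- `gamma_statistic` and `colless_index` require binary trees by
  definition; degraded (polytomic) trees are stratified by the statistics
  of their true counterparts.
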