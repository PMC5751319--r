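---
title: "Gaussian KDA and reconstruction-error scale selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian KDA and reconstruction-error scale selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdaselect)
```

This vignette records the model, the algorithmic and numerical choices, and
the limitations of the package, at the level of detail a maintainer or a
reviewer of the method would want.

## The model

Kernel discriminant analysis performs Fisher discriminant analysis in the
feature space induced by a kernel. With `N` training samples in `C`
classes (`N_i` per class) and the Gaussian kernel

$$K(x, y) = \exp(-\lVert x - y\rVert^2 / s^2),$$

the discriminant directions never need an explicit feature map: writing
each direction as a kernel expansion over the training samples with
coefficient vector $a$, the Fisher criterion becomes the generalized
Rayleigh quotient

$$J(a) = \frac{a^\top \tilde M a}{a^\top \tilde L a}, \qquad
\tilde M = \sum_{i=1}^{C} N_i (M_i - M)(M_i - M)^\top, \qquad
\tilde L = \sum_{i=1}^{C} K_i \left(E - \tfrac{1}{N_i} J\right) K_i^\top,$$

where component $k$ of $M_i$ is the mean kernel value between sample $k$
and class $i$, $M$ is the analogous grand mean, $K_i$ is the $N \times
N_i$ block of kernel values against class $i$, $E$ is the identity and
$J$ the all-ones matrix. The fitted model keeps the top
$d \le C - 1$ eigenvectors of $\tilde L^{-1} \tilde M$ (the between-class
scatter has rank at most $C - 1$, so more directions carry no
discriminant signal). A query $x$ is projected by
$t_k(x) = \sum_j \alpha_{jk} K(x, x_j)$.

### Reconstruction error

Because $K(x, x) = 1$ for the Gaussian kernel, the squared distance from
the feature-space image of $x$ to its projection onto the fitted subspace
collapses to

$$RE(x) = 1 - \lVert t(x)\rVert^2,$$

*provided* the coefficient columns are orthonormal in the kernel metric
($\alpha^\top K \alpha = I$). Generalized eigenvectors are not
automatically kernel-orthonormal, so the fit orthonormalizes them after
solving; without this step the identity above is false and the selection
objective below loses its meaning. With it, $RE \in [0, 1]$ by Bessel's
inequality, which the test suite asserts across random models.

### Scale selection

The selector exploits a novelty-detection intuition: for a well-chosen
scale, samples at the boundary of a class should be reconstructed markedly
worse than samples at its core, while the core reconstructs consistently.
From the largest class the package picks

* **edge samples** — centroid distance strictly above the class median
  *and* at least one other-class sample inside the ε-ball;
* **internal samples** — centroid distance strictly below the median *and*
  an ε-ball free of other classes,

with ε the mean distance to the `u`-th nearest neighbour over the class
members (`u = 8` by default). The chosen scale maximizes

$$f(s) = \frac{\lVert RE(\Omega_{ed})\rVert_\infty -
               \lVert RE(\Omega_{in})\rVert_\infty}
              {\mathrm{std}\{RE(\Omega_{in})\}}.$$

Because the rules hinge on the *median centroid distance* rather than on
local tangent-plane geometry, a class lying entirely on a sphere — the
failure mode of border-pattern edge detection, where every sample's
neighbours fall on one side of its tangent plane — still yields a
non-degenerate split: at most half the members can strictly exceed the
median distance.

The grid-search baseline fits KDA per candidate scale and measures
leave-one-out KNN accuracy in the reduced space; it is the accuracy
optimum the selector is compared against. The selector does the same
number of KDA fits but no classifier work, which is the entire efficiency
argument; the package asserts this as call counts rather than wall-clock.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `s` | Gaussian scale (same units as feature distances) | selected from `S = {0.1, 0.2, 0.3, 0.4, 1, 2, 3, 4}` | the experiment protocol's candidate set |
| `d` | retained discriminants | `C − 1` | the maximum informative dimension |
| `u` | neighbour rank defining ε | 8 | the protocol default; downstream accuracy is insensitive to `u` in 6–10, which the suite checks |
| `k` | KNN neighbours | 20 (5 on the 60-sample demo) | protocol default; scaled to the demo's class size |
| `reg` | relative ridge on $\tilde L$ | `1e-8` | see below |
| `xi_max` | PsePSSM lag depth | 49 | gives the canonical 1000 dimensions |

## Feature encodings

**PsePSSM**: column means $\bar M_j = \frac1L \sum_i M_{i\to j}$ plus, for
each lag $\xi = 1..\xi_{max}$, the mean squared difference
$G_j^\xi = \frac{1}{L-\xi}\sum_i (M_{i\to j} - M_{(i+\xi)\to j})^2$. The
zero-lag block would be identically zero, so lags start at 1 and the mean
block takes its place — that is what makes $20(1 + 49) = 1000$ come out.
Scores enter raw; an optional logistic squashing flag exists but is off by
default, since raw log-odds are the reference behaviour.

**PSSM-S** (220 = 20 + 20 + 80 + 100): the four blocks are AAO (consensus
residue occurrence frequencies; consensus = row argmax, ties to the
earliest column), PSSM-AAO (column sums over `L`), PSSM-SD (per column,
the normalized positions at which the running absolute-score mass first
reaches 25% and 50% of the column total, from each terminus), and
PSSM-SAC (mean-centered auto covariance at lags 1–5 per column). The
literature fixes only the block names and sizes, not the formulas; these
choices are consistent with both and are validated against an independent
loop oracle in the tests. They are configurable (`sd_fracs`, `sac_lags`)
for fidelity experiments against other implementations.

## Numerical choices

* **Kernel exponent.** The kernel is implemented as
  $\exp(-\lVert\cdot\rVert^2/s^2)$, without the factor 2 sometimes placed
  in the denominator; the variant only rescales the candidate grid by
  $\sqrt 2$, so nothing downstream depends on the convention.
* **Ridge.** $\tilde L$ is generically singular (rank $\le N - C$), so
  the solve uses $\tilde L + \mu I$ with $\mu = 10^{-8}\,
  \mathrm{tr}(\tilde L)/N$, floored at $10^{-12}$ and inflated by factors
  of 100 (up to six attempts) if the Cholesky factorization still fails —
  relevant in the large-scale degeneracy limit where the kernel matrix
  approaches all-ones and $\mathrm{tr}(\tilde L) \to 0$.
* **Eigen-solve.** The symmetric-definite generalized problem is reduced
  by Cholesky ($\tilde L + \mu I = R^\top R$, then a symmetric eigen
  decomposition of $R^{-\top} \tilde M R^{-1}$) rather than forming an
  explicit inverse; eigenvalues are then real and non-negative up to
  roundoff.
* **Determinism.** Eigenvector sign is fixed by making the first
  non-negligible coefficient positive; argmax ties in both selection
  routes go to the smallest scale (favouring the smoother kernel); KNN
  distance ties resolve by training order and vote ties by the
  best-ranked neighbour of a tied class.
* **Clamping.** Reconstruction errors are clamped to $[0, 1]$; a
  violation beyond $10^{-8}$ warns, since it indicates a degenerate fit
  rather than roundoff.
* **Degenerate inputs.** A singleton class is allowed in the fit (its
  within-class block is exactly zero). A boundary sample sitting exactly
  at the median centroid distance joins neither edge nor internal set —
  the rules are strict inequalities and deliberately non-exhaustive, and
  unassigned samples are simply left out rather than defaulted to
  internal. An empty edge or internal set is an error suggesting a
  different `u`, because the objective is undefined without both. A zero
  internal spread makes the objective undefined for that candidate; such
  candidates are excluded from the argmax with a warning, and an error is
  raised only if every candidate is undefined.

## Design decisions on genuinely open points

* **Fit set during selection.** Each candidate's KDA is fitted on the full
  labeled dataset and only the reconstruction errors are restricted to the
  edge/internal sets. KDA needs at least two classes, so the largest class
  alone could not serve as the fit set.
* **Neighbour pool.** Both the ε-ball membership test and the `u`-th
  neighbour distances are taken over the *full* dataset, consistent with
  the ε-neighbourhood being defined over all samples; restricting the
  radius computation to the class alone is a defensible alternative that
  would only rescale ε.
* **Standard deviation.** The objective's denominator uses the sample
  standard deviation (`n − 1`); with the internal sets this selector
  produces the distinction from the population form is far below the
  resolution of the argmax.
* **Specificity.** The package reports the standard
  $TN/(TN+FP)$; a historical variant $TN/(TP+FP)$, which can exceed 1 and
  is not a specificity, is available behind `spe_variant = "printed"` for
  comparison work. MCC is reported on $[-1, 1]$ and Sen/Spe/Q as
  proportions; undefined ratios (zero denominators) surface as `NA` and
  print as `"-"`, never as numbers.
* **Jackknife.** The default refits KDA in every fold (statistically
  correct). A `fast` mode fits once on all data and leaves only the KNN
  step out-of-sample; it is what grid search uses internally, matching
  the cost profile of a screening run. The two agree on well-separated
  data (asserted on a fixture) and may diverge elsewhere — fast mode is
  mildly optimistic because the held-out sample influenced the subspace.

## What the synthetic generators do and do not emulate

`make_blobs` produces equidistant isotropic Gaussian classes — the regime
where any reasonable method works; it is used to validate algebra, not
difficulty. `make_rings` produces concentric noisy shells: linearly
inseparable, the motivating case for kernel methods, and in the noiseless
limit the exact all-on-a-sphere configuration that breaks tangent-plane
edge selection. `make_pssm` draws integer scores uniformly from a typical
log-odds range, and `demo_localization` induces class structure by
shifting each class's scores — enough to reproduce the *shapes* of the
bacterial benchmarks (4 or 8 classes, 1000- or 220-dimensional), nothing
about their biology.

The demonstration dataset `demo_rings` (radii 1 and 2, noise 0.2, 30
points per class) was designed so the selection rule is exercisable at
`u = 8`: the ε radius on the inner ring is about 0.8, so members pushed
outward by noise have other-class points inside their ε-ball (edge rule
satisfiable) while members pushed inward do not (internal rule
satisfiable). Wider ring spacing makes the split degenerate — a real
constraint of the method worth knowing: on data whose classes are very
far apart relative to within-class spacing, no member of the largest
class has foreign neighbours and the selector refuses to run.

Consequently, passing tests show the machinery is correct and the
selector's agreement with grid search holds on controlled nonlinear
geometry; they do not show that the selected scale is optimal for real
proteomes, which requires the external benchmark sets and PSI-BLAST
profiles.

## Problem sizes used in the checks

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is non-trivial: 12-sample,
3-class data for the scatter-matrix oracle; 10 seeded problems × 200
random directions for Rayleigh optimality; 20 random models × 5 queries
for the reconstruction-error bounds; five 60-sample two-ring datasets for
selector/grid agreement; `u ∈ {6,…,10}` on one of them for robustness; a
40-point noiseless shell for the degenerate-geometry regression.

## Known limitations

* The selector requires both edge and internal samples to exist in the
  largest class; very clean, well-separated data defeat it (see above).
* `fast` jackknife is optimistic on small or unstable fits.
* Only the Gaussian kernel is implemented; the architecture admits other
  kernels but none is specified or tested.
* Strict jackknife refits are $O(N)$ eigen decompositions of size $N$;
  beyond a few thousand samples a solver exploiting low-rank updates
  would be needed.
* The PSSM-S block formulas are one defensible reading of the published
  block names and sizes; exact numeric parity with other PSSM-S
  implementations is not guaranteed.
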