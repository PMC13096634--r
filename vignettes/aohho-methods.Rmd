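---
title: "Hybrid AO-HHO hyperparameter tuning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid AO-HHO hyperparameter tuning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science inside `aohho`: the two metaheuristics
and their hybridization, the CNN objective they minimize, the synthetic
image generator used to exercise the full pipeline, and every place where a
design decision had to be made that the underlying formulations leave open.

## The optimization problem

A convolutional network's behaviour is governed by hyperparameters fixed
before training. `aohho` tunes five of them over the mixed space

| hyperparameter | domain | decoding |
|---|---|---|
| learning rate | [1e-4, 1e-2] | log-uniform |
| batch size | {16, 32, 64} | equal-width bins |
| base filters | {32, 64, 128} | equal-width bins |
| dropout rate | {0.3, 0.5} | equal-width bins |
| optimizer | {adam, sgd} | equal-width bins |

Population-based optimizers such as AO and HHO act on real vectors, so the
search runs in the unit hypercube $[0,1]^5$ and `decode_config()` maps each
vector to a configuration: the learning-rate coordinate is decoded
log-uniformly (the range spans two decades; a linear map would give the
top decade 90% of the mass), and each categorical coordinate is decoded by
equal-width binning with the boundary value 1 assigned to the last bin so
the decoder is total on the closed cube. `encode_config()` inverts the map
through bin centers, making decode-after-encode the identity — a property
the test suite checks exhaustively over all categorical combinations.
Whether the original formulation searched a relaxed continuous space or a
discrete one is not documented anywhere we know of; the continuous
relaxation is this package's choice, made because it keeps every AO/HHO
update equation usable verbatim.

## Aquila Optimizer (AO)

AO models four hunting behaviours of the eagle *Aquila*; each iteration
every agent proposes a new position with one of them:

* **X1, high soar with vertical stoop** (exploration):
  $X_{best}(1 - t/T) + (X_M - X_{best}\,r)$, with $X_M$ the population mean.
* **X2, contour flight with short glide attack** (exploration):
  $X_{best} \cdot LF(D) + X_R + (y - x)\,r$, where $X_R$ is a uniformly
  chosen other agent and $(x, y)$ come from a spiral with radius
  $r_1 + 0.00565\,D_1$ and angle $-\omega D_1 + 3\pi/2$ over coordinate
  indices $D_1$, $r_1 \sim U[1, 20]$.
* **X3, low-flying strike** (exploitation):
  $(X_{best} - X_M)\alpha - r_1 + ((UB - LB) r_2 + LB)\delta$ with
  $\alpha = \delta = 0.1$.
* **X4, stalking and grabbing** (exploitation):
  $QF\,X_{best} - G_1 X r_1 - G_2\,LF(D) + r_2 G_1$ with quality function
  $QF = t^{(2r-1)/(1-T)^2}$, mobility $G_1 = 2r - 1 \in [-1, 1]$ and flight
  slope $G_2 = 2(1 - t/T)$ decaying linearly from 2 to 0.

$LF(D)$ is a Mantegna Lévy flight, component-wise
$s\,u\,\sigma/|v|^{1/\beta}$ with $u, v$ standard normal, $s = 0.01$,
$\beta = 1.5$. Three conventions had to be fixed here:

* Some printings of the Lévy denominator show $|v|^{\beta}$; with
  $\beta = 1.5$ that *shrinks* large $|v|$ draws instead of heavy-tailing
  the steps, defeating the purpose of a Lévy flight. The package uses the
  canonical Mantegna exponent $1/\beta$ and exposes `strict_levy = TRUE`
  on `ao_params()` for comparison with the literal form.
* $\sigma$ is the gamma-function bracket itself (not raised to $1/\beta$);
  any constant step-scale difference from the classic recipe is absorbed
  by $s$. The suite pins $\sigma(1.5)$ against an arbitrary-precision
  gamma evaluation to $10^{-10}$.
* Every scalar `rand` appearing in an equation is one uniform draw shared
  across coordinates (not redrawn per component), matching the reference
  AO implementation.

No published switching rule selects among X1–X4; the package follows the
canonical AO schedule: X1/X2 with equal probability for the first
$2/3$ of iterations, X3/X4 afterwards (`exploration_fraction`, exposed).
Acceptance of a proposal is greedy — an agent moves only if the proposal is
not worse — which is what guarantees the monotone best-so-far trace that
the tests assert; the iteration counter is 1-based so $t^x$ in $QF$ is
always defined.

## Harris Hawks Optimization (HHO)

HHO's schedule is driven by the prey's escape energy
$E = 2 E_0 (1 - t/T)$. While $|E| \ge 1$ the hawks explore with one of two
perching rules (chosen by a uniform draw $q$); once $|E| < 1$, the escape
probability $r$ and the energy select among four besiege modes:

* **soft** ($r \ge 0.5$, $|E| \ge 0.5$): $\Delta X - E\,|J X_{best} - X|$
  with jump strength $J = 2(1 - r')$;
* **hard** ($r \ge 0.5$, $|E| < 0.5$): $X_{best} - E\,|\Delta X|$;
* **soft/hard with progressive rapid dives** ($r < 0.5$): two candidates,
  $Y = X_{best} - E\,|J X_{best} - X|$ and $Z = Y + S \cdot LF(D)$ with
  $S \sim U[0,1]^D$; the better one replaces the agent only if it improves,
  and $Z$ is only evaluated when $Y$ fails to improve (lazy evaluation, so
  dive moves never worsen an agent and cost at most one extra evaluation).

Conventions fixed here: $q$, $r$ and $E_0$ are uniform draws per agent per
iteration ($E_0 \in [-1, 1]$; describing $q$ as a 0/1 integer would let the
second perching branch fire with probability zero); $|\cdot|$ is the
component-wise absolute value; the hard-dive variant reuses the same
$Y$/$Z$ equations with the agent's own position as anchor, with
`canonical_hard_dive = TRUE` switching to the population-mean anchor used
in the original HHO description. The Lévy generator is shared with AO
(same $s$, $\beta$) since both formulations define $LF(D)$ identically.

## The hybrid

The hybrid runs AO for the first `switch_fraction` (default 0.5) of the
iteration budget and then hands the *entire population and incumbent best*
to HHO unchanged — an elitist hand-off with no re-initialization, so the
best-so-far trace cannot increase at the seam. "A few initial iterations"
is the only published guidance on the switch point; 0.5 is this package's
default and the fraction is exposed. With `switch_fraction = 1` the hybrid
is bit-identical to AO alone under the same seed, with 0 to HHO alone —
the ablation helper `ablate()` exploits this to run paired arms from
identical initial populations. Early stopping declares convergence when
the last `patience` (default 10) successive changes of the best objective
are below `epsilon` (default 1e-4); both defaults are the package's own,
chosen conservatively because CNN validation losses are noisy at small
epoch counts. Note that on trivially smooth problems early stopping can
halt refinement well above machine precision — the convergence fixtures in
the tests therefore run with it disabled.

Duplicate decoded configurations are served from a cache keyed by the
configuration (not the raw vector), so categorical plateaus do not trigger
redundant CNN trainings; `evaluations_used` counts actual trainings.

## The CNN and the composite objective

The classifier is deliberately small: two valid 3×3 convolution blocks
(ReLU, 2×2 max-pool) with the second block holding twice the base filter
count — generalizing the printed 32→64 template to the tuned filter
hyperparameter — then a 128-unit dense layer, inverted dropout, and a
4-way softmax on 64×64 single-channel inputs. Kernel 3×3, pool 2×2,
stride 1 are the universal defaults for such a sketch. No R deep-learning
framework is assumed: the engine is ~300 lines of RcppArmadillo
(im2col + GEMM convolutions, exact backprop verified against central
finite differences in the tests, Adam and plain SGD). Training runs in
single precision — the GEMMs dominate and sgemm is about twice dgemm —
while the gradient-check entry point uses double precision. All
randomness (He-initialized weights, shuffling, dropout masks) is drawn
from R's RNG, so a seed makes training bit-reproducible.

Candidates are scored by
$J(\theta) = \lambda_1 \mathrm{Loss}(\theta) + \lambda_2 T(\theta)/T_{max}$,
with Loss the validation cross-entropy on a stratified 80/20 split of the
tuning data and $T$ either wall-clock seconds (`time_mode = "measured"`) or,
by default, a deterministic proxy built from the forward-pass complexity
$O(N \sum_i L_i F_i^2)$: epochs × batches × batch size × $\sum_i 9 L_i$.
The proxy makes the objective hardware-independent and reproducible, which
is why every test and the acceptance script use it. $\lambda_1 = 1$,
$\lambda_2 = 0.1$ and $T_{max}$ = the proxy of the most expensive
configuration in the space are package defaults (no published values
exist); with that normalization the time term is at most 0.1 and acts as a
tie-breaker between configurations of similar loss. A non-finite
validation loss (diverged training) is mapped to a large finite penalty so
the search continues. Metrics are computed from the confusion matrix with
one-vs-rest reductions and **macro** averaging — a point the reported
tables do not state, but micro averaging would force precision = accuracy,
which those tables contradict. Training epochs per candidate evaluation
are likewise unreported anywhere; the package defaults to 3 during tuning
and 8 for the final refit.

## The synthetic image generator

`generate_dataset()` emulates a 4-class brain-MRI-like task: a smooth
elliptical "head" with radial intensity falloff plus a class-specific
lesion — glioma a large irregular off-center diffuse blob (three
overlapping Gaussians), meningioma a round bright peripheral blob,
pituitary a small bright central blob, no-tumor background only — with
per-image geometric jitter, additive Gaussian noise (`noise_sd`, default
0.05 on [0,1] intensities), and a difficulty dial `class_overlap` that
interpolates every lesion template toward the across-class mean (1.0 makes
the templates identical). Default class counts follow the public data's
training-set balance (1321/1339/1595/1457 for glioma, meningioma,
no-tumor, pituitary). The geometry was calibrated once so that, at zero
noise, class-mean images are more than 5× further apart than the
within-class spread, then frozen; the tests verify both that margin and
that a nearest-class-mean template classifier is perfect on a fresh clean
draw.

These are geometric caricatures, not anatomy: there is no MRI physics, no
3-D structure, no scanner artifacts, no interclass similarity of the kind
real gliomas and meningiomas exhibit. Passing the end-to-end recovery test
therefore shows that the optimizer-plus-CNN machinery works — it finds a
configuration whose refit network separates separable classes — and says
nothing about accuracy on real MRI data. Augmentation (rotation ±15°,
horizontal flip at 0.5, zoom 0.9–1.1, ±10% shifts, composed into a single
bilinear affine via EBImage with background padding 0) is available for
training only and is off during tuning evaluations, where determinism and
small epoch budgets matter more than regularization; flips are exact row
reversals so a double flip restores the input bit-for-bit.

## Statistical validation

`repeated_runs()` repeats the tune-refit-test pipeline over a seed list
(default five runs) and reports per-metric mean and sample SD (n−1).
`pairwise_test()` compares two optimizers' per-run metrics with a paired
two-sided t-test and 95% t-interval — pairing is by shared seed, which is
what makes the arms comparable; identical vectors are reported as p = 1
with a zero-width interval rather than an undefined statistic. No
multiple-testing correction is applied (the emitted report says so in a
footnote), matching the raw-p-value presentation convention of the tables
this format mirrors. `emit_report()` writes deterministic CSVs: point
metrics, formatted mean ± SD, pairwise tests, optional ablation and cost
tables, convergence traces, confusion matrices.

## Validation problem sizes

The convergence fixtures run the optimizers on the classic benchmark
functions, with domains fixed a priori to the De Jong boxes: sphere and
Rastrigin on $[-5.12, 5.12]^5$, Rosenbrock on $[-2.048, 2.048]^5$. The
suite requires median-over-10-seeds best objectives of at most 1e-2 (AO),
1e-2 (HHO) and 1e-3 (hybrid) on the sphere at population 15 / 100
iterations, and at most 5.0 on Rastrigin at population 20 / 150
iterations. The end-to-end recovery test uses 100 images per class at
noise 0.05 and zero overlap, population 4, 6 iterations, 3 epochs per
evaluation, and requires refit test accuracy of at least 0.90; these sizes
keep a full run in the minutes range on a single CPU while still
exercising every stage.

## Known limitations

* The search space is flat; conditional or hierarchical spaces (e.g.
  optimizer-specific learning-rate ranges) are out of scope.
* Fitness evaluations are sequential; no parallel population evaluation.
* Constraint handling is box clipping only.
* Plain SGD (no momentum) is deliberately minimal; at the bottom of the
  learning-rate range it trains very slowly, which the tuner learns to
  avoid but which makes some corners of the space poor.
* Wall-clock `time_mode = "measured"` is hardware-dependent and excluded
  from every reproducible check.
* The dive modes evaluate up to two candidates per agent per iteration, so
  an iteration containing them can cost up to twice the population size in
  evaluations; the reported `evaluations_used` is the exact training count.
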