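---
title: "Screening medium supplements with a Plackett-Burman design and an SVR surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening medium supplements with a Plackett-Burman design and an SVR surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsvr)
```

## The problem

Serum-free media for mammalian cell culture are built from a long list of
candidate supplements (trace metals, carrier proteins, polyamines, iron
sources, ...), and each cell line responds differently. Testing all level
combinations of even seven supplements is out of the question, so the
screening stage asks a cheaper question: *which few supplements actually
move the growth rate?* `pbsvr` implements a complete analysis pipeline for
that stage, built around the packaged case study `cho_screen()`: a 12-run
screen of seven supplements (ZnSO4, transferrin, putrescine, BSA, ferric
citrate, sodium pyruvate, ethanolamine) for suspension CHO-K1 cells, with
the specific growth rate (d^-1^) after 72 h as the response.

The pipeline has two independent legs that should tell the same story:

1. **Design-based statistics.** A Plackett-Burman (PB) design assigns every
   supplement a low (-1) and high (+1) concentration and varies all of them
   simultaneously in an orthogonal pattern. Range analysis and a
   single-degree-of-freedom contrast ANOVA then rank the supplements.
2. **A machine-learning surrogate.** An epsilon-support-vector regression
   (SVR) with an RBF kernel is trained on the same 12 runs, its
   hyperparameters tuned by a genetic algorithm, and the influence of each
   supplement is measured by mean-impact-value (MIV) perturbation. Agreement
   between the two legs is the method's internal cross-check.

## The design leg

### Plackett-Burman designs

`pb_design(n, m)` builds the classical cyclic-generator PB arrays for
n = 8, 12, 16, 20, 24 runs. Two invariants define validity and are enforced
in exact integer arithmetic by `screen_design()`: every column is balanced
(equal runs at each level) and every pair of columns is orthogonal. With
n runs up to n - 1 main effects can be screened; two-factor interactions
are aliased with main effects and are *not* estimable — the screen
deliberately trades them away for economy. The packaged case study stores
its run matrix verbatim in its published "Trial" order (which is not the
generator order); the validity invariants, not a specific row order, are
what the analyses rely on.

### Range analysis

For factor $j$, $t_{1j}$ and $t_{2j}$ are the mean responses at the high
and low level and $R_j = |t_{1j} - t_{2j}|$ ranks influence. The reported
$T$ rows follow the convention of the case study's published report,
$T = 2t$ (for a 12-run screen in triplicate this equals the level sum
divided by 3, not the raw sum); the package computes all columns at full
precision. Ties in the $R$ ranking are broken by factor order, so output
ordering is deterministic.

### Contrast ANOVA

In a balanced orthogonal two-level design each factor's contrast
$c_j = \sum_{+1} y - \sum_{-1} y$ carries one degree of freedom and
$SS_j = c_j^2 / n$. With $m$ factors in $n$ runs the pooled residual has
$n - 1 - m$ degrees of freedom (4 for the 12-run, 7-factor screen) and each
factor is tested against $F(1, n-1-m)$. The decomposition
$\sum_j SS_j + SS_{err} = SS_{tot}$ is exact and is verified to a relative
$10^{-10}$ in the tests, along with location invariance, scale
equivariance, and agreement of each $SS_j$ with a per-factor least-squares
fit. A response with (numerically) zero variance is reported as an
undefined-F case with a warning rather than silently producing 0/0.

On the packaged screen the ANOVA declares BSA (X4) and ferric citrate (X5)
significant at $\alpha = 0.05$, with ZnSO4 (X1) just above the threshold
(p = 0.0589); the range analysis ranks the same three supplements on top.

## The surrogate leg

### Epsilon-SVR via SMO

`svr_fit()` solves the standard dual of epsilon-insensitive SVR with the
RBF kernel $K(u, v) = \exp(-\gamma \lVert u - v \rVert^2)$: minimise over
$\alpha, \alpha^* \in [0, C]^n$ with $\sum(\alpha^* - \alpha) = 0$

$$\tfrac12 (\alpha - \alpha^*)^\top Q (\alpha - \alpha^*)
  + \varepsilon \sum_i (\alpha_i + \alpha_i^*)
  - \sum_i y_i (\alpha_i^* - \alpha_i), \qquad Q_{ij} = K(x_i, x_j),$$

giving the prediction $f(x) = \sum_i \beta_i K(x, x_i) + b$ with
$\beta_i = \alpha_i^* - \alpha_i$. The solver is sequential minimal
optimization with maximal-KKT-violating pair selection (ties by lowest
index), stopping at a KKT gap below `tol` (default $10^{-6}$). The bias is
averaged over the KKT estimates of unbounded support vectors, or taken as
the feasible-interval midpoint when every support vector is at bound. The
full Gram matrix is cached — trivially affordable at these sample sizes.
Correctness is established against two independent routes: a generic
interior-point QP solve of the same dual (`kernlab::ipop`, dual objectives
within $10^{-6}$ over 50 random instances) and LIBSVM predictions
(`e1071`, tight tolerance).

Numerical conventions worth knowing:

* **Features are the coded -1/+1 settings**; natural-unit inputs are
  encoded through the model's factor table at prediction time. Responses
  are left unscaled.
* **Tube width.** $\varepsilon$ defaults to 0.01 d^-1^, an order of
  magnitude below the response span of the case study (0.124–0.319 d^-1^),
  so the surrogate can track the data closely without chasing every last
  digit. It is freely configurable; published error statistics of this kind
  of analysis cannot be pinned down without knowing $\varepsilon$, so the
  package reports its own fit metrics (`mse_half()`, the SVM-conventional
  half-sum of squared residuals, and `r_squared()`).
* **Iteration cap** defaults to `max(1000, 10 n^2)` (hard cap $10^5$);
  non-convergence is an error reporting the residual KKT gap, never a
  silent partial fit.

### Hyperparameter search

`svr_tune()` searches $(C, \gamma)$ over $[0.01, 100] \times [0.01, 1000]$
with a real-coded genetic algorithm (population 20, 200 generations,
tournament selection of size 2, blend crossover with probability 0.7,
Gaussian mutation with probability 0.1 and per-gene sd of 10% of the box
width, elitism 1, fixed seed). Two design choices deserve explanation:

* **Fitness is leave-one-out CV error** (mean squared, `loo_cv_mse()`).
  With 12 runs, LOO costs twelve small fits per candidate and is the
  honest estimate of out-of-sample error; a training-error fitness
  (`fitness = "train"`) is available for comparison and, as expected,
  drives $\gamma$ toward large values where the model memorises the runs.
* **The GA works in log coordinates** (`scale = "log"`, the default).
  $C$ and $\gamma$ are scale parameters spanning four to five decades; in
  linear coordinates the cross-validation basin ($\gamma \lesssim 1$)
  occupies about 0.1% of the box and a linear-space search reliably stalls
  on the flat large-$\gamma$ plateau. Log space is the natural metric, and
  the same operators applied there locate the basin consistently. A
  `scale = "linear"` option preserves the naive behaviour for study.

Under the default seed the tuned surrogate lands at small $\gamma$ (around
0.01–0.05 depending on seed) — a smooth, nearly additive fit — rather than
at a memorising large-$\gamma$ configuration, even though the latter has
the higher training $R^2$. Both regimes fit the training runs well; they
differ in what they generalise, which matters for importance analysis
(below).

### Mean-impact-value importance

`miv()` perturbs each supplement's column by $\pm 10\%$ *in natural
units* (concentrations), re-encodes through the model's scaling, and
reports the mean prediction difference. Perturbing the coded matrix
directly would be degenerate: the $\pm 10\%$ shifts point in opposite
directions at the two levels of a balanced column, and any linear effect
cancels exactly. For a linear predictor the natural-unit scheme gives the
closed form $MIV_j = 2\delta \beta_j \overline{u_j}$, which the tests
verify to $10^{-10}$.

#### Why perturbation importance collapses for a memorizing kernel

A subtler degeneracy affects *any* symmetric multiplicative or additive
perturbation pushed through an RBF model with large $\gamma$. The +10% and
-10% versions of an entry sit at equal coded distance $\delta$ on either
side of it, and the kernel is an even function of that offset, so the
contribution of each sample's own kernel term to
$f(X^+) - f(X^-)$ cancels *exactly*. What remains are cross-terms between
different runs, which are of order $e^{-\gamma (2-\delta)^2}$ — at
$\gamma \approx 90$ on coded data that is below $10^{-100}$, i.e. under
floating-point noise. A near-interpolating surrogate therefore yields MIV
values that are pure rounding noise, and its importance ranking is
meaningless, even though its training $R^2$ looks excellent. This is the
practical reason the default pipeline tunes by cross-validation: in the
moderate-$\gamma$ regime the cross-terms carry real signal and the MIV
ranking is stable. On the packaged screen the tuned surrogate's top three
supplements by $|MIV|$ coincide (as a set) with the range-analysis top
three — ferric citrate, BSA, ZnSO4 — which is the pipeline's headline
consistency check.

### Response exploration

`corner_predictions()` evaluates the surrogate at all $2^k$ corners of a
chosen supplement subset (Gray-code enumeration, deterministic tie-break
by enumeration order; excluded factors held at -1, the leaner medium, by
default). `grid_predictions()` produces contour-ready grids over two
factors, and `predict_expanded_levels()` rescales all concentrations by a
common factor (e.g. 1.5) — such settings leave the trained range, are
flagged as extrapolations, and an RBF surrogate decays toward its bias
there, so they should be read qualitatively. On the packaged screen the
best corner of {ZnSO4, BSA, ferric citrate} is the all-high corner.

## The synthetic-data generator

`synthetic_spec()` + `simulate_response()` generate two-level screens with
known truth: $y_i = \beta_0 + \sum_j \beta_j x_{ij} + \text{interactions}
+ N(0, \sigma^2)$, clipped at zero (with a message) because growth rates
are non-negative. Defaults emulate the case study's scale: intercept
0.24 d^-1^ and $\sigma = 0.01$ d^-1^, the order implied by the screen's
residual mean square. `recovery_report()` replicates the screen and
reports per-factor detection rates and effect-estimate bias; on orthogonal
designs $(t_1 - t_2)/2$ recovers $\beta_j$ exactly at $\sigma = 0$ and
unbiasedly under noise.

What the generator does *not* emulate: replicate-level error structure
(one response per run, as in the case study), heteroscedasticity,
non-Gaussian noise, and any mechanistic growth kinetics. Passing recovery
tests therefore demonstrates the statistical machinery, not biological
realism.

Problem sizes used by the test-suite and the acceptance script: 200
replicates for power at the case study's effect scale (0.04 d^-1^ on two
factors, 0.02 on one, $\sigma = 0.01$), 2000 replicates for the type-I
error of the null screen, 50 random instances for the solver/QP-oracle
comparison, and the full population-20 x 200-generation GA for the
quadratic-recovery and tuning runs.

## Known limitations

* PB screens alias interactions with main effects; a strong interaction
  will masquerade as (or hide) a main effect in both legs of the pipeline.
* Twelve runs is a small training set for any nonlinear surrogate; the
  SVR's value here is ranking and interpolation inside the design box, not
  extrapolation.
* The GA's published-style configuration is a reference point, not a
  reproducibility guarantee: different operators/seeds reach different
  points of the flat LOO basin, though in practice the downstream
  conclusions (significant set, top-3 ranking, best corner) are stable
  across them.
* MIV importance is computed at the design's own runs; it summarises local
  sensitivity around the screened region only.
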