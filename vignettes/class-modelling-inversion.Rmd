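---
title: "Probabilistic class-modelling by PLS and the algebra of its inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic class-modelling by PLS and the algebra of its inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plscm)
```

## The model

`plscm` treats binary classification as a regression problem with a coded
response: class A objects get −1, class B objects +1, both blocks are
autoscaled (columns centred, divided by their sample standard deviation —
the (n−1) convention throughout), and a PLS1 model with `a` latent
variables is fitted by NIPALS with deflation. Two conventions matter for
everything downstream:

* We store both the NIPALS weights **W** and the *applied* weights
  **R** = **W**(**P**ᵀ**W**)⁻¹. Scores of new objects are **x**ᵀ**R**, so
  **R**ᵀ**P** = **I** holds exactly, and it is this identity that makes the
  inversion algebra close: a boundary score mapped to input space through
  **P**ᵀ and projected back gives the same score, hence the same
  prediction. Every formula that is conventionally written with **W**
  (predictions, the input-space normal **QW**ᵀ, the W-null space) uses
  **R** here, which is the version of those formulas valid for deflated
  NIPALS factors.
* Thresholds, predictions and trajectories are reported in *coding units*
  (the scale where the classes sit near −1 and +1), converting to the
  internally scaled response only where the algebra needs it
  (y_scaled = (y_d − ȳ)/s_y). Raw variable units are used for all
  input-space output.

The model is probabilistic through the second stage: per-class
distributions fitted to the predicted responses. These, not the regression
itself, carry the sensitivity/specificity semantics of the class-model.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| number of latent variables | crossvalidated | smallest `a` whose R²cv is within `eps_cv = 0.01` of the maximum; a one-SE-style parsimony rule. `rule = "max"` gives the plain argmax for users who prefer it. |
| CV scheme | leave-one-out | venetian blinds (`k_splits`, one sample per blind, default 10) for larger n. |
| PLSbox confidence | 0.95 | the conventional level for T²/Q control limits; configurable per call, and feasibility can be re-evaluated at another confidence without refitting. |
| outlier rule | exceed *both* T² and Q limits | the conservative compound rule: a point extreme in only one statistic is retained. At most 10 refit iterations; autoscaling is recomputed after each removal. |
| normality acceptance | min p ≥ 0.10 | across Shapiro–Wilk, Anderson–Darling and a D'Agostino K² omnibus; 0.10 rather than 0.05 because here the *null* (normality) is the modelling convenience we only want to keep when nothing speaks against it. |
| distribution support | sample range ± 1% of the span | for the triangular and beta4 candidates; widened so observed extremes get nonzero density. `support = "sample"` uses the exact range. |
| balanced threshold tolerance | 1e−12 in y | bisection; gives \|sensitivity − specificity\| ≤ 1e−9 by construction. |
| boundary sample | 50 feasible points, `box_scale = 1` | null-space coefficients drawn uniformly inside the range of the *training projections* on each null direction, so samples land where the model is applicable; 50 points trace a boundary without clutter. |
| repair steps | `n_steps = 10`, auto step | the auto step spans twice the prediction deficit over the trajectory, so a rejected start crosses the boundary near the midpoint; steps are equally spaced in *scaled* units so they are comparable across variables of different magnitude, then reported in raw units. |

## Statistics and limits

T² of a score vector is Σ t_k²/var(t_k) with training score variances; the
limit is a(n² − 1)/(n(n − a)) · F₁₋α(a, n − a). The Q-residual is the
squared norm of the unreconstructed part of the scaled object; its limit is
Jackson–Mudholkar from the residual eigenvalues, falling back to
moment-matched g·χ²_h when fewer than two residual eigenvalues remain, and
identically zero when a = p (no residual subspace; Q ≡ 0 for every point,
and the PLSbox degenerates to the T² ellipse alone).

## The inversion and its degenerate cases

For a threshold y_d, the minimum-norm particular score solution
t_d = y_scaled·**Q**/‖**Q**‖² is used; "any particular solution" would do,
the minimum-norm one is canonical and reproducible. Null bases are
orthonormalized by SVD with a fixed sign convention (first nonzero entry of
each row positive) so that repeated runs and serialized models agree
exactly. Dimensions are audited: a − 1 (latent), p − a (W-null), p − 1
(input), and `input_null_basis()` errors rather than silently returning a
rank-deficient basis. If some y-loading is exactly zero the corresponding
latent variable is dropped with a warning — the boundary normal is
undefined along it. Domain bounds are inclusive, so an inversion solution
sitting exactly on a training extreme is still feasible.

`sample_boundary()` draws coefficients uniformly (not on a grid): a grid
commits to an orientation and resolution per null direction, while uniform
draws under a fixed seed are unbiased over the same box and trivially
reproducible. Draws continue in batches until the requested number of
feasible points is found or 100× that many have been spent; all draws are
returned with their feasibility flags (discarding infeasible points is the
caller's choice, e.g. via the CLI's `--drop-infeasible` behaviour of
filtering on the `feasible` column), because an audit trail of *where* the
boundary leaves the applicability region is itself informative.

## Distribution fitting choices

The triangular likelihood is non-smooth in the mode and unbounded if the
support touches the sample extremes, which is why the fit profiles the mode
over the order statistics while the bounds move on a log-spaced grid
anchored at the expanded sample range, with Nelder–Mead refinement of the
bounds only. Family selection among the non-normal candidates is by
maximized log-likelihood, ties broken toward the triangular (fewer
parameters). The beta4 support is fixed, not estimated: joint ML over
support and shapes is ill-posed (the likelihood diverges as the support
shrinks onto the sample when a shape drops below 1).

Fewer than 8 observations cannot support the battery; between 4 and 7 a
plain normal ML fit is returned with a warning, mirroring the situation of
a class too small to test, where a normal is adopted on inspection.

## What the synthetic generator does and does not emulate

`generate_two_class()` produces two isotropic Gaussian clouds in p
dimensions whose means differ by `delta` noise units along one direction —
the defaults (200 per class, p = 6, delta = 6, unit noise) give a
well-separated but overlapping pair, with population prediction means at
±(δ/2)²/(σ² + (δ/2)²) = ±0.9, the regression-attenuation closed form the
tests check recovery against. This emulates the geometry PLS-CM assumes: a
class difference concentrated in a low-dimensional subspace with
uninformative isotropic remainder. It does **not** emulate correlated
measurement blocks, per-class covariance differences, skewed prediction
clouds caused by bounded instrument responses, or class imbalance — so a
green test suite shows the algebra and the decision machinery are correct,
not that any particular real dataset will yield normal prediction
distributions or a high-sensitivity class-model. Test problem sizes (40–400
rows, p = 2–6, a = 1–4) were chosen as the smallest sizes at which the
statistical assertions are stable across seeds; the whole suite runs in
seconds.

## Known limitations

* Single response only: the threshold algebra and null-space dimensions
  (a − 1, p − 1) are specific to one coded response; multi-class or
  multi-response class-modelling needs a different inversion.
* The repair direction is the boundary normal — the shortest path in
  scaled units — with no notion of per-variable cost or manipulability;
  all variables are assumed adjustable in concert.
* Distribution families are fixed at normal/triangular/beta4; no empirical
  or kernel class-models.
* Crossvalidated R²cv on a binary response saturates well below 1 for
  overlapping classes; the parsimony rule therefore tends to pick very few
  latent variables, which is intended.
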