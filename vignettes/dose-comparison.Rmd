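---
title: "Comparing planar dose distributions with MDdiff and the gamma index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing planar dose distributions with MDdiff and the gamma index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddiff)
```

## The model

Patient-specific IMRT QA compares a measured planar dose distribution
(the *reference*, $D_r$) against the calculated one (the *evaluated*,
$D_e$), both regular 2D grids of absolute dose in cGy. Two tolerances
parameterize every comparison here: the dose-difference criterion
$\delta D^0$ (cGy, conventionally 3% of the prescribed dose) and the
distance-to-agreement criterion $DTA^0$ (mm, conventionally 3 mm).

The plain dose difference $\delta D(r) = D_e(r) - D_r(r)$ is intuitive
but misleading on penumbrae, where tiny alignment errors produce large
$\delta D$. The modified dose difference divides it by a factor that
grows with the local reference gradient expressed in tolerance units:

$$\beta_{DG}(r) = |\nabla D_r(r)|\,\frac{DTA^0}{\delta D^0},
\qquad
MDdiff(r) = \frac{\delta D(r)}{1 + \beta_{DG}(r)}.$$

The construction has three structural properties, all enforced as tests:
$|MDdiff| \le |\delta D|$ with equality exactly where the gradient
vanishes; the sign of $\delta D$ is preserved; and for a fixed
$\delta D$ the suppression is strictly monotone in the gradient. Two
limits anchor the interpretation: on flat regions
$MDdiff \to \delta D$, and on steep gradients $MDdiff \to 0$. For a
reference ramp of slope $g$ rigidly shifted by $s$ the interior value is
closed-form,

$$MDdiff = \frac{-g\,s\,\delta D^0}{\delta D^0 + g\,DTA^0},$$

which the tests verify to $10^{-6}$. A point fails QA when
$|MDdiff| \ge \tfrac12\,\delta D^0$; the factor $\tfrac12$ is an
empirical calibration constant aligning the rule with the gamma
criterion $\gamma \ge 1$, and is exposed as `threshold_factor` rather
than hard-wired. The literal one-sided rule
$MDdiff \ge \tfrac12\,\delta D^0$ would ignore under-dosed points, which
contradicts the metric's signed character; the default is therefore the
absolute-value rule, with `signed = TRUE` available for the one-sided
variant.

The gamma index is implemented as the comparator:
$$\gamma(r_r) = \min_{r_e}\sqrt{
  \frac{|r_e - r_r|^2}{DTA^{0\,2}} +
  \frac{(D_e(r_e) - D_r(r_r))^2}{\delta D^{0\,2}}},$$
with global (absolute-dose) normalization. `gamma_map()` and the
exhaustive `gamma_bruteforce()` minimize over the identical candidate
set and must agree to $10^{-9}$; the accelerated path only skips
candidates whose spatial term alone already exceeds the best bound, so
the agreement is exact, not approximate.

## Conventions and geometry

* **Axes.** x runs along matrix dimension 1 (rows), y along dimension 2;
  `values[i, j]` sits at the pixel *center*
  $(x_0 + (i-1)\,dx,\; y_0 + (j-1)\,dy)$ mm. One convention had to be
  fixed; this one is used consistently by both metrics and the I/O
  format.
* **Units.** All doses are absolute cGy. A percentage criterion is
  converted exactly once, at `dose_criteria()` construction
  (`"3%"` of 200 cGy → 6 cGy), never downstream.
* **Resampling.** MDdiff needs $D_e$ on the reference lattice;
  `resample_to_reference()` interpolates bilinearly (exact on constant
  and linear fields) and never extrapolates: reference points outside
  the evaluated extent are flagged invalid and excluded from all counts.
* **Gradient estimator.** $|\nabla D_r|$ uses second-order central
  differences (one-sided at edges), the standard unbiased choice on a
  regular grid; it is exact on linear fields, which is what makes the
  ramp closed form testable at $10^{-6}$.
* **Gamma search.** The evaluated grid is bilinearly refined by
  `subsample` (default 4) and searched within `search_radius` (default
  $\max(3\,DTA^0,\; DTA^0 + 2\,\max dx)$ — far enough that the spatial
  term alone exceeds 3 at the cut-off). Reference points whose full
  search disc is not covered by the evaluated extent still receive a
  $\gamma$ from the available candidates but are flagged invalid, so
  summaries are not biased by artificial edge failures; as a result the
  gamma denominator excludes an edge band that the MDdiff denominator
  keeps.
* **No low-dose cutoff** is applied by default: summary counts run over
  the full valid plane. ROI restriction and local normalization are out
  of scope.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `dose_diff` ($\delta D^0$) | cGy or % | — | clinical standard 3% of prescribed |
| `dta` ($DTA^0$) | mm | — | clinical standard 3 mm |
| `threshold_factor` | — | 0.5 | empirical MDdiff critical value, $\tfrac12\delta D^0$ |
| `signed` | — | `FALSE` | absolute-value failing rule (see above) |
| `subsample` | — | 4 | gamma's resolution sensitivity; convergence is property-tested |
| `search_radius` | mm | $\max(3DTA^0, DTA^0{+}2dx)$ | spatial term alone > 3 beyond it |

## What the synthetic generator emulates

No measured data ship with the package; every experiment runs on
synthetic planes. `imrt_like_field()` sums rectangular apertures
convolved with a Gaussian penumbra (products of error-function edge
profiles), giving exactly the three regimes a clinical QA plane
presents: flat plateaus ($\beta \approx 0$), penumbrae of tens of cGy/mm
($\beta \gg 1$, peak edge gradient $dose/(\sigma\sqrt{2\pi})$), and
low-dose background. `apply_perturbation()` imposes a known ground-truth
discrepancy: rigid shift (bilinear, edge-clamped), multiplicative dose
scale, and seeded Gaussian noise.

`synthetic_cohort()` fixes the study conditions for the cohort-level
analyses: nine cases on a shared 80×80-pixel, 1 mm plane (6400 points,
the size of a typical planar QA export) holding four apertures at 200,
150, 100 and 60 cGy with a 2.5 mm penumbra; prescribed dose 200 cGy with
6 cGy/3 mm criteria downstream. Case 1 is the identity; cases 2–9
combine a dose scale rising 4%→10%, a shift rising 1→4 mm, and 0.3 cGy
noise. The ladder starts at 4% because that is the smallest plateau
error that clearly fails both rules on a 200 cGy plateau
($\gamma = 8/6$, $|MDdiff| = 8 \ge 3$ cGy), so the failing region then
grows continuously along the penumbra dose continuum — which is what
makes both methods' failing counts strictly increasing and their
Spearman rank correlation exactly 1 on this cohort, the desk-scale
analogue of observing the "same tendency" between the methods across
clinical QA cases. What the generator does **not** emulate: detector
response and calibration drift, film grain or array sampling patterns,
TPS calculation artefacts, and real multi-leaf aperture shapes; passing
on these planes shows the metrics' algebra and concordance, not clinical
performance on any particular dosimeter.

## Numerical choices

* Boundary positions in bilinear sampling carry a $10^{-9}$ relative
  tolerance so grid-edge points are not dropped by floating-point
  jitter.
* Gamma's candidate disc membership uses one shared tolerance expression
  in both the accelerated and the brute-force path, so the two routes
  see identical candidate sets.
* The pruning bound is seeded from the candidate nearest the reference
  point; pruning discards only candidates whose spatial term already
  exceeds the bound, hence cannot change the minimum.
* Degenerate inputs: grids smaller than 2×2 refuse a gradient;
  zero-overlap geometries refuse resampling; an all-invalid map refuses
  summarization; an all-perfect cohort reports its rank correlation as
  not applicable rather than 0/0.
* Spearman ties use average ranks (the `stats::cor` convention).
* Noise requires an explicit seed; the same `perturbation_spec`
  reproduces the same plane bit for bit.

## Problem sizes

The test suite exercises grids from 8×8 to 40×40 for oracle-equivalence
sweeps (100 randomized pairs), 80×80 for the cohort analyses, and 100
randomized pairs for the shrinkage/sign properties — sizes at which the
brute-force gamma oracle remains exhaustive while the whole suite stays
interactive. The acceptance script mirrors these sizes.

## Known limitations

* 2D only. The types would extend to a third axis, but no 3D search or
  gradient is implemented.
* Global normalization only; no local-dose gamma, no ROI restriction.
* Gamma values depend on interpolation depth and search radius, which
  published clinical analyses rarely state; numerical agreement with any
  particular clinical software's gamma output is therefore not a goal —
  the in-package brute-force oracle is the correctness anchor.
* The $\tfrac12\,\delta D^0$ critical value is an empirical constant;
  its clinical calibration cannot be reproduced from synthetic planes,
  only its consequences tested.
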