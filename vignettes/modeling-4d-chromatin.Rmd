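---
title: "Modeling 4D chromatin from time-series Hi-C: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 4D chromatin from time-series Hi-C: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A time-series Hi-C experiment assays the same chromosome at a handful of
time points along a biological process (cell reprogramming, differentiation)
and yields one symmetric contact matrix per time point. Each matrix is a
population-averaged snapshot; nothing in the data directly says how the
chromosome moved between snapshots. `hic4d` turns such a series into a
single smooth trajectory of 3D conformations on a discrete time grid — a 4D
consensus model — and uses that model to reconstruct contact maps at the
observed times and to *interpolate* them at times where no experiment was
done.

# The model

## From contacts to restraints

Contact frequency and spatial distance are inversely related; following
common 3D-modeling practice we use a power law. With exponent magnitude
$\gamma$ (default 0.6), a contact of frequency $\mathrm{IF}_{ij}$ becomes a
target distance

$$D_{ij} = \mathrm{IF}_{ij}^{-\gamma},$$

and extraction of synthetic maps from a structure applies the exact inverse
$\mathrm{IF}_{ij} = d_{ij}^{-1/\gamma}$, so that building restraints and
extracting maps are mutually inverse operations. Pairs with zero contact
carry no restraint at that time (absent data should not pull the model
anywhere), the diagonal is never restrained, and bins empty at *every* time
point are excluded throughout. All target distances of a series are
rescaled by one global factor so the largest is 1; the factor is recorded
on the restraint set and the fitted structure. This puts the targets on the
same scale as the uniform-$(0,1)$ initialization. Since the raw counts'
absolute scale is experiment-dependent and not recoverable from a
structure, downstream comparisons use rank (Spearman) or Pearson
correlations, which do not care about it.

## The time grid

The model tracks coordinates at $g$ equally spaced grid times spanning the
observed interval (the *granularity*). Each observed time is snapped to its
nearest grid point; a displacement above 25% of the grid spacing is an
error rather than a silent shift, because moving an observed time distorts
the interpolation weights below. For the 6-day toy data the default is one
grid point per day ($g = 6$); for a 10-day series sampled every two days a
granularity of 21 puts every observed day exactly on the grid.

## Likelihood

Restraint residuals at an observed time $\tau$ are modeled as i.i.d.
Gaussian with unknown scale $\sigma_\tau$. Profiling $\sigma_\tau$ out
(its MLE is the mean squared residual) leaves, per observed time, the
negative log-likelihood

$$L_\tau \;=\; \frac{n_\tau}{2}\,
  \log\!\Big(\frac{\sum_i (H_{i\tau} - D_{i\tau})^2}{n_\tau}
  + \sigma_0^2\Big),$$

where $H_{i\tau}$ are the target distances, $D_{i\tau}$ the model's
Euclidean distances at that frame, $n_\tau$ the restraint count, and
$\sigma_0$ a small variance floor discussed below. A grid time $t$ with no
data of its own borrows from its two flanking observed times $a_1 < t <
a_2$ through the convex weights

$$w_1 = \frac{t - a_2}{a_1 - a_2}, \qquad w_2 = 1 - w_1,$$

its term being $w_1 L_{a_1}(t) + w_2 L_{a_2}(t)$ — each unobserved frame is
pulled toward both neighboring restraint sets in proportion to temporal
proximity. This is what makes interpolation work: the frame at a held-out
time is constrained by its neighbors' data while remaining free to satisfy
them in the geometrically most economical way.

The user-facing diagnostic `data_loss()` reports the normalized form
$\log(\mathrm{SSE}_t/n_t)$ by default (its argmin is identical); the fit
minimizes the weighted form above, which is the exact profiled likelihood
and — because its gradient scales with $n_\tau$ — is also the form for
which the default learning rate actually moves the structure within the
default epoch budget.

## Smoothness

Satisfying distance restraints fixes geometry only up to a rigid motion per
frame, so consecutive frames of a purely restraint-driven fit could rotate
arbitrarily against each other. A movement penalty couples them:
`smoothness_penalty()` is the raw sum of squared per-bin displacements
between consecutive frames, and the fit adds

$$\eta \cdot \frac{D_\mathrm{moves}}{(g-1)\,n}$$

to the objective — the *mean* squared displacement per bin and transition,
so that the default weight $\eta = 1000$ has the same meaning for an 11-bin
toy chromosome and a 4000-bin real one. (With the raw sum, the penalty's
relative strength would grow linearly in $g \cdot n$ and the same $\eta$
would crush all motion on small systems while doing nothing on large
ones.)

## Optimization

Full-batch fixed-step gradient descent: all coordinates of all frames are
updated simultaneously with step $\lambda = 10^{-4}$ for 400 epochs. All
frames start from the *same* uniform-$(0,1)$ draw, so the movement penalty
starts at exactly zero and motion only appears where the data demand it.
Three independent restarts (seeds derived from the configured seed) are
fitted and the lowest final objective kept: distance-geometry objectives
are non-convex and a single random start occasionally tangles into a
mirror-image knot; in our toy experiments roughly one start in ten did,
and three restarts made every seed we tried recover cleanly. Everything is
deterministic given the seed.

Two numerical guards matter:

* **Variance floor** (`sigma_floor`, default 0.05 on the unit-max distance
  scale). On noiseless synthetic data a perfect fit exists, the profiled
  likelihood is unbounded as residuals shrink, and its gradient grows like
  $1/\mathrm{SSE}$ — a fixed step then oscillates around the degenerate
  optimum instead of settling, and the loss trace saw-tooths. The floor
  bounds the objective, caps the gradient prefactor at $1/\sigma_0^2$, and
  makes the descent monotone to numerical precision. Its value is the
  distance below which residuals are treated as "as good as perfect":
  5% of the largest restrained distance.
* **Distance clamp**: model distances are clamped at $10^{-12}$ when they
  enter gradients, so coincident random initial points cannot produce a
  division by zero.

Degenerate inputs are refused rather than repaired: all-zero maps cannot
produce restraints, fewer than two retained time points cannot span a
grid, and a non-finite loss aborts with the epoch at which it occurred.

# Parameters at a glance

| parameter | default | units / scale | role |
|---|---|---|---|
| `gamma` | 0.6 | dimensionless | distance–frequency exponent magnitude |
| `granularity` | one per observed time | grid points | temporal resolution of the model |
| `learning_rate` | 1e-4 | step size | gradient-descent step |
| `smoothness_weight` | 1000 | per mean squared displacement | inter-frame coupling |
| `epochs` | 400 | iterations | descent length |
| `sigma_floor` | 0.05 | unit-max distance scale | likelihood floor |
| `restarts` | 3 | count | local-optimum guard |
| DI `window_bp` | 2 Mb | base pairs | directionality-index window |
| TAD overlap `tol_bins` | 3 bins | bins (150 kb at 50 kb) | border matching tolerance |

# Downstream features

**A/B compartments.** The observed/expected matrix divides each entry by
the mean frequency at its separation, removing the distance decay; the
Pearson correlation matrix of its rows is decomposed by PCA and each bin is
assigned a compartment by the sign of PC1. PCA signs are arbitrary, so
profiles are oriented to correlate positively with the per-bin total O/E
row sum; comparisons across profiles should additionally consider the
sign-invariant $|r|$ when orientation is in doubt. Compartment
*trajectories* embed the per-time sign vectors (A = +1, B = −1, masked =
0) into their first two principal components.

**TADs.** The directionality index contrasts each bin's upstream and
downstream contact sums within a 2 Mb window (truncated at chromosome
ends, keeping the track full length); with $E = (A+B)/2$,
$\mathrm{DI} = \mathrm{sign}(B-A)\big((A-E)^2/E + (B-E)^2/E\big)$, zero
when $A = B$ (the only symmetric choice where the sign is 0/0). A 3-state
Gaussian hidden Markov model (upstream bias / none / downstream bias) is
fitted to the DI track by EM — deterministic, data-driven initialization:
means at $(-s, 0, s)$ with $s$ the DI standard deviation, shared variance,
uniform transitions — and decoded by Viterbi; a border is placed wherever
the decoded path enters a downstream-biased run, the convention that
domain starts are downstream-biased. The HMM is implemented in the package
(forward–backward with scaling, shared-variance M-step, floor on the
variance for two-valued degenerate tracks).

**Structure comparison.** Procrustes disparity $M^2$ centers both point
sets, scales each to unit Frobenius norm, applies the optimal rotation
(reflections allowed — chirality is unidentifiable from distances alone)
and optimal scaling, and reports the residual sum of squares,
$M^2 = 1 - (\sum_k \sigma_k)^2$ with $\sigma_k$ the singular values of the
cross-covariance. 4D structures are compared frame-by-frame at shared grid
times by distance-vector correlations and $M^2$, then averaged.

# The synthetic generator

`make_toy_trajectory()` builds an 11-bin, 50 kb toy chromosome evolving
over days 0–5, as a freely-jointed chain of exactly unit bonds defined by
per-joint turning angles (so the inextensible-chain invariant holds to
machine precision). Both variants start as a closed loop (a regular
11-gon; ends one bond apart) and end as a straight line:

* **unravel** — pulled from both ends: the arms' background curvature
  decays monotonically (32.7° → 0 per joint) while the apex angle at bin 5
  tightens into a hairpin (32.7° → 110° → 0), keeping bins 4 and 6 within
  1.5 bond lengths around day 3 before the final release;
* **swing** — the loop swings open as one arc: every joint relaxes
  uniformly, and bins 4 and 6 separate from day 1 onward.

The day-3 proximity of bins 4 and 6 in exactly one variant is the
discriminating geometric signature used by the variant-discrimination
tests; 1.5 bond lengths is the operational contact threshold.

`simulate_hic()` applies $\mathrm{IF} = d^{-1/\gamma}$ per frame
(noiseless, the default) or resamples each entry as Poisson with a
coverage scale. What the generator does *not* emulate: excluded-volume and
persistence-length polymer physics, structural heterogeneity across the
cell population (real bulk Hi-C averages millions of nuclei; the model is
a consensus structure by construction), distance-dependent noise, and
unmappable-region masking. Tests passing on this generator therefore
demonstrate the correctness and self-consistency of the pipeline — that
the optimizer recovers structures whose maps match their inputs, and that
interpolation genuinely infers withheld frames — not that real
chromosomes satisfy the model's Gaussian and consensus assumptions.

# Problem sizes

The packaged experiments run at toy scale: 11 bins, 6 time points,
grid granularities 6–11, 400 epochs, 3 restarts — a full fit takes about a
second and the complete recovery-plus-holdout battery under a minute on one
CPU. The fitting core is $O(g \cdot n_\mathrm{pairs})$ per epoch with dense
restraints ($n_\mathrm{pairs} = n(n-1)/2$), so whole-chromosome fits at
50 kb resolution (thousands of bins) are possible but slow in pure R;
they were not run here.

# Known limitations

* The consensus-structure assumption: one trajectory per population. No
  ensemble modeling.
* Interpolation is only defined strictly inside the observed interval;
  grid endpoints are always observed, so there is no extrapolation.
* The power-law exponent is treated as known (default 0.6); no
  per-dataset calibration against imaging data is attempted.
* Raw and normalized (ICE/KR) matrices are accepted alike; no balancing
  is performed in-package.
* The HMM TAD caller implements the directionality-index convention
  without post-processing (no minimum domain length, no median filtering
  of states).
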