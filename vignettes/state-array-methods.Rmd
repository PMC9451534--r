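---
title: "Inferring distributions of diffusing states from short SPT trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring distributions of diffusing states from short SPT trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statearray)
```

## The problem

Single-particle tracking with photoactivation (sptPALM) in mammalian
cells produces very large collections of very short trajectories.  Two
features of the measurement dominate the analysis:

* **Localization error.** Each measured position carries additive,
  approximately Gaussian error with per-axis variance
  $\sigma_{loc}^2$.  Because the same noisy position terminates one
  jump and starts the next, sequential jumps are anticorrelated with
  lag-1 covariance exactly $-\sigma_{loc}^2$; observed displacements
  are *not* a Markov process unless $\sigma_{loc}^2 = 0$.
* **Defocalization.** High-NA objectives observe a focal slab well
  under a micron deep.  Emitters are seen only while their axial
  position is inside the slab, so fast particles fragment into many
  short transits while slow particles yield a few long ones.  Any
  estimator that weights trajectories (or even jumps) uniformly is
  biased toward slow states.

The package infers the *distribution* of diffusing states — how much
of the tracked population moves at which diffusion coefficient —
jointly handling both effects, without fixing the number of states in
advance.

## Motion models

**RBME** (regular Brownian motion with localization error).  For a
trajectory with $L$ jumps at frame interval $\Delta t$, the per-axis
jump vector is mean-zero Gaussian with tridiagonal covariance

$$\Gamma_{ij} = 2(D\Delta t + \sigma_{loc}^2)\,I_{i=j}
  - \sigma_{loc}^2\,I_{|i-j|=1}.$$

`rbme_log_likelihood()` evaluates the exact density through the
closed-form eigendecomposition of the tridiagonal matrix (the discrete
sine basis with eigenvalues $2D\Delta t + \sigma_{loc}^2\,
(2 - 2\cos\tfrac{j\pi}{L+1})$), which is exact, $O(L^2)$, and turns
the evaluation of the whole trajectory-by-state likelihood matrix into
a few dense matrix products per distinct trajectory length.

**FBME** (fractional Brownian motion with localization error) adds a
Hurst parameter $H$; increments carry the fBm covariance plus the same
localization-error band.  We parameterize by the *modified* scaling
coefficient $\bar S = S\,\Delta t^{2H-1}$ so the one-frame jump
variance is $2\bar S\Delta t$ for every $H$, and recover $\bar S = D$
exactly at $H = 1/2$.  $\bar S$ is acquisition-specific and must be
converted back to $S$ before comparing across frame intervals.

## State arrays

Rather than selecting a number of states, the state array fixes a
dense grid of candidate states — by default 101 diffusion coefficients
log-spaced on $[10^{-2}, 10^2]$ µm²/s crossed with 36 localization
errors linearly spaced on $[0, 0.06]$ µm — and infers a sparse
occupation vector over it by variational Bayes.  With a
$\mathrm{Dirichlet}(\alpha/K, \dots, \alpha/K)$ prior on the
occupations $\tau$ and trajectory-to-state assignments $Z$, the
mean-field updates are

$$n_k = \frac{\alpha}{K} + \sum_i L_i r_{ik}, \qquad
  r_{ik} = \frac{A_{ik}\,e^{\psi(n_k)}}{\sum_j A_{ij}\,e^{\psi(n_j)}},$$

initialized from the row-normalized likelihoods.  Trajectories enter
the pseudocounts in proportion to their jump counts $L_i$: jumps, not
trajectories, are the unit of evidence, which keeps heavily fragmented
fast states from being discounted further.  The *naive estimate*
(`naive_occupations()`) is the same weighted average evaluated at the
initialization — a cheap per-nucleus or per-block summary.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | total Dirichlet concentration (split as $\alpha/K$) |
| `max_iter` | 250 | EM iterations |
| `tol` | 1e-6 | stop when $\max_k |\Delta E[\tau_k]|$ falls below |
| grid | 101 × 36 | D × $\sigma_{loc}$ resolution |

Two of these deserve justification.

**Prior concentration.** The grid mixture approximates a Dirichlet
process whose concentration stays $O(1)$ as the grid is refined, so
the package defaults to a *total* $\alpha = 1$ rather than one
pseudocount per vertex.  One pseudocount per vertex ($\alpha = K
\approx 3600$) would amount to several percent of the evidence of a
typical 12,800-trajectory experiment spread uniformly over the grid —
and the defocalization correction then inflates the artificial fast
tail by up to $1/\eta \approx 5\times$.  A sensitivity test in the
suite checks that integrated occupations move by well under two
percentage points across weak priors ($\alpha \in [0.5, 5]$).

**Stopping rule.** The strict per-vertex criterion keeps decreasing
roughly as a power law because posterior mass slowly exchanges between
near-duplicate adjacent vertices; meanwhile every integrated summary
(range occupations, immobile fraction, mean free $D$) is stable to
better than 0.1 percentage points after roughly a hundred iterations.
The default budget of 250 iterations with `tol = 1e-6` reflects that:
hitting the iteration cap is reported as a warning with the last
occupation change, not as a failure.  The exact fixed-point property
is verified in the test suite on small grids, where the EM converges
to machine-level residuals.

### Postprocessing

Reported profiles are always (1) marginalized over the localization
error axis and (2) corrected for defocalization.  The order is
immaterial because the correction depends only on $D$; the package
fixes marginalize-then-correct for reproducibility.

## Defocalization correction

For a state with diffusion coefficient $D$, the probability that a
particle uniformly distributed in a slab of depth $\Delta z$ is still
inside it one frame later is computed by propagating the axial density
with one convolution–transmission step,
$\mathrm{Diffuse}[f] = T(z)\,[f * g(z, \Delta t)]$, and integrating.
Occupations are corrected as
$\tau_k' \propto \tau_k / \eta_k$.  Numerically the axial grid uses a
spacing of about $\min(\Delta z/50, \sigma_z/8)$ — snapped so that the
slab spans an odd whole number of cells, making the slab transmission
exactly idempotent — and an extent of $\Delta z/2 + 6\sigma_z$;
`diffuse_step()` refuses grids coarser than $\sigma_z/4$.  $\eta$
depends on its inputs only through $\sqrt{2D\Delta t}/\Delta z$.  The
one-step $\eta$ is what the correction uses; multi-frame propagation is
available for diagnostics.  FBME profiles are corrected through the
effective one-frame jump variance ($D_{\mathrm{eff}} = \bar S$), exact
for the first increment and an approximation beyond it.

## The 1D Dirichlet-process sampler

The DPMM route drops the off-diagonal covariance terms, collapsing
each trajectory to $(S_i, L_i)$ with likelihood
$\log p \propto -S_i e^{-\phi} - L_i \phi$ in the single parameter
$\phi = \log[4(D\Delta t + \sigma_{loc}^2)]$.  A Chinese-restaurant
Gibbs sweep with $m_0 = 20$ uniform auxiliary candidates per new
state, jump-count weighting of existing states, and truncated-Gaussian
Metropolis–Hastings nudges ($\nu = 0.1$) samples the posterior;
defaults are $\alpha = 5$, 2000 iterations with 500 burn-in, all
configurable and all driven by a single seed.  We use the standard
Metropolis rule (accept when $u < r$, with the truncation-volume
correction $\Phi((\phi_{max}-\phi)/\nu) - \Phi((\phi_{min}-\phi)/\nu)$
in $r$).

Because $\phi$ confounds $D$ and $\sigma_{loc}^2$, the sampler needs an
external error estimate; `estimate_loc_error()` supplies the mean
negative lag-1 covariance of sequential jumps, pooled over both axes.
This is the method's structural weakness: when localization error
differs between states, a single pooled $\sigma_{loc}^2$ mis-maps
$\phi$ to $D$ state by state, and the state array — which keeps
$\sigma_{loc}$ as an explicit grid axis — degrades far more
gracefully.  The acceptance suite quantifies exactly this contrast.

## The trajectory simulator

`simulate_dataset()` generates the validation conditions: particles
photoactivate uniformly inside a reflecting sphere (radius 5 µm),
diffuse by Euler–Maruyama (10 substeps per 7.48 ms frame, so boundary
reflections are resolved; 100 substeps when two-state switching is
simulated), photobleach at 14 Hz, and are recorded only on frames with
$|z| \le \Delta z/2 = 0.35$ µm.  Re-entries into the slab become
separate trajectories; per-state iid Gaussian localization error is
added to recorded positions; state membership is multinomial, and the
realized fractions (returned as ground truth) fluctuate around the
nominal ones exactly as in a real experiment.

Mean transit length at these settings is 3–5 frames when every
observed transit is counted, including single-detection ones, as raw
tracking output would; the inference dataset excludes zero-jump
transits (they carry no displacement information) and therefore
averages somewhat longer.  Both numbers are exposed.

What the simulator does *not* emulate: camera noise, motion blur,
defocus-dependent localization error, or tracking errors — observation
is geometrically ideal and linking is unambiguous by construction.
Passing benchmarks therefore demonstrate correctness of the inference
given trajectories, not robustness to detection and linking artifacts
of real movies.

The class-3 benchmark preset assigns per-state localization errors
$\sigma_{loc} = (0.05, 0.06, 0.02)$ µm to states
$D = (0.02, 0.5, 5.0)$ µm²/s: values spread across the grid's
$[0, 0.06]$ µm range, with the middle state near
$D\Delta t \approx \sigma_{loc}^2$ — the regime where a pooled error
estimate is most misleading.

## Problem sizes used in validation

The accuracy benchmarks in the test suite and the acceptance script
use 12,800 trajectories per replicate (5 seeds for the three-state
occupation benchmark, 3 replicates for the class-3 CDF benchmark), the
scale at which the inference is designed to operate; property-style
checks (likelihood oracles, propagator vs Monte Carlo, sampler
invariants) use 10^3–10^5-jump synthetic sets built directly from the
model definitions.

## Degenerate inputs and edge cases

* Grid vertices with $D = 0$ and $\sigma_{loc} = 0$ have a singular
  covariance; they receive zero likelihood and are reported, never
  fatal (the default grid starts at $D = 10^{-2}$).
* Duplicate grid vertices are allowed; posterior mass splits among
  them.
* Trajectories with frame gaps are split at the gaps on import
  (the covariance model assumes strictly consecutive frames);
  single-detection trajectories are excluded but counted.
* DPMM samples whose implied $D$ falls below the histogram grid
  (including $e^{\phi}/4 < \sigma_{loc}^2$) are clamped to the
  smallest vertex and counted.

## Known limitations

* Neither method models state *transitions*; switching faster than
  roughly the frame interval appears as a single intermediate state
  (demonstrated in the acceptance suite's rate sweep).
* The defocalization correction assumes the slab transmission is
  binary and the in-slab distribution uniform; both are excellent
  approximations for a thin slab bisecting a much larger nucleus.
* FBME inference is provided at full fidelity but with a generic
  per-vertex Cholesky path, so large FBME grids are substantially
  slower than RBME.
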