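# statearray

Bayesian recovery of diffusing-state distributions from large
collections of short single-particle-tracking (sptPALM) trajectories.

Live-cell sptPALM yields tens of thousands of trajectories that are
each only a handful of frames long: emitters bleach within ~100 ms and
drift out of a sub-micron focal slab even faster.  Two measurement
effects dominate any attempt to infer a molecule's dynamic profile from
such data — localization error (which anticorrelates sequential jumps,
with lag-1 covariance exactly \(-\sigma_{loc}^2\)) and defocalization
(fast particles fragment into many short transits, biasing naive
estimators toward slow states).  `statearray` implements two
complementary inference routes that handle both:

* **State arrays** — a finite mixture over a dense fixed grid of
  candidate states (101 diffusion coefficients log-spaced on
  \([10^{-2}, 10^{2}]\) µm²/s × 36 localization errors on
  \([0, 0.06]\) µm).  Occupations carry a weak symmetric Dirichlet
  prior and are inferred by variational EM,

  \[ n_k = \tfrac{\alpha}{K} + \sum_i L_i r_{ik}, \qquad
     r_{ik} = \frac{A_{ik} e^{\psi(n_k)}}{\sum_j A_{ij} e^{\psi(n_j)}}, \]

  where \(A_{ik}\) is the exact likelihood of trajectory \(i\) under
  grid state \(k\) (regular or fractional Brownian motion with
  localization error) and \(L_i\) its jump count.  Sparsity emerges
  automatically; no state count is chosen.
* **A Dirichlet-process mixture** sampled by a Chinese-restaurant
  Gibbs sweep with auxiliary candidates and Metropolis–Hastings
  nudges, on the 1D parameter
  \(\phi = \log[4(D\Delta t + \sigma_{loc}^2)]\) — fast, but dependent
  on an external localization-error estimate (the mean negative lag-1
  jump covariance), which is its documented weakness when the error
  varies between states.

Both posteriors are marginalized over localization error and corrected
for defocalization: each state's occupation is divided by its
one-frame in-focus probability \(\eta(D)\), computed by propagating
the axial density with a convolution–transmission step through the
focal slab.

A full stroboscopic trajectory simulator (reflecting sphere, focal
slab, photobleaching, multinomial state assignment, sub-frame
two-state switching, per-state localization error) provides ground
truth for every benchmark.

## Worked example

Simulate the three-state benchmark (0.02 µm²/s at 20%, 0.5 at 30%,
5.0 at 50% — immobile / slow / fast, as for a chromatin-binding
factor), then recover the occupations:

```r
library(statearray)

model <- sim_preset("three_state")
geom  <- sim_geometry(n_trajectories = 12800)   # 5 um sphere, 0.7 um slab,
                                                # 7.48 ms frames, 14 Hz bleach
sim <- simulate_dataset(model, geom, seed = 1)
sim$dataset
#> Trajectory dataset
#>   trajectories: 12800 (singletons excluded: 7169)
#>   total jumps:  53034
#>   mean length:  5.14 frames
#>   frame interval 0.00748 s, focal depth 0.7 um

res <- sa_analyze(sim$dataset)   # likelihoods -> EM -> marginalize -> correct
round(c(immobile = occupation_in_range(res$profile, 0,    0.08),
        slow     = occupation_in_range(res$profile, 0.08, 1.5),
        fast     = occupation_in_range(res$profile, 1.5,  40)), 3)
#> immobile     slow     fast
#>    0.209    0.315    0.476
round(sim$truth$realized_occupations, 3)   # multinomial ground truth
#> [1] 0.200 0.301 0.500

immobile_fraction(res$profile)        # corrected occupation below 0.05 um^2/s
#> [1] 0.2092592
mean_free_diffusion(res$profile)      # posterior mean D of the mobile mass
#> [1] 3.133152
```

Every estimate lands within ~2.5 percentage points of the realized
truth; without `correct_occupations()` the fast state would be
under-counted by the defocalization bias.  The same pipeline runs from
the shell on trajectory CSVs:

```sh
Rscript inst/cli/statearray-cli.R sa --input tracks.csv --out results/ \
    --frame-interval 0.00748 --pixel-size 0.16 --focal-depth 0.7
```

writing the naive profile, the marginal and corrected posterior
profiles, and a JSON report (trajectory counts, immobile fraction,
mean free diffusion coefficient).  `simulate` and `dpmm` subcommands
wrap `run_simulate()` and `run_dpmm()` the same way.

## Layout

* `R/`, `src/` — data model and I/O, likelihoods, variational state
  array, DPMM sampler (Rcpp), defocalization propagator, simulator,
  spatial/temporal posterior aggregation, pipeline wrappers.
* `vignettes/state-array-methods.Rmd` — model assumptions, parameter
  choices, numerical decisions, limitations.
* `tests/testthat/` — unit, property and acceptance suites; all
  fixtures are generated in code.
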