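---
title: "Vibrational spectral diffusion of an HDO probe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrational spectral diffusion of an HDO probe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdospec)
```

# The measurement model

A dilute HDO molecule in liquid water carries three localized vibrational
reporters — the HOD bend, the OD stretch and the OH stretch — whose
instantaneous harmonic frequencies respond to the probe's hydrogen-bonding
environment. Sampling those frequencies over an equilibrium trajectory
yields, per mode:

* the **central frequency** ω₀, the intensity-weighted mean of the sampled
  frequencies (weights are the IR intensities of each snapshot's mode);
* the **fluctuation amplitude** σ, the intensity-weighted population
  standard deviation;
* the **spectral-diffusion time** τ_c, extracted from the
  frequency–fluctuation correlation function (FFCF)
  C(t) = ⟨δω(t)δω(0)⟩ fitted with a biexponential
  A₁e^(−t/τ₁) + A₂e^(−t/τ_c) + y₀ and reported as the longest time
  constant.

In the Kubo stochastic-lineshape picture the instantaneous frequency is a
Gaussian stochastic process; water's FFCF has two well-separated
components, a femtosecond hydrogen-bond making/breaking time and a
picosecond network-reorganization time. That two-timescale structure is
both the model fitted to data and the generative model the package's
simulator implements.

# Cluster extraction

Snapshots are periodic orthorhombic water boxes. Water molecules are
perceived by assigning every hydrogen to its nearest oxygen under the
minimum-image convention (bonding cutoff 1.25 Å by default, wide enough
for flexible models); frames with unassignable atoms or non-water species
are rejected loudly rather than silently filtered, because a silent drop
would bias the sampled ensemble.

Shell geometry comes from the O–O radial distribution function: the first
local minimum of the smoothed g(r) (centered moving average, 5 bins,
bin width 0.05 Å by default) defines the first-shell cutoff r₁, the third
minimum the cluster radius r₃ covering three solvation shells. O–O is used
as the pair convention throughout — both for the cutoffs and for shell
membership — as is standard for water-structure analysis; the coordination
criterion is distance-only (no angular hydrogen-bond test). Membership is
strict (`<`) at every cutoff; a neighbor exactly at the cutoff is
excluded, and the rule is documented at the API.

Two carving modes exist because a fixed radius produces frame-to-frame
variable cluster sizes while frequency engines prefer homogeneous inputs:
`radius` implements the three-shell criterion literally, `nearest_n`
(default, n = 29 environment waters, i.e. a 30-molecule cluster) gives
reproducible engine decks. Coordination counts always use r₁ regardless of
mode. Before export every molecule is made whole around its own oxygen and
then shifted by the lattice vector minimizing the O–O distance to the
probe, so no cluster is split across a boundary.

# The frequency engine contract

The engine boundary is deliberately thin: the package emits a deck (probe
atoms first; every environment atom in a 1-based `$fix`-style frozen list;
a single isotope override of 2.014 amu on the designated deuterium) and
expects back a table of frequency–intensity pairs plus a convergence flag.
Whether the engine computes a partial or full Hessian is its own concern.
Non-converged snapshots are retained with their flag and excluded from all
observables, with the exclusion count reported.

Mode identification is by disjoint frequency windows — bend [1100, 1800),
OD [1800, 2900), OH [2900, 4200) cm⁻¹ — chosen to bracket the published
central frequencies of all common water models by a wide margin.
Low-frequency pseudo-translations/rotations of the constrained probe fall
outside every window and are discarded. If a window contains several
candidates the most intense is taken and the snapshot flagged; an empty
window is an error naming the snapshot, because a missing mode indicates
an engine failure rather than a statistical fluctuation.

The built-in mock engine maps cluster geometry to frequencies
deterministically:

ω_mode = base_mode − slope_mode·n₁ − Σⱼ c_mode·exp(−rⱼ/λ)

over first-shell neighbors j, with bases (1355, 2600, 3530) cm⁻¹, slopes
(1, 20, 25) cm⁻¹ per neighbor, c = (2, 30, 35) cm⁻¹ and λ = 0.5 Å; the
steep exponential mimics the distance sensitivity of hydrogen-bond
frequency maps. Intensities are a positive affine function of n₁. The map
is not a physical model — it exists so that end-to-end tests have known
qualitative structure: stretches redshift monotonically with coordination,
and low-coordination subdistributions inherit a low-frequency tail
(negative skewness) from the convex distance term.

# Observables

All moments are intensity-weighted population forms: mean Σwx/Σw, variance
Σw(x−ω₀)²/Σw without Bessel correction, and the asymmetry coefficient as
the weighted Fisher third standardized moment (negative = low-frequency
tail). With uniform weights they reduce exactly to the unweighted
formulas, which the tests assert.

Uncertainties are 95% half-widths, 1.96·SE. For ω₀, SE = σ/√N over the
pooled snapshots. For σ the pooled-SE formula would be dishonest — the
samples are strongly serially correlated within a replica — so its
half-width comes from the dispersion of per-replica σ estimates,
1.96·sd(σ_r)/√R; with a single replica it is reported as `NA` rather than
fabricated.

Frequency distributions are normalized intensity-weighted histograms
(default bin widths 2 cm⁻¹ for the bend, 5 cm⁻¹ for the stretches — about
a tenth of the respective σ values). Coordination-resolved
subdistributions share the bin grid of the pooled distribution and report
intensity-weighted population fractions, so that
Σ_c fraction_c·density_c reconstructs the total density bin-by-bin exactly
when every observed count is requested. Gaussian component fits (k = 1–3)
use Levenberg–Marquardt with deterministic initialization from histogram
quantiles; a fit with R² < 0.9 or a failed optimizer is flagged, never
silently reported.

# FFCF and τ_c

Fluctuations are defined per replica against that replica's unweighted
mean (intensity weighting is not applied to the FFCF). The estimator
divides each lag by its own pair count (unbiased denominator), so C(0)
equals the pooled population variance of δω to machine precision — an
identity the acceptance checks exercise. Replica correlation series are
averaged pointwise with equal weights and fitted once (fit of the average,
not average of fits): at ~1,000 points per replica the individual
biexponential fits are ill-conditioned, while the averaged curve is
stable.

The fit excludes lag 0 by default (the motionally narrowed ultrafast
component contaminates it; toggleable), bounds all amplitudes and times
positive, and multi-starts from the τ-pair grid {0.05, 0.1, 0.5} ×
{0.5, 1, 2} ps with amplitudes split evenly from C(dt), keeping the
lowest-residual solution. Components are ordered so τ_c ≥ τ₁; when one
amplitude falls below 2% of C(dt) the fit is flagged effectively
monoexponential rather than reporting a meaningless second time. τ_c's
uncertainty is 1.96 times its standard error from the fit covariance. The
fit is unnormalized (C(0) is not divided out) — the free offset y₀ absorbs
any unresolved slow plateau. No constraint ties A₁ + A₂ to σ²; the Kubo
relation between them is left as a diagnostic the user can inspect.

# Synthetic data: what it does and does not emulate

The simulators define the package's study conditions:

* `simulate_ou` uses the exact discretization
  δω_{k+1} = δω_k·e^(−Δt/τ) + σ√(1−e^(−2Δt/τ))·ξ_k with a stationary
  start, so the analytic autocorrelation σ²e^(−t/τ) holds at any time step
  and no burn-in is needed.
* `simulate_two_timescale` sums two independent OU components; defaults
  (σ₁ = 60 cm⁻¹, τ₁ = 0.1 ps, σ₂ = 40 cm⁻¹, τ₂ = 1.0 ps, 50 fs sampling,
  12 replicas × 1,000 points) sit in the physical regimes of water
  spectral diffusion — the fast component inside the 50–400 fs
  hydrogen-bond window, the slow one inside the 0.7–1.2 ps network window —
  at the sampling protocol the observables are designed for (12,000
  snapshots).
* `generate_water_box` packs rigid waters (O–H 0.9572 Å, 104.52°) by
  random sequential insertion with a minimum O–O distance of 2.6 Å.
  End-to-end checks use 44 waters in an 11.3 Å box (0.0305 Å⁻³, about 9%
  below bulk density): random insertion cannot reach bulk density reliably
  for every seed — it sits near the sequential-insertion jamming limit —
  and the slightly looser box packs deterministically while keeping
  first-shell counts 3–5 well populated.

What passing tests therefore show: the estimators recover known means,
amplitudes and time constants from Gaussian two-timescale dynamics at
production-scale sampling; the periodic geometry agrees with brute-force
image scans; the pipeline preserves the qualitative solvatochromic
structure its input carries. What they do not show: random boxes have no
hydrogen-bond network, no orientational correlations and no dynamics
(snapshots are independent), and the mock map is not an electronic
structure — absolute ω₀/σ/τ_c values for real force fields require real
trajectories and a real engine.

# Numerical choices and edge cases

* Problem sizes: parameter-recovery checks use 20 seeds of 12 × 1,000
  points; the end-to-end mock analysis uses 3,000 snapshots so the
  third-moment (skewness) estimator at the least-populated coordination
  count resolves its sign at roughly three standard errors.
* Strict inequalities at all distance cutoffs; ties in mode assignment
  broken by intensity; equal fitted time constants returned as-is.
* The snapshot schedule truncates with a warning when the stride does not
  divide the usable length.
* Degenerate inputs error early and name the offending atom, window or
  replica: lone atoms, non-water species, featureless RDFs, empty mode
  windows, all-zero weights, sub-minimal sample counts.
* All generators are bitwise reproducible given (seed, parameters);
  pipeline CSVs carry a config-hash + seed provenance header and
  reproduce byte-identically.

# Known limitations

Orthorhombic boxes only; water-only solvent; distance-only coordination
(no angular hydrogen-bond criterion); biexponential FFCF model only (no
stretched or triexponential forms); no spectral line-shape synthesis or
motional-narrowing corrections; uncertainty propagation in the benchmark
assumes independent errors between force fields, which separate
simulations justify.
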