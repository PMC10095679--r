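---
title: "gamdkit: methods, numerical choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gamdkit: methods, numerical choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamdkit)
```

`gamdkit` is a desk-scale laboratory for the analysis pipeline used in
enhanced-sampling studies of protein dynamics: Gaussian-accelerated
dynamics (GaMD) with a harmonic boost, free-energy reweighting,
free-energy landscapes with basin detection, essential-dynamics PCA,
dynamic cross-correlation maps, structural-fluctuation metrics, and
geometric interaction networks.  Nothing here simulates a solvated
protein.  Instead, every component runs against analytic or synthetic
ground truth, so that each link of the pipeline can be validated in
isolation.  This vignette records the model assumptions, the tunable
parameters and their defaults, the numerical choices, and — importantly —
what a passing test does and does not establish.

## 1. The boost potential and its parameters

For potential energy $V(\vec r)$ below a threshold $E$, GaMD samples the
modified surface

$$V^*(\vec r) = V(\vec r) + \Delta V(\vec r), \qquad
\Delta V = \begin{cases} 0 & V \ge E \\ \tfrac{k}{2}(E - V)^2 & V < E,
\end{cases}$$

with $V_{max} \le E \le V_{min} + 1/k$ and $k = k_0/(V_{max}-V_{min})$.
The statistics $V_{max}, V_{min}, V_{avg}, \sigma_V$ are measured over a
conventional Langevin run (`run_cmd()`) and then **frozen** — the original
method's on-the-fly update during equilibration is deliberately out of
scope, matching the common practice of deriving production boost
parameters from a preceding conventional stage.  `compute_boost_params()`
implements both threshold placements:

* lower bound, $E = V_{max}$:
  $k_0 = \min\!\big(1,\ \frac{\sigma_0}{\sigma_V}\,
  \frac{V_{max}-V_{min}}{V_{max}-V_{avg}}\big)$;
* upper bound, $E = V_{min} + 1/k$:
  $k_0 = \big(1-\frac{\sigma_0}{\sigma_V}\big)\,
  \frac{V_{max}-V_{min}}{V_{avg}-V_{min}}$.

An upper-bound $k_0 \notin (0,1]$ — the usual situation when
$\sigma_0 \gtrsim \sigma_V$ or the energy distribution is tight — falls
back to the lower bound with a warning, the standard behaviour of GaMD
implementations.  $\sigma_0 = 0$ gives $k_0 = 0$: the boost vanishes
identically and the engine provably reduces to conventional dynamics
(tested bitwise at matched seeds).

**On $\sigma_0$.**  The source analyses this package grew from never state
their $\sigma_0$, nor whether the boost acted on the dihedral, total, or
both energy terms.  `gamdkit` applies a total-potential boost only and
exposes $\sigma_0$ (kcal/mol) as an explicit argument; the worked examples
use $\sigma_0 = 3$, which saturates $k_0 = 1$ on the toy double well and
is of the order of typical production settings.

## 2. Integrator

`run_cmd()`/`run_gamd()` integrate Langevin dynamics with the BAOAB
splitting (half-kick, half-drift, Ornstein-Uhlenbeck velocity refresh,
half-drift, half-kick), which has an unusually small configurational
sampling bias at moderate step sizes.  Velocities are initialised from the
Maxwell distribution at the stated temperature.  Defaults:

* friction 2.0 ps$^{-1}$ (the collision frequency used by the thermostat
  in the reference workflow);
* timestep `default_dt()` $= 0.25/\omega_{max}$, i.e. ~1/25 of the fastest
  oscillation period obtained by probing the stiffest curvature of the
  surface — on the built-in potentials this keeps zero-friction energy
  drift below $10^{-3}$ kcal/mol per 1000 steps;
* burn-in: the first 10% of stored frames are excluded from the potential
  statistics;
* units: Angstrom, ps, kcal/mol, amu, K, with
  1 kcal/mol = 418.4 amu A$^2$/ps$^2$ and $kT = 0.0019872041\,T$.

The boosted force is the exact gradient of $V^*$: $F^* = F\,(1 - k(E-V))$
for $V < E$; the threshold bracket guarantees the scaling factor is
non-negative, so the boost can flatten but never invert the landscape.
The compiled (Rcpp) core covers the two analytic potential families; a
pure-R integrator with an identical RNG stream covers arbitrary
user-supplied potentials, and the two paths are cross-checked in the test
suite.  All randomness flows from the user seed through R's RNG, so every
run is bitwise reproducible.

## 3. Toy potentials and what "ground truth" means

`make_double_well(h, a)` builds $V(x) = h((x/a)^2-1)^2$: minima of zero
energy at $\pm a$, barrier $h$ at the origin.  In 1D the pointwise
potential of mean force *is* $V(x)$ up to a constant, and
`reference_pmf` returns $-kT\ln p_{Boltz}$ with the partition function
from adaptive quadrature.  Tests compare *binned* PMFs against a per-bin
quadrature of the Boltzmann density, not against pointwise values, so
bin-averaging is accounted for rather than absorbed into the tolerance.

`make_multiwell_2d(depths, centers, width)` sums inverted Gaussians inside
a confining quartic wall ($r_0$ = outermost centre + 3 widths, prefactor
20 kcal/mol).  Overlapping wells are a warning, not an error — a merged
double minimum is a legitimate, if unusual, landscape.

## 4. Reweighting and basins

`reweight_pmf()` histograms 1-2 reaction coordinates (defaults: 100 bins
in 1D, 50x50 in 2D) and corrects the biased density per bin:

* `exp_avg`: multiply by $\langle e^{\Delta V/kT}\rangle_{bin}$ (exact but
  noise-amplifying);
* `cumulant2`: multiply by
  $\exp[(\langle\Delta V\rangle + \mathrm{Var}(\Delta V)/2kT)/kT]$, the
  second-order cumulant expansion that is the recommended estimator when
  $\Delta V$ per bin is near-Gaussian.  Bins with fewer than two frames
  cannot estimate a variance; they take the first-order (mean-only)
  correction and are listed in `first_order_bins` rather than silently
  degrading.

The PMF is min-shifted to zero over visited bins; empty bins are rendered
at `max(pmf) + kT` and excluded from basin detection, keeping plots
bounded without manufacturing infinite barriers.  The exponential in both
estimators is computed relative to its global maximum, which cancels in
the min-shift and avoids overflow.

`detect_basins()` implements a watershed/persistence flood: visited bins
are processed in increasing PMF order and merged into catchments
(4-neighbourhood in 2D); when two catchments meet, the shallower dies and
its depth is the saddle PMF minus its minimum.  Basins shallower than
`min_depth` (default 0.5 kcal/mol, a bit under 1 kT at 300 K) are
discarded and survivors are labelled `EB1, EB2, ...` by ascending PMF.
Ties in PMF are broken by bin index, making the outcome deterministic; a
perfectly flat surface has no basins by construction.

The source workflow never states its histogram resolution or estimator
choice; both estimators are provided and the one used is recorded in the
grid's metadata.

## 5. Structure metrics

`kabsch_superpose()` returns the weighted least-squares **proper**
rotation (reflections excluded by flipping the smallest singular
direction) and is validated against a quaternion-search + simplex-polish
oracle that shares no code with the SVD path.  RMSD fits and measures on
the same atom selection.  RMSF uses the iteratively aligned mean structure
(two passes, frame 1 seeding the first reference) rather than frame 0 —
the standard essential-dynamics convention; the reference kind is recorded
in the profile.  `probability_distribution()` reports unit-area densities
(renormalised so the trapezoid rule over bin centres integrates to exactly
1) with peaks at bin centres, plateau ties resolved to the leftmost bin;
default widths are 0.05 A for interaction distances and 0.1 A for RMSD and
radius of gyration.  Figure axes in the literature are sometimes
normalised per-curve-maximum instead; unit area was adopted because it
makes peak *heights* comparable across curves.

## 6. PCA and cross-correlation

The covariance uses the ensemble-average $1/n$ normalisation (not
$1/(n-1)$), mass-unweighted Cartesian coordinates in `x1,y1,z1,...`
order, and frames aligned to the iterative mean.  Eigenvectors get a
deterministic sign (largest-magnitude component positive).  Two facts
discovered during validation are worth recording:

* **Alignment projects out rigid-body motion.**  A randomly oriented
  planted mode has, on average, a $\sqrt{6/3N}$ share of its norm in the
  rigid-body subspace; superposition removes it, tilting the recovered
  direction by ~30 degrees for $N = 8$.  Mode-recovery tests therefore
  run on the unaligned covariance — the planted generator produces
  ensembles with no rigid-body motion, so alignment is unnecessary there.
  On real trajectories alignment is essential and remains the default.
* **"Independent movers" means uncorrelated displacements.**  Truly
  integrated random walks exhibit O(1) spurious sample correlation no
  matter the length; the decorrelation bound (|C| < 0.05 at 5000 frames)
  holds for — and is tested on — independent random displacements about
  fixed sites.

`dccm()` flags zero-variance particles, nulls their rows/columns and
keeps the unit diagonal, rather than dividing by zero or dropping atoms
silently.

## 7. Interaction network

A hydrogen bond exists in a frame iff the acceptor-donor distance is
**strictly** below 3.5 A and the acceptor-H-donor angle — the angle at the
hydrogen, a convention stated prominently because donor-centred
conventions exist — is **strictly** above 120 degrees.  Occupancy is the
percentage of frames satisfying the criteria, reported to 0.1.

Strict inequalities meet floating point at the threshold: a fixture built
*exactly* at 3.5 A / 120 deg could land an ulp on either side.
`make_hbond_fixture()` therefore snaps its frame-0 geometry to the
criterion-safe side (recomputed distance >= request, recomputed angle <=
request, both within $10^{-12}$ of the request against a $10^{-9}$
contract), so threshold semantics are deterministic.

Salt-bridge and ion-coordination records are bare distance series with a
configurable formation cutoff (default 5.5 A, a common salt-bridge
criterion; the source workflow states none).  Ring stacking is reported as
a centroid-distance descriptor only — no plane-angle classification — and
automated donor/acceptor perception is replaced by explicit manifests,
because toy fixtures carry no chemical typing.  Each donor-H-acceptor
triplet is a distinct record; nothing merges multiple acceptor atoms of
one residue into a single "bond".

## 8. Synthetic generators: what a green test establishes

The planted-mode generator emulates slow collective motion:
$x_t = \mu + \sum_m a_m(t)\,u_m + \varepsilon_t$ with orthonormal modes,
AR(1) amplitudes (default autocorrelation 0.9, stationary standard
deviation equal to the stated amplitude) and isotropic Gaussian noise
(default 0.1 A) around a helical mean with C-alpha-like spacing.  Its
population covariance is known exactly
($\sum_m s_m^2 u_m u_m^T + \sigma^2 I$), which is what the PCA and DCCM
tests recover.  The two-state and bimodal fixtures plant known state
populations and mode positions for the basin and distribution tests.

What these ensembles do **not** reproduce: anharmonic couplings between
modes, fat-tailed displacement distributions, solvent friction profiles,
periodic-boundary artefacts, or chemically realistic interaction geometry.
A green PCA test establishes that the estimator recovers a planted linear
subspace at the stated noise level — not that six eigenvectors of any real
protein mean anything.  Likewise the PMF-recovery test establishes
estimator correctness (sampling + reweighting + binning), not force-field
accuracy.

## 9. Sampling-length choices in the acceptance suite

Two choices deserve explanation because they were set by physics, not
convenience:

* The unboosted PMF-recovery run uses $3\times10^8$ steps.  At 300 K the
  6 kcal/mol barrier is 10 kT; the measured transition rate is ~35
  well-to-well crossings per $10^8$ steps, and the inter-well free-energy
  error scales like $kT/\sqrt{n_{cross}}$.  A "long" conventional run
  must therefore deliver on the order of a hundred crossings to resolve
  the well balance within the 0.3 kcal/mol tolerance.
* The boosted run stores $2\times10^5$ frames at stride 100 (storage
  stride is a free parameter of the engine).  Striding decorrelates the
  stored frames and gives the boosted trajectory ~$10^3$ crossings of its
  residual ~3.4 kcal/mol barrier, equilibrating the well populations that
  reweighting cannot repair after the fact.

## 10. Known limitations

* 1-based indices everywhere (R and PDB convention); no 0-based internal
  layer.
* Analytic potentials are 1-2D; the engine does not integrate many-body
  molecular systems, and the `box` field is carried but never applied (no
  periodic imaging).
* The dual dihedral+total boost, on-the-fly statistics updates, kinetics
  reweighting, time-lagged component analysis, plane-angle ring
  classification, and solvent-accessible surface areas are out of scope.
* The PDB dialect is the minimal robust v3.3 subset (ATOM/HETATM/MODEL/
  ENDMDL/TER; occupancy/B-factor written as 1.00/0.00); mmCIF, CONECT and
  compressed trajectory formats are not read.
* Element inference from atom names uses a small table of common
  biomolecular species; exotic elements fall back to carbon's mass with a
  warning.
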