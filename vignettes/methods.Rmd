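---
title: "Methods: kernel emulation, regressor chains, and voxel dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel emulation, regressor chains, and voxel dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpkchain)
```

## The quantity being modelled

A dose point kernel (DPK) describes the radial distribution of absorbed dose
around an isotropic electron point source in an infinite homogeneous medium.
`dpkchain` works throughout with the dimensionless *scaled* kernel

$$F(x) = 4\pi \rho r^2 r_0 \Phi(r), \qquad x = r/r_0,$$

where $\rho$ is the mass density (g/cm³), $r_0$ the electron range in the
continuous-slowing-down approximation (CSDA), and $\Phi(r)$ the specific
absorbed fraction (fraction of emitted energy absorbed per gram at distance
$r$). On a shell-scored grid this is computed as the deposited energy
fraction per scaled shell thickness,

$$F_i = \frac{\delta E_i / E_0}{\delta r / r_0},$$

so that $\sum_i F_i \, \Delta x$ equals the total absorbed fraction exactly —
an identity the tests exploit repeatedly. The monoenergetic scoring geometry
is 60 concentric shells of thickness $r_0/40$ (outer radius $1.5\,r_0$);
kernels are unstable beyond about $1.2\,r_0$ in transport calculations, which
is why nothing downstream relies on the outermost region.

## Materials and electron ranges

The material registry embeds 23 Hounsfield-unit-binned training tissues and
4 ICRP-style testing tissues (air, lung, soft tissue, cortical bone) as
weight fractions over a fixed 12-element set {H, C, N, O, Na, Mg, P, S, Cl,
Ar, K, Ca} plus mass density. Registering materials containing other
elements is rejected: the effective-atomic-number parameterization below is
only exercised for this element range (Z ≤ 20), and silently accepting e.g.
metals would extrapolate it badly.

**Effective Z/A.** For compounds the range fit needs a single
$(Z_{\mathrm{eff}}, A_{\mathrm{eff}})$ pair. Several compound rules exist;
we adopt electron-fraction weighting,

$$Z_{\mathrm{eff}} = \frac{\sum_i w_i (Z_i/A_i) Z_i}{\sum_i w_i (Z_i/A_i)},
\qquad A_{\mathrm{eff}} = \frac{Z_{\mathrm{eff}}}{\sum_i w_i (Z_i/A_i)},$$

which preserves the electron density of the mixture
($Z_{\mathrm{eff}}/A_{\mathrm{eff}} = \sum_i w_i Z_i/A_i$) — the quantity
electron stopping actually depends on. The rule is pluggable
(`effective_za(material, rule = ...)`) because the choice is a genuine
degree of freedom: no single compound rule is canonical in the literature.

**Range fit.** `csda_range()` evaluates the Tabata–Ito–Okabe generalized
analytic range formula,

$$r_0 = a_1\left[\frac{\ln(1 + a_2\tau)}{a_2} -
\frac{a_3\tau}{1 + a_4\tau^{a_5}}\right],
\qquad \tau = T/m_ec^2,$$

with the published coefficient set, in which $a_1..a_5$ depend on
$(Z_{\mathrm{eff}}, A_{\mathrm{eff}})$. That coefficient set was fitted to
the *extrapolated* range, which lies below CSDA-range tabulations by roughly
2–15% over 10 keV–3 MeV for water (largest at low energy, where the detour
factor is furthest from unity). The coefficients of the later CSDA refit of
the same functional form are not embedded here. Consequences and mitigation:

* Internally the pipeline is self-consistent — the same range function is
  used for feature construction, kernel scaling, and beta-grid construction,
  so the scaled kernels and everything derived from them are unaffected by a
  monotone re-definition of the range scale.
* When absolute ranges matter (comparing against published kernels in cm, or
  against range tabulations), pass a two-column table
  (`energy_keV,range_g_cm2`) via `range_table=`; it is log-log interpolated
  and overrides the analytic fit. A small NIST-ESTAR water CSDA table ships
  in `inst/extdata/` as an example and as the reference for the
  range-fidelity test, which documents the deviation of the analytic fit
  (that test is expected to fail at the 2% level with the embedded
  extrapolated-range coefficients — it is kept as an honest record of the
  discrepancy, not silenced).

## The synthetic kernel emulator

The emulator is a stand-in for shell-scored transport simulation, so that
the package is buildable and testable without a Monte Carlo engine. It is a
*documented parametric family*, not physics: per shell midpoint $x$,

$$g(x) = x^a e^{-b x^c}, \quad c = 2.2, \quad
a = \mathrm{clip}\big(0.6 + 0.25\ln(E/100\,\mathrm{keV}),\ 0.2,\ 1.8\big),$$

with the mode $m = \mathrm{clip}(0.35 + 0.05\ln(E/100) +
0.01(Z_{\mathrm{eff}}-7),\ 0.2,\ 0.7)$ fixing $b = a/(c\,m^c)$. The shape is
normalized so the deposited fraction sums to an absorbed fraction
$\eta = 1 - Y$ with the radiative-loss proxy
$Y = q/(1+q)$, $q = 6\times10^{-4} Z_{\mathrm{eff}} T_{\mathrm{MeV}}$.
Multiplicative Gaussian noise per shell has relative standard deviation

$$\sigma_i = 0.01\sqrt{f_{\mathrm{peak}}/\max(f_i, 10^{-4})}
\sqrt{10^7/n_{\mathrm{primaries}}},$$

i.e. 1% at the peak shell for $10^7$ histories and growing in the tail, the
error structure typical of shell-scored kernels; draws are clipped at zero
and, in the rare low-statistics case where the noisy sum would exceed unity,
rescaled to conserve energy. `n_primaries = Inf` disables noise and returns
the closed form, which the tests compare against an independent evaluation
of these formulas.

What the emulator reproduces: the scoring geometry, smooth dependence on
energy and effective Z, energy bookkeeping (absorbed fraction in
(0.6, 1]), and the calibrated noise scale. What it does not: backscatter
structure, bremsstrahlung tails, density-effect subtleties, or any material
dependence beyond $(\rho, Z_{\mathrm{eff}})$. Passing tests therefore
demonstrate that the *learning and dosimetry machinery* is correct, not that
the emulated kernels match real tissue kernels; for the latter, import
transport-code output via `read_kernel_table()` (schema
`material_label,energy_keV,shell_index,x_mid,F`), which substitutes for the
emulator everywhere downstream.

## Regressor chains

The 60 shell values of a kernel are correlated targets, so the model is a
*regressor chain*: model $M_1$ maps the 13 features to $F_1$; model $M_i$
receives the features plus targets $F_1..F_{i-1}$. We train on *observed*
targets and cascade *predictions* at inference — the canonical chaining
algorithm; training on the model's own predictions would amplify early
errors through the chain.

The feature vector is `[E0_keV, R_CSDA_g_cm2, density, w_H, w_C, w_Na,
w_Mg, w_P, w_S, w_Cl, w_Ar, w_K, w_Ca]`. Nitrogen and oxygen fractions are
deliberately not features (they are nearly determined by the others through
the unit-sum constraint and are almost collinear with density in tissue);
the 13-feature layout is fixed so that serialized models are unambiguous.

**Base objectives.** Ridge minimizes $\|Xw-y\|_2^2 + \alpha\|w\|_2^2$ and is
solved in closed form through the SVD; at $\alpha = 0$ the minimum-norm
least-squares solution is returned, which keeps exactly collinear chain
designs well defined. Lasso and elastic net minimize

$$\frac{1}{2n}\|Xw-y\|_2^2 + \gamma\alpha\|w\|_1 +
\frac{\alpha(1-\gamma)}{2}\|w\|_2^2,$$

so that $\gamma = 1$ is exactly the lasso — one consistent normalization for
both L1-penalized objectives (the ridge objective keeps its conventional
un-normalized form). They are solved by cyclic coordinate descent with
covariance updates (compiled inner loop), coefficients initialized at zero,
fixed cyclic column order, convergence when the largest coefficient update
falls below $10^{-6}$ (or $10^4$ sweeps). Tests certify solutions by their
subgradient (KKT) conditions and against an independent solver. Intercepts
are never penalized: design columns and the response are centered, and the
intercept is recovered from the means.

**Standardization.** Features — and targets when they enter as chain inputs
— are z-scored with training statistics (constant columns get unit scale);
the targets themselves are fitted unscaled. Penalized objectives are
scale-sensitive, and the weight-fraction features span four orders of
magnitude against the energy feature.

**Hyperparameters.** No canonical $(\alpha, \gamma)$ exists for this
problem, so by default `dpk_chain()` grid-searches $\alpha \in 10^{\{-4,
-3, -2, -1, 0, 1\}}$ (and $\gamma \in \{0.25, 0.5, 0.75\}$ for the elastic
net) on a seeded 20% validation split, selecting by pooled RMSE and
refitting on all rows.

**Metrics.** `regression_metrics()` pools the coefficient of determination
and RMSE over all shells and rows; $R^2$ uses the pooled grand mean (the
per-target breakdown is also returned, since pooled $R^2$ is flattered by
the large between-shell variance). MAPE is taken over nonzero-truth entries
and reported in percent.

## Beta-emitter kernels

A beta spectrum tabulated as (energy, intensity) pairs is resampled with a
degree-3 smoothing spline to 1000 equally spaced energies from 10 keV to the
endpoint $E_{\max}$; negative spline values are clipped and intensities
renormalized to unit sum (a constant spectrum is passed through unchanged —
the spline of a constant is that constant, special-cased to avoid
cross-validation degeneracies). Intensities are normalized *before* use so
that $E_{\mathrm{eff}} = \sum_j I_j E_{0j}$ is a weighted mean regardless of
the tabulation's units. The emitter kernel on 120 shells of thickness
$r_N/100$ ($r_N$ = range at $E_{\max}$) is

$$F_\beta(r/r_N) = \frac{r_N \sum_j I_j E_{0j} F_j(r/r_{0j}) / r_{0j}}
{E_{\mathrm{eff}}},$$

the unique combination of the monoenergetic kernels consistent with the
definitions of $F$, $F_\beta$ and the spectral superposition of specific
absorbed fractions (a printed form of this relation circulating in the
literature is typographically corrupted; the implementation follows the
dimensional analysis). Monoenergetic kernels are evaluated at each shell by
linear interpolation in scaled distance with $F = 0$ beyond the
monoenergetic grid's outer radius — kernels are smooth and non-negative, and
higher-order interpolation can overshoot at the peak. When kernels come from
an imported table rather than a fitted chain, values are additionally
interpolated linearly in log energy between tabulated energies.

Because the beta grid stops at $1.2\,r_N$ while lines near the endpoint have
support to $1.5\,r_{0j}$, a small tail fraction of the highest-energy lines
is truncated; the energy-bookkeeping test bounds this at 2% for a realistic
spectrum (endpoint lines carry little intensity).

`x90_rescale()` re-expresses a kernel on the X90 scale — the linearly
interpolated distance containing 90% of the kernel's own integral — the
abscissa convention used for cross-study kernel comparisons;
`mape_vs_reference()` then computes the mean absolute percentage error
against a reference kernel interpolated onto the same abscissae.

## Voxel dosimetry

`build_vdk()` integrates the beta kernel over voxel-pair geometry by Monte
Carlo: for each offset of a 23³ voxel cube (1 mm default), source and target
points are drawn uniformly in the central and target voxel, and the point
specific absorbed fraction $\Phi_\beta(r) = F_\beta(r/r_N)/(4\pi\rho r^2
r_N)$ (per gram) is averaged into a dose per decay,
$K = E_{\mathrm{eff}}[\mathrm{J}] \cdot \overline{\Phi_\beta} \cdot 10^3$ Gy
(1 keV = 1.602176634×10⁻¹⁶ J). Pairs closer than 10⁻⁴ cm are redrawn with
bounded retries: $\Phi_\beta \propto r^{-2}$ and the self-dose voxel would
otherwise have unbounded sample variance. Everything is deterministic given
the seed.

Dose is the discrete convolution of the cumulated activity with the kernel.
Cumulated activity assumes permanent trapping,
$\tilde A = 1.443\,T_{1/2}\,A$ (1.443 ≈ 1/ln 2) — appropriate for
microsphere radioembolization where there is no biological clearance. The
convolution is computed in the frequency domain, zero-padded to the full
linear convolution and cropped, and verified against a brute-force spatial
sum; map spacing must equal the kernel voxel size exactly (no silent
resampling). A single spatially invariant kernel is used: that is what a
convolution *is*. Per-voxel material-dependent kernels would make the
operator shift-variant; partitioning activity by material class and summing
per-class convolutions is a possible extension but is not implemented as the
default because it changes the mathematical object being computed.

**Gamma index.** For each reference voxel above a dose threshold (default 0:
all positive-dose voxels are evaluated), `gamma_index()` minimizes
$\Gamma = \sqrt{\Delta r^2/\delta r^2 + \Delta D^2/\delta D^2}$ over
evaluated voxel *centers* within a search sphere of radius $3\,\delta r$ —
no sub-voxel interpolation, which makes the result slightly conservative and
fast. Dose differences are normalized to the reference maximum by default
(the common clinical convention for 3%/3 mm reporting); a `local` mode
divides by the local reference dose instead. A voxel at exactly
$\gamma = 1$ counts as passing (comparison at $1 + 10^{-9}$ absorbs FFT and
rounding noise at the boundary case).

## Problem sizes and seeds

The test suite and the acceptance script run everything at sizes chosen to
exercise the full pipeline while staying comfortably desk-scale: chains are
benchmarked on 23 training materials × 30 log-spaced energies (690 kernels)
with 10⁷ emulated histories over five replicate seeds; voxel kernels in
tests use 9³–23³ voxels with 150–4000 pairs per voxel; the synthetic phantom
is 32³–48³ voxels. Every stochastic stage takes an explicit integer seed,
and stage seeds fan out from a master seed through a fixed affine counter
scheme, so identical seeds give bit-identical outputs across partial
re-runs.

## Known limitations

* Emulated kernels are synthetic (see above); real-tissue accuracy claims
  require imported transport kernels.
* The embedded analytic range coefficients fit the extrapolated range, not
  the CSDA range; use the table override for absolute-range work.
* Only beta/electron emission spectra are handled — no Auger or conversion
  electrons, no photons.
* The gamma search is voxel-center based; for spacings much coarser than
  $\delta r$ it is pessimistic compared to interpolating implementations.
* `region_stats()` reports first-order statistics only; no dose-volume
  histograms.
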