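---
title: "Estimating bilayer elasticity from NPT area fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bilayer elasticity from NPT area fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membelast)
```

## The model

A lipid bilayer simulated in the NPT ensemble at zero lateral tension has a
fluctuating projected area $A(t)$ (the box $x \cdot y$ cross-section). For a
tensionless membrane the equilibrium statistics of those fluctuations encode
the in-plane elastic stiffness: the **area expansion modulus**

$$K_A \;=\; \frac{k_B\,T\,A_0}{\langle \delta A^2 \rangle},
\qquad \langle \delta A^2 \rangle = \langle A^2\rangle - \langle A\rangle^2,$$

where $A_0$ is the mean area of the tensionless membrane and
$k_B = 1.380649\times10^{-23}$ J/K. The harder a membrane resists areal
strain, the smaller its area fluctuations at fixed temperature.

The **bending rigidity** follows from $K_A$ through the polymer-brush
relation

$$\kappa \;=\; \tfrac{1}{24}\,K_A\,(d - d_0)^2,$$

with $d$ the bilayer thickness measured as the peak-to-peak distance of the
phosphorus (head-group) number-density profile along the membrane normal,
and $d_0$ a fixed 1 nm offset subtracting the part of the thickness that
does not contribute mechanically. $\kappa$ is reported in units of $k_BT$
(the natural scale for membrane shape energetics) with joules carried
alongside; the two stored values always satisfy
$\kappa_{k_BT} \cdot k_B T = \kappa_J$ to within $10^{-12}$ relative.

Assumptions worth keeping in mind: the membrane must be tensionless (the
estimator reads the *equilibrium* variance; an applied tension shifts both
mean and variance), the series must be stationary (hence the equilibration
cut), and the polymer-brush relation treats the bilayer as two grafted
monolayer brushes — it is a good comparative tool across lipids but not an
exact identity.

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| equilibration cut | fraction or frames | 0.25 | a 50 ns equilibration is a quarter of a 200 ns production run, the shortest run length the pipeline is parameterized for, when frames map 1:1 to ns |
| histogram bin width | nm | 0.05 | resolves head-group peaks (width ~0.35 nm) with ~7 bins per peak while keeping per-bin counts high |
| $d_0$ | nm | 1.0 | the standard offset of the polymer-brush relation |
| verdict band | combined SE | 1 | two $\kappa$ values closer than one combined standard error are reported as indistinguishable; only statistical (block-average) errors enter, no hypothesis test is implied |
| stride | frames | 1 | every stored frame is used; a stride option exists for very finely saved trajectories |

Temperatures are accepted in °C in configurations (`temperature_C`, matching
how experimental conditions such as 30/50/70 °C are usually quoted) and
converted once to kelvin; all physics is computed in K.

## The synthetic ensemble generator

`membrane_spec()` fixes a ground truth $(K_A^*, A_0^*, T, d^*, \sigma)$ and
the generators sample from the *stationary* distribution that ground truth
implies:

* areas are Gaussian with mean $A_0^*$ and variance
  $k_B T A_0^* / K_A^*$, optionally as a stationary AR(1) process with the
  same variance and a chosen lag-1 autocorrelation $\rho$ — enough to
  exercise the estimator and the block-average error machinery, since the
  fluctuation relation depends only on stationary moments;
* phosphorus z coordinates come from a symmetric two-component Gaussian
  mixture with peaks at $\pm d^*/2$ and width $\sigma$, each atom assigned
  to a leaflet with probability 1/2.

Defaults mimic a 400-lipid, two-leaflet bilayer patch at 30 °C:
$A_0^* = 130$ nm² (about 0.65 nm² per lipid and 200 lipids per leaflet),
$K_A^* = 240$ mN/m, $d^* = 3.8$ nm, $\sigma = 0.35$ nm, 400 phosphorus
atoms. One integer seed controls everything; the area and coordinate
streams use separate derived seeds, and both are drawn frame-sequentially,
so generating more frames extends a series without perturbing the earlier
frames, and generating coordinates never changes the areas.

What the generator deliberately does **not** emulate: undulation modes and
their finite-size spectrum, area–thickness coupling, non-Gaussian tails,
protrusions, or any chemistry. Passing recovery tests therefore shows the
*estimators* are correct and calibrated on data satisfying their own
assumptions; it does not validate a force field, nor guarantee that a real
trajectory is long or stationary enough. One deliberate degenerate case:
$\sigma = 0$ is accepted and produces exact point masses at $\pm d^*/2$,
which pins the peak finder down exactly in tests.

## Numerical choices

**$A_0$.** The tensionless area is taken as the post-cut sample mean of the
same series. For a simulation run at zero tension this is the natural
reading; an `a0` override exists for workflows that fix $A_0$ externally.

**Variance.** The unbiased $(n-1)$ estimator. At $10^4$–$10^5$ frames the
bias of the alternative is negligible, but the choice is pinned down and
tested so the estimator is reproducible bit for bit against its oracle.

**Block averaging.** Block sizes double from 1; each block size must leave
at least 8 blocks. The standard error of the variance is obtained by
blocking the squared deviations about the global mean, which reduces a
variance error to a mean error and keeps block size 1 well defined. The
plateau is the smallest block size from which the SE changes by less than
5% over each of the next two doublings; if none exists the largest
admissible block size is used and flagged. The trailing `n mod b` frames
are discarded at each block size. The SE of $K_A$ follows by first-order
propagation, $\mathrm{SE}(K_A) = K_A \cdot \mathrm{SE}(\langle\delta
A^2\rangle)/\langle\delta A^2\rangle$; a moving-block bootstrap of the whole
estimator is available as a cross-check. A single block-SE realization at
the plateau carries sampling noise of order $\sqrt{2/n_{\mathrm{blocks}}}$
(tens of percent at 50 blocks), so calibration checks in the test suite
compare ensemble means over seeds, as one should when validating an error
estimator.

**Density profile.** Each frame is centered by subtracting its own mean
phosphorus z, which removes bilayer drift along the normal without needing
box information (center-then-average; the alternative, averaging before
centering, is exposed via `center = "none"` applied to pre-centered
coordinates). Bins are uniform and symmetric with $z = 0$ on a bin edge, so
the two leaflets never share a bin; the density integrates to the per-frame
atom count to $10^{-9}$ relative, which the suite asserts.

**Peak finding.** Each peak is the highest interior local maximum on its
side of the midplane, refined by a three-point parabola through the peak
bin and its neighbours (the refinement is clamped to half a bin and tested
against a no-interpolation argmax oracle). Ties between bins are broken
toward the midplane, deterministically. A valley guard rejects profiles
whose candidate peaks are not separated by a dip below half the lower peak
height: noise always produces *some* local maximum on each side of an
effectively monomodal profile, and reporting a sub-bin "thickness" there
would be meaningless. The reported uncertainty combines half a bin width
with the interpolation shift for each peak, in quadrature — a resolution
statement, not a sampling SE.

**Thickness per trajectory.** $d$ is measured once from the full post-cut
profile rather than per block; head-group peaks move far less than the
area fluctuates, so the histogram resolution dominates the error budget.

**Degenerate inputs.** Constant area series (zero variance), series shorter
than 100 frames after the cut, monomodal profiles, thickness below $d_0$,
selections matching no atoms, and non-monotonic time columns are all
reported as errors, never silently clamped.

## Scope of the bundled comparisons

`inst/extdata/pc_trio.toml` and `pe_trio.toml` define synthetic
DOPC/DAPC/DDPC and DOPE/DAPE/DDPE trios at 30 °C whose ground truths follow
the usual trend with acyl-chain polyunsaturation — larger area per lipid,
thinner bilayer, smaller $K_A$, hence smallest $\kappa$ for the di-DHA
species. Running `analyze` on them demonstrates the comparative report and
its verdict logic on realistic magnitudes (roughly 12–20 $k_BT$); the
ground-truth values are illustrative inputs, not measurements.

The test suite and the acceptance script run at desk scale by design:
$2\times10^4$ frames per ensemble (100 ensembles for recovery calibration),
$10^6$ mixture draws for thickness recovery, $5\times10^4$ frames for the
AR(1) error calibration. These sizes put the statistical noise of each
check well below its assertion margin while keeping the whole suite in the
tens of seconds.

## Known limitations

* No undulation-spectrum estimator of $\kappa$: the package derives
  $\kappa$ only through $K_A$ and $d$. For very soft or very large
  membranes the height-fluctuation route would be the natural complement.
* The fluctuation estimator assumes the saved frames sample the area
  decorrelation time reasonably; for extremely correlated series the block
  plateau may not be reached within the admissible block sizes, in which
  case the result is flagged (`plateau_found = FALSE`) and the SE is a
  lower bound.
* The coordinate adapter reads GRO/PDB text only and treats coordinates as
  already unwrapped; binary trajectory formats should be converted or
  reduced to z tables upstream.
* Electron-density or per-species profiles are out of scope; thickness is
  defined on the phosphorus number density alone.
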