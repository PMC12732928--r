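---
title: "Inferring protein oligomeric state from SAXS, MALDI, AFM and ITC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protein oligomeric state from SAXS, MALDI, AFM and ITC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(oligostate)
```

## The problem

Ice-binding proteins (IBPs) adsorb to ice crystal surfaces, and their
activity scales with the area of the ice-binding site. One route to a larger
binding surface is self-association: a small (~17 kDa) monomer assembling
into dimers, trimers, tetramers and beyond. No single technique settles the
oligomeric state of such a loose, polydisperse assembly. This package
implements the complementary computational analyses that together support a
stoichiometry call for the longhorn-sculpin type IBP system:

* **MALDI-TOF** — an oligomer ladder of protonated ions at
  $m/z = (nM + z m_p)/z$ is matched against a monomer mass $M$;
* **AFM** — particles in height images are measured as equivalent ellipses
  and stratified into morphometric classes;
* **SAXS** — Guinier and cross-sectional Guinier fits, the dimensionless
  Kratky transform, an indirect Fourier transform (IFT) to $P(r)$,
  analytic form-factor fitting and an excluded-volume molecular weight;
* **ITC** — injection-peak integration and the temperature ordering of
  total dissociation heat;
* a **consistency report** reconciling the molecular-weight, rod-diameter
  and particle-size evidence into ranked stoichiometry candidates.

Because raw instrument data for this system are not publicly deposited, the
package ships seeded synthetic generators that emulate the statistical
structure each analysis assumes. Every analysis is validated against closed
forms or against generator ground truth.

## Synthetic generators: what they emulate, and what they do not

`simulate_saxs()` evaluates an analytic form factor (Guinier law, sphere,
circular or elliptical cylinder) and applies multiplicative Gaussian noise
with fractional sd per point (default 2%, a typical azimuthally averaged
synchrotron profile). It does not simulate detector images, buffer
mismatch, aggregation upturns or interparticle structure factors — so a
passing recovery test says the *estimator* is right, not that real data
reduction is this clean.

`simulate_maldi()` produces delta-like peak lists, not rendered spectra:
series matching consumes peak positions, so baselines, centroiding and
isotope structure (unresolvable in linear mode at 17–120 kDa) are out of
scope. Intensities decay geometrically with oligomer order.

`simulate_afm()` renders particles as smooth elliptical caps
$h(x,y) = z\,\max(0, 1 - (x'/a_1)^2 - (y'/a_2)^2)$ on i.i.d. Gaussian
background roughness (default sd 0.05 nm). The cap is a deliberate choice:
the z-profile of a soft protein particle is not known, and a smooth
single-maximum cap matches the observed "elongated particle" phenomenology.
Particles are placed on a jittered grid, which guarantees non-overlap and
a deterministic count; real images have Poisson-clustered, partially
overlapping particles and tip-convolution broadening (tip radius 1–3 nm
versus 10–50 nm particles, a second-order effect we do not model).
Per-particle $(a_1, a_2, z)$ are drawn from the per-class truncated
Gaussian marginals in `afm_particle_classes()`. Drawing marginals
independently cannot also reproduce the tabulated joint statistics (axis
ratio, $\sqrt{\text{area}}$) exactly — the class-IV reference row is itself
internally inconsistent with $\sqrt{\pi a_1 a_2}$ — so recovery is asserted
on $a_1$, $a_2$ and height, with ratio/area checked loosely.

`simulate_itc()` composes each injection as a single-exponential response
peak ($\tau$ = 15 s, the standard power-compensation instrument response)
scaled so its time integral equals the specified heat, plus optional linear
drift and Gaussian noise. Only integrals matter downstream, so the exact
kernel shape is immaterial.

## SAXS reductions

**Guinier fit.** Weighted linear regression of $\ln I$ on $q^2$ over the
largest low-$q$ window satisfying $qR_g \le 1.3$ (the community convention,
configurable), found by iterating fit → recompute $R_g$ → shrink. For an
ideal Guinier scatterer the inversion is exact. For a sphere, the finite
window carries a known systematic of about +2% (the $q^4$ term of the
sphere's $\ln I$ is concave); the package therefore cross-checks Guinier
$R_g$ against the IFT real-space $R_g$ at the 3% level, and uses the IFT
value where 1% accuracy matters.

**Cross-sectional Guinier.** For elongated particles, $\ln(qI)$ vs $q^2$
yields the cross-section $R_c$, and a uniform rod has diameter
$d = 2 R_c \sqrt 2$. The default window starts at $1/R_g$ and shrinks its
upper end to $qR_c \le 1$. A diameter near 12 Å is the single-α-helix
scale; `rod_vs_helix()` formalizes that comparison with a ±25% band.

**Dimensionless Kratky.** $(qR_g)^2 I/I_0$ against $qR_g$ peaks at
$(\sqrt 3, 3/e \approx 1.104)$ for compact particles — the analytic maximum
of $x^2 e^{-x^2/3}$ — and plateaus for flexible chains. The peak is located
by quadratic interpolation through the maximum sample; a boundary maximum
is reported as "no interior peak".

**IFT.** $I(q) = 4\pi \int_0^{D_{max}} P(r)\,\mathrm{sinc}(qr)\,dr$ is
inverted by Tikhonov regularization with a squared-second-difference
penalty and $P(0) = P(D_{max}) = 0$ pinned. The weight $\alpha$ is chosen
by maximizing a Bayesian-evidence score over a 50-point log grid
($10^{-2}$–$10^8$); the linear algebra is whitened through the Cholesky
factor of the penalty so one SVD serves the whole grid. A soft active-set
penalty keeps $\min P \ge -1\%$ of $\max P$, as required for convex
homogeneous bodies. `scan_dmax()` repeats the fit over candidate supports
and scores evidence minus an endpoint-steepness penalty, breaking ties
toward the smallest support within 1% of the best score. On noise-free
sphere data the recovered $P(r)$ matches the closed form to 0.1% RMS and
the scan selects the true diameter.

**Form-factor fitting.** The elliptical-cylinder intensity is the
orientational average of
$[2J_1(u)/u]\,\mathrm{sinc}(qL\cos\alpha/2)$ squared, with
$u = q\sin\alpha\, a\sqrt{\cos^2\psi + \nu^2\sin^2\psi}$, computed by
fixed-order Gauss–Legendre quadrature (default order 76 per axis,
self-converged to $10^{-14}$ against order 152 and to machine precision
against the circular-cylinder limit at $\nu = 1$). `fit_form_factor()`
profiles the linear parameters (scale, background) analytically and
searches only the shape parameters, scoring a coarse grid of starts and
polishing the best two by Nelder-Mead — cheap protection against local
minima in an oscillatory objective. Fixing the cylinder length to an
AFM-derived thickness (16 Å) while optimizing the cross-section axes
mirrors how complementary thickness information is used in practice. The
interpretation that the ~77 Å figure is the *semi*-axis is adopted
because only then does the closed-form
$R_g = \sqrt{(a^2+b^2)/4 + L^2/12} = 60.3$ Å match the measured ~60 Å.

**Molecular weight.** `volume_to_mw()` converts an excluded volume using
the protein partial specific volume ($\bar v = 0.73$ cm³/g by default,
divisor 1.212 nm³/kDa, both printed). Literature weight estimates for this
system's ~105 nm³ volume imply a slightly larger divisor (1.24–1.31); the
package keeps the standard $\bar v$ and reports the convention rather than
tuning it.

## MALDI series assignment

Peaks are matched against the protonated ladder with a two-tier tolerance:
500 ppm for $n \le 4$ and 2000 ppm for $n \ge 5$, reflecting the broadening
of high-mass peaks (the published hexamer $z=1$/$z=2$ pair itself disagrees
by ~0.12%). The primary assignment takes the smallest $z$, then smallest
$n$; all candidates are retained, and the intrinsic degeneracy
$(2k, 2) \equiv (k, 1)$ is reported, never silently resolved. The proton is
included by default (`protonated = FALSE` reproduces bare $nM/z$); at this
mass scale the two conventions differ by ~60 ppm, inside tolerance either
way.

## AFM morphometry

Row-wise polynomial flattening uses only pixels below a robust
median + 2 MAD mask. Detection is hysteresis segmentation: regions are
*delineated* at a low boundary threshold (3 robust background sd,
~0.15 nm at default roughness) but *kept* only if their maximum exceeds
0.5 nm — the height below which protein-free control surfaces show no
objects. Delineating at the detection level instead would clip a cap of
height $h$ to $\sqrt{1 - 0.5/h}$ of its axes (a 10–15% shortfall at 1.6–2.4
nm heights); the boundary threshold keeps the bias at the few-percent
level, the same reason Gwyddion-style grain marking thresholds near the
background. Regions touching the border are censored and discarded;
8-connectivity is used throughout.

The equivalent ellipse comes from the second central moments of the binary
mask (semi-axes $2\sqrt{\lambda}$, with the 1/12 px discretization
correction); the height statistic is the region maximum, which matches the
control-threshold semantics but inherits a small positive noise bias
(≈ +4% at class-I heights), well inside the 10% recovery band. Both mask
and ellipse areas are emitted ($S_{mask}$, $S_{ellipse}$); class
comparisons use $S_{mask}$. Classes are the four semi-major-axis windows
I (5–20 nm), II (17–27), III (28–44), IV (44–60); I/II overlap on 17–20 nm
and particles there carry dual membership with a flag. Class statistics are
ML Gaussian estimates with a histogram-curve fit as a diagnostic.

## ITC

Per injection, the baseline is a linear fit through two anchor stretches
bracketing the peak — the final 20% of the preceding inter-injection
segment and the final 20% of the injection's own segment (at 300 s spacing
an exponential tail with $\tau = 15$ s has decayed to $10^{-7}$ there) —
evaluated across a 290 s integration window; the heat is the trapezoidal
integral of power minus baseline. Bracketing matters: a one-sided fit
extrapolated 290 s forward amplifies anchor noise roughly tenfold and
would drown µJ-scale heats at realistic instrument noise, while
interpolation keeps the baseline contribution below the direct
integration noise. The construction is exactly invariant to constant
offsets and cancels linear drift. No dissociation model is fitted — with several
coexisting oligomer equilibria the quantitative problem is ill-posed — so
the analysis stops at per-injection heats and the temperature ordering of
total |Q|.

## Consistency report

`stoichiometry_from_mw()` ranks $n$ by $|MW/M - n|$ (ties toward smaller
$n$). With the excluded-volume MW (~86.6 kDa at the default $\bar v$) and a
17.4–17.5 kDa monomer, the top candidates are $n = 5$ and $n = 4$ — the
tetramer/pentamer window. The rod-diameter and AFM-vs-SAXS checks use
explicit tolerance bands (±25% and ±35%) printed in the report, so the
qualitative claims stay auditable; the AFM/SAXS comparison uses the full
major axis $2a_1$ and prints $a_1$ alongside, since either convention can
be argued.

## Numerical choices and problem sizes

Test and acceptance runs use: 220–600-point q grids, IFT grids of
$n_r = 101$ with a 50-point α scan, quadrature order 76, and AFM fields of
1000 particles per class at 1–2 nm/px (images of roughly 1800–2500 px per
side). These sizes keep every estimator's sampling error well below its
assessment band. Degenerate inputs are handled explicitly: increasing
low-q intensity → "no Guinier region"; non-negative $\ln(qI)$ slope → "no
rod-like regime"; one-pixel-wide AFM regions get an $a_2$ floor of half a
pixel with a flag; unassigned MALDI peaks and empty AFM detections are
valid outcomes, not errors.

## Known limitations

* No ab initio bead modeling, structure factors or multiphase models on
  the SAXS side; the 0.07–0.12 1/Å inflexion of real data is outside the
  single-shape models shipped.
* The AFM generator's independent marginals understate the correlations of
  real particle populations, and no tip deconvolution is applied.
* ITC stops deliberately short of thermodynamic constants.
* MALDI analysis is list-based; raw spectrum processing belongs upstream.
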