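# oligostate

Multi-technique oligomeric-state analysis for protein assemblies, in R.

Small ice-binding proteins (IBPs) gain ice-binding surface — and activity —
by self-associating into dimers, trimers, tetramers and larger assemblies.
No single biophysical technique settles the stoichiometry of such loose,
polydisperse complexes; the call comes from reconciling several.
`oligostate` implements that reconciliation as a tested, tidyverse-native
pipeline for four evidence streams plus a cross-technique report:

| evidence | analysis |
|---|---|
| MALDI-TOF peak lists | oligomer ladder matching at m/z = (nM + z·m_p)/z; monomer-mass estimation; charge-degeneracy flagging |
| SAXS profiles I(q) | Guinier fit (auto window, qRg ≤ 1.3); cross-sectional Guinier Rc with rod diameter 2Rc√2; dimensionless Kratky ((√3, 3/e) compactness reference); regularized indirect Fourier transform to P(r) with evidence-selected α and Dmax scanning; elliptical-cylinder form-factor fitting; excluded-volume → MW |
| AFM height maps | flattening, hysteresis particle detection, moment-based equivalent ellipses (a1, a2, a1/a2, √area, height), four semi-major-axis classes with Gaussian statistics |
| ITC thermograms | bracketed-baseline injection-peak integration; temperature ordering of total dissociation heat |
| all of the above | ranked stoichiometry candidates from MW/M; rod-vs-helix and AFM-vs-SAXS dimension checks |

Seeded synthetic generators (`simulate_saxs()`, `simulate_maldi()`,
`simulate_afm()`, `simulate_itc()`) emulate each instrument so the whole
pipeline runs and is validated without raw instrument data. Every analysis
returns a tibble or a small S3 object with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate a 2%-noise scattering profile of the package's reference shape —
an elliptical cylinder with semi-axes 77 / 92.4 Å and 16 Å thickness —
and run the SAXS reductions, then fold in MALDI anchors and build the
consistency report:

```r
library(oligostate)

q <- seq(0.005, 0.35, length.out = 300)
profile <- simulate_saxs("elliptical_cylinder", list(a = 77, nu = 1.2, l = 16),
                         q, frac_sd = 0.02, seed = 1)

guinier_fit(profile)
#> Guinier fit: Rg = 60.25 Angstrom (sd 1.02), I0 = 1.003
#> window q in [0.005, 0.02115] (15 pts), max qRg = 1.275 (limit 1.30)

ift(profile, dmax = 190)
#> IFT P(r): Dmax = 190 Angstrom, real-space Rg = 60.26, I0 = 1.003
#> alpha = 1e+08 (evidence -287.9), reduced chi^2 = 0.937, effective params 24.1

est <- estimate_monomer_mass(
  data.frame(mz = c(34828.6, 52245.1, 69653.1), n = 2:4, z = 1))
est
#> Monomer mass estimate: M = 17413.65 Da (sd 0.529) from 3 anchor peak(s)

build_report(maldi = est,
             saxs = list(volume_nm3 = 105, rod_diameter = 13.7, dmax_nm = 20.8),
             afm = list(range_I_a1_nm = 14.2))
#> == Oligomeric-state consistency report ==
#> monomer mass: 17.414 kDa
#> assembly MW (SAXS): 86.6 kDa
#> top stoichiometry candidates: n = 5, 4 (MW/M = 4.97)
#> rod diameter 13.7 A vs helix 12 A: ratio 1.14 (consistent)
#> AFM 2*a1 = 28.4 nm vs SAXS Dmax = 20.8 nm: ratio 1.37 (borderline)
#> missing techniques: itc
```

Reading the output: the Guinier and real-space radii agree at ~60 Å (the
reference shape's closed-form Rg is 60.3 Å); the back-transform fits the
data at reduced χ² ≈ 0.94; the monomer-mass ladder and the
excluded-volume molecular weight (105 nm³ → 86.6 kDa at v̄ = 0.73 cm³/g)
rank the pentamer and tetramer as the top stoichiometry candidates; the
4.86 Å cross-section (diameter 13.7 Å) is consistent with a single
α-helix; and the smallest AFM particle class brackets the SAXS maximum
dimension.

The methods vignette (`vignettes/oligomeric-state-pipeline.Rmd`) documents
the models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices.

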