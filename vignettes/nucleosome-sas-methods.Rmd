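---
title: "Methods: small-angle scattering analysis of nucleosome core particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-angle scattering analysis of nucleosome core particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `nucsas`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Scattering-length densities and contrasts

Component neutron scattering-length densities are computed from
residue-level tables (20 amino acids, 4 deoxynucleotides) that carry
explicit atom inventories, so any residue-level quantity can be audited
against a per-atom sum — the test suite does exactly that with a
poly-glycine chain. The in-chain monomer conventions are: amino-acid
residue = free amino acid − H₂O (plus one H₂O of chain termini per
chain); deoxynucleotide residue = nucleoside + HPO₃ − H₂O, i.e. the
free-acid phosphodiester form. Volumes come from mass densities, default
1.35 g/cm³ (protein) and 1.69 g/cm³ (DNA).

Solvent SLDs are the volume-fraction linear mixture of the pure-water
endpoints computed from bound coherent scattering lengths
(b_H = −3.739 fm, b_D = 6.671 fm, b_O = 5.803 fm) at 1.000 and
1.105 g/cm³. This gives −0.56 × 10⁻⁶ Å⁻² for H₂O and ≈ 6.36 × 10⁻⁶ Å⁻²
for D₂O. A value of 6.67 × 10⁻⁶ Å⁻² is sometimes quoted for D₂O; that
number coincides with the deuteron scattering length (6.671 fm) and is
not consistent with the Σb/V definition, so the computed 6.36 is used
throughout.

**H/D exchange.** A single `exchange_fraction` (default 0.5, the
mass-spectrometry-motivated figure for folded nucleosomal protein) scales
the replacement of labile hydrogens — backbone amides plus side-chain
OH/NH/SH, and base NH/NH₂ plus one phosphate OH for DNA — by deuterium in
proportion to the solvent D₂O fraction. A finer per-residue-class
exchange model is deliberately out of scope. Note that nucleic-acid
labile hydrogens in reality exchange essentially completely; users
modeling DNA-only samples should set `exchange_fraction = 1`, which moves
the DNA match point from 0.57 to the classical ≈ 0.62.

## Guinier analysis

`guinier_fit()` performs a weighted linear fit of ln *I* vs *q*² with
weights (I/σ)². The automatic window starts at the first
positive-intensity point, rejects leading outliers with studentized
residuals above 3 (deterministic emulation of manual low-q cleanup), and
iterates the window to the largest self-consistent set with
*q*·*R*g ≤ 1.2 (relative tolerance 10⁻⁴, with limit-cycle detection for
the rare window oscillation). The 1.2 ceiling is the conventional bound
for compact particles and is configurable. On exact Guinier-law data the
closed form is recovered to machine precision; on an exact homogeneous
sphere the finite window inflates *R*g by ≈ 1.7% (the known quartic term
in the expansion), which drops below 1% by `qrg_max = 0.8`.

## Indirect Fourier transform

`ift_pr()` inverts the spherically averaged Fourier relation on a fixed
r-grid (default 120 nodes) with p(0) = p(Dmax) = 0 pinned, minimizing the
χ² misfit plus α·‖Δ²p‖² (second-difference curvature penalty).

* **Choice of α.** Generalized cross-validation over a 40-point
  logarithmic grid anchored on the ratio of operator norms. GCV was
  chosen over the L-curve corner after the corner criterion proved
  unstable across the package's wide range of noise levels (from
  noise-free synthetic curves to 10% counting noise); GCV degrades
  gracefully to near-interpolation on noise-free data.
* **Quality score.** The geometric mean of a χ² plausibility term,
  1/(1 + max(0, χ²red − 1)²), with χ²red computed against the effective
  degrees of freedom (n − tr of the smoother matrix), and a shape term
  penalizing negative excursions and extra local extrema. It is a
  transparent surrogate for the perceptual "total estimate" scores of
  classical IFT software; numerical equality with those scores is not
  claimed. The D_max scan recommends the smallest candidate within 2% of
  the best quality, biasing ties toward compact supports.
* **Feasibility.** When q_min·D_max > π the first Shannon channel is not
  measured and a warning flag is raised; the fit proceeds but the large-r
  part of p(r) is extrapolation.

## Stuhrmann analysis and contrast-series inference

`stuhrmann_fit()` is linear-in-parameters least squares of *R*g² on
(1, 1/Δρ, −1/Δρ²), weighted by σ(Rg²) = 2·Rg·σ(Rg) by default with an
unweighted option (the plot-space convention of manual fitting).
Ill-conditioning — contrasts clustered within a 1.5× span — is flagged
rather than refused. Sign conventions: α > 0 places the higher-SLD
component peripherally; β ≠ 0 indicates displaced component centers, and
centrosymmetric bodies give β = 0 (verified against closed-form two-phase
bodies).

The component molecular-weight solve uses the two-component
forward-scattering relation √(I₀/n) = |Δρ_P| V_P-per-mass·MW_P +
|Δρ_D| V_D-per-mass·MW_D across contrast points, with the particle number
density n = c·N_A/MW_total iterated to self-consistency (the total mass
appears on both sides). The |Δρ| form assumes all measured contrasts sit
on one side of each component's match point or on matching sides — the
standard experimental design (e.g. 0/20/70/80/95% D₂O) satisfies this.
Negative solved masses are reported with a warning flag, never silently
clamped.

The per-q decomposition solves I(q) = Δρ_P²·I_P + Δρ_P·Δρ_D·I_PD +
Δρ_D²·I_D by weighted least squares at each q. The coefficient of the
final term is the DNA contrast squared — the physically standard form of
the contrast-variation decomposition (one transcription of this equation
circulates with the protein contrast squared on the DNA term; that is a
typographical error and is not implemented). An optional per-profile flat
background nuisance is available for series with uncertain incoherent
subtraction.

## Core–shell cylinder and global fitting

The core–shell cylinder uses a uniform shell on **all** faces: core
(R, L) at the core SLD inside an outer cylinder (R + t, L + 2t) at the
shell SLD. The amplitude is the sum of the core at contrast
(ρ_core − ρ_shell) and the outer cylinder at (ρ_shell − ρ_solvent),
orientationally averaged by Gauss–Legendre quadrature (default 76 nodes;
orders below 16 are refused; 76 nodes agree with a 10×-order reference to
better than 10⁻⁴ over q ≤ 0.3 Å⁻¹). A side-shell-only variant is *not*
assumed; for the nucleosome mapping (core = histone octamer, shell = DNA
wrap, t = DNA-wrap radius) the all-faces shell is the standard model and
the difference from a side-only variant is part of what the global fit
absorbs into geometry.

`global_cv_fit()` shares (R, t, L) across curves and profiles out each
curve's scale and flat background by weighted linear least squares inside
the objective, so the nonlinear optimizer (Levenberg–Marquardt with box
bounds, optional seeded multi-start) sees only the three geometry
parameters. X-ray curves enter through electron-density contrasts; since
scale is per-curve, only the protein:DNA contrast ratio matters there.

## The synthetic generator

The generator's defaults are the study conditions of the package's
validation suite: superhelix radius 41.8 Å, pitch 25.9 Å, 1.65 wrap
turns, 147 bp, protein core cylinder 32 × 55 Å — canonical nucleosome
crystallographic conventions, exposed as configuration. DNA is traced as
two strand tracks offset 10 Å from the duplex axis (twisting at one turn
per 10.4 bp), giving the particle its ~110 Å maximum dimension; protein
beads fill the core on a 5 Å lattice. Profiles are evaluated through
partial Debye sums (protein–protein, DNA–DNA, cross) so that one distance
histogram serves every contrast, and are placed on the absolute scale
(cm⁻¹) through the particle number density.

Noise is Gaussian with σ = √(I + background)/exposure_scale — counting
statistics over a flat incoherent background that scales linearly with
the solvent H fraction (level 0.05 cm⁻¹ at 0% D₂O, exposure scale 100 by
default, i.e. ≈ 3% relative noise at the forward intensity of a 1 mg/mL
sample). By default the background is subtracted from the emitted
intensity while still inflating σ, emulating reduced, buffer-subtracted
data; `subtract_background = FALSE` keeps it. Pressure series are
number-weighted mixtures of native, end-unwrapped (default 25 bp per end,
15% extension) and fully extended states, the last modeled as a Gaussian
coil at the rigid-rod Rg of the full DNA contour (L/√12 ≈ 144 Å for
147 bp) with conserved forward intensity; hysteresis is emulated by
residual extended weight at labeled return points.

**What the generator does not emulate:** instrument resolution smearing
(wavelength spread), interparticle structure factors (S(q) = 1, the
dilute regime), aggregation, radiation damage, and detector artifacts.
Passing recovery tests on these synthetics therefore demonstrates the
estimators' correctness and calibration, not robustness to those
real-data effects.

The shipped histone chains are synthetic histone-like sequences with
realistic lengths and residue composition (octamer ≈ 102 kDa), documented
as such; the DNA positioning sequences (Widom 601, α-satellite) are the
standard published 145-mers.

## Series analysis and hysteresis

`analyze_series()` tabulates Guinier and IFT parameters per profile.
Hysteresis deltas at labeled return-to-baseline points use the
*real-space* (IFT) Rg as the tracking statistic — the convention of
pressure-series work, and markedly more sensitive than the Guinier Rg
when a minor extended fraction (coil Rg ≈ 144 Å) has mostly decayed below
the instrument's q_min ≈ 0.009 Å⁻¹ by the start of the Guinier window.
With 10% residual extended weight, six seeded replicates detect a
positive ΔRg at better than 3 standard errors of the replicate mean.

## Problem sizes and determinism

The validation suite uses bead models of ~1,800 beads, 120-point q grids,
120-node r-grids, 20-replicate global-fit studies and 6-replicate
hysteresis studies — sizes chosen so the full suite exercises every
estimator end to end in a few minutes on a laptop core while keeping
Monte-Carlo standard errors well below the tolerances being asserted.
All stochastic steps are seeded; simulated profiles are bit-reproducible
from their manifests.

## Known limitations

* The IFT has no positivity constraint; strongly undersmoothed fits of
  very noisy curves can oscillate (the quality score flags this).
* The forward-intensity molecular-weight solve requires absolute-scale I₀ and
  concentrations; arbitrary-unit data yield only mass ratios.
* The Stuhrmann fit propagates Guinier σ(Rg) but not the covariance
  between points sharing a calibration.
* X-ray and neutron curves are combined in global fits through fixed
  composition-derived contrast ratios; excipient-based X-ray contrast
  modulation is not modeled.
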