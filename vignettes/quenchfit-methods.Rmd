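---
title: "Models and methods in quenchfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in quenchfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchfit)
```

quenchfit analyses fluorescence quenching titrations of a protein by a
small molecule: how much signal is lost as ligand is added, what binding
constants and thermodynamics that implies, and — through the interaction
density function — how many site classes are involved and whether they
cooperate. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Inner-filter correction

An absorbing ligand attenuates both the excitation beam and the emitted
light, so the observed fluorescence is

$$F_{obs}(\lambda) = F_{true}(\lambda)\,
  10^{-(A_{ex} + A(\lambda))/2},$$

and `innerFilterCorrect()` inverts it wavelength by wavelength,
$F_{corr}(\lambda) = F_{obs}(\lambda)\,10^{(A_{ex}+A(\lambda))/2}$. The
factor of 2 is the usual 1-cm-cuvette midpoint approximation. Correcting
*the whole spectrum*, not just the peak intensity, matters: when the
ligand's absorbance band overlaps the emission band asymmetrically, the
uncorrected spectrum's maximum drifts to longer wavelengths with ligand —
an artefact easily mistaken for a genuine polarity change around the
fluorophore. The correction removes the drift; only a shift that survives
correction reports on the fluorophore's microenvironment.

Two absorbance entry points are provided because practice varies: a
measured total-sample absorbance spectrum per titration step, or a
Beer-Lambert ligand band built from the concentration
(`ligandAbsorbanceSpectrum()`, default
$\varepsilon = 18700\ \mathrm{M^{-1}cm^{-1}}$ at 326 nm, 1 cm path).
Absorbance is interpolated linearly between grid points and never
extrapolated. Correction is applied after buffer-baseline subtraction, the
only order that does not amplify buffer scatter; negative differences
after subtraction are clamped to zero (and counted), since fluorescence
cannot be negative. Peak location is plain grid argmax with ties broken
toward the blue — its resolution is the grid spacing, which is why shift
tests speak of "within one grid step".

## Quenching analysis

`buildCurve()` reduces each corrected spectrum to a scalar — intensity at
340 nm or trapezoidal band area over 305–400 nm — and forms
$F_0/F$ ratios. The Stern-Volmer model
$F_0/F = 1 + K_{SV}[L]$ has no free intercept, so `sternVolmerFit()` fixes
it at 1 by default (a free-intercept ordinary regression is available as a
diagnostic). With the unquenched lifetime $\tau_0$ the bimolecular rate
$k_q = K_{SV}/\tau_0$ follows exactly.

The area and intensity routes should agree whenever quenching scales the
whole band uniformly (one fluorophore class, equally accessible); the
package tests this equivalence on generated data. On real spectra the two
modes differ by residual band-shape effects — a useful consistency check,
not an error.

Mechanism classification uses the standard rules made explicit: *dynamic*
if $\tau_0/\tau$ tracks $F_0/F$ (within 5% relative by default); *static*
if $k_q$ exceeds the diffusion limit $10^{10}\ \mathrm{M^{-1}s^{-1}}$ and
the lifetime response is small next to the intensity response (under 25%
of it by default); *mixed* otherwise. Both tolerances are arguments of
`classifyMechanism()` — the literature states these rules qualitatively,
so the thresholds are necessarily a convention and are kept visible.

The double-log binding model
$$\log\frac{F_0-F}{F} = n \log K_a -
  n \log\frac{1}{[L] - \frac{F_0-F}{F_0}[P]}$$
is fitted as written: one pass, base-10 logs, the bound-ligand correction
$([F_0-F]/F_0)[P]$ subtracted without iteration. Points whose log
arguments are non-positive are dropped with a warning, and at least four
usable points are required.

## Van't Hoff thermodynamics

`vantHoffFit()` regresses $\ln K_a$ on $1/T$ (unweighted by default; the
inputs rarely come with usable weights, though $1/SE^2$ weighting is
available), giving $\Delta H = -R\,\mathrm{slope}$ and
$\Delta S = R\,\mathrm{intercept}$ under the usual
temperature-independent-enthalpy assumption; $R = 8.314$ J/(mol K),
temperatures in Kelvin only. $\Delta G$ is reported both per temperature
as $-RT\ln K_a$ and from the regression as $\Delta H - T\Delta S$; the two
differ by the regression residual, and showing both makes that residual
visible. Units follow the conventional table layout: $\Delta H$ and
$T\Delta S$ in kJ/mol, $\Delta S$ in J/(mol K).

## The interaction density function

IDF is model-free: if titrations at several total protein concentrations
reach the *same* quench percentage
$\Delta F = |F_{obs}-F_{free}|/F_{free}\cdot 100$, those solutions share
the same free ligand concentration and binding density, so the
mass-conservation line
$$[L]_{total} = [L]_{free} + \Big(\sum\nu_i\Big)[P]$$
fitted across protein concentrations at each level yields $\sum\nu_i$
(slope) and $[L]_{free}$ (intercept) with no binding model assumed.

Choices a user should know about:

* **Levels.** 20 evenly spaced $\Delta F$ cuts inside the intersection of
  the series' ranges, trimmed by a 2% margin at each end; both count and
  placement are configurable, since there is no canonical choice.
* **Inversion.** Each series' $\Delta F$ curve is inverted against
  $\log_{10}[L]_{total}$ by monotone piecewise-linear interpolation —
  titration ladders act geometrically, so log-spacing is the natural
  abscissa.
* **Monotonicity.** The inversion needs a monotone $\Delta F$ ladder.
  Measurement noise always produces small decreases near saturation, so
  decreases up to 5% of the series' $\Delta F$ range (the `monotoneTol`
  argument) are pooled away by isotonic regression; anything larger
  aborts with an error naming the series, because it indicates a corrupt
  titration rather than noise.
* **Level rejection.** A negative intercept (free ligand cannot be
  negative) or $r^2 < 0.95$ discards the level, with a message.
* **Signal.** Area mode (305–400 nm) by default, consistent with the
  quenching module; intensity at 340 nm available.

The accepted levels form a binding density curve. `scatchard()` transforms
it to $(\sum\nu, \sum\nu/[L]_{free})$: monotone decline means independent
identical sites; a rise to an interior maximum followed by decline is
positive cooperativity. The verdict tolerates jitter below 0.5% of the
largest transformed value, because level interpolation leaves small
non-monotonic wiggles even on noiseless input.

`hillFit()` then fits
$$\sum\nu = \sum_j \frac{n_j (k_j [L]_{free})^{w_j}}
  {1 + (k_j [L]_{free})^{w_j}},$$
with $n_j$ fixed at 1 per class by default ($w_j$ is then an *affinity
index* — it measures the steepness of each class's occupancy rise, and is
not bounded by the site count; a `"free"` policy fits $n_j$ too for
exploration). The fit is Levenberg-Marquardt in $\log k_j, \log w_j$ from
a deterministic multi-start grid ($k$ decade-spaced over the range
bracketing $1/[L]_{free}$, $w \in \{0.5, 1, 2, 4, 8\}$), so repeated runs
give identical answers. The number of classes is scanned from 1 to
`maxClasses` and selected by the corrected Akaike criterion (counting the
residual variance as a parameter), with ties broken toward fewer classes.

## Time-resolved decays and CD

`fitDecay()` fits $I(t) = \sum_i \alpha_i e^{-t/\tau_i}$ (one or two
components; more is an error, not a silent extension) by weighted least
squares with Poisson-motivated weights $1/\max(\mathrm{counts},1)$,
starting at the peak channel — tail fitting without instrument-response
deconvolution, which is adequate at multi-nanosecond lifetimes.
Initialisation is deterministic from log-linear tail slopes. Amplitudes
are reported normalised to sum 1, and `averageLifetime()` returns the
intensity-weighted mean $\sum\alpha_i\tau_i^2/\sum\alpha_i\tau_i$.

`meanResidueEllipticity()` converts raw ellipticity by
$[\theta] = \theta / (10\,[P]\,l\,n)$ with $[P]$ in mol/L and $l$ in cm —
the convention that yields deg cm$^2$ dmol$^{-1}$ — and `bandMinima()`
reports negative local minima (208/222 nm for helical proteins). The
concentration enters as an explicit argument because CD runs are often
made at concentrations not recorded alongside the spectra.

## The synthetic-data generator

`simulateTitration()` produces ground-truthed input for every stage. Its
defaults are the study design the package is validated against: ladder
0–32 µM in 2 µM steps; protein 2, 4 and 8 µM; 288 K; excitation 295 nm on
a 305–500 nm, 1-nm grid; lifetime 6.71 ns. The forward model is

1. exact mass conservation, solved to a relative residual below
   $10^{-12}$ (`solveFreeLigand()`; bracketed root plus Newton polish);
2. occupancy from a two-class cooperative model with
   $k = 2.3\times10^5, 1.3\times10^5\ \mathrm{M^{-1}}$ and
   $w = 2.93, 8.15$, one site per class;
3. static quenching as a wavelength-independent factor
   $1 - q_e \sum\nu / \sum n_j$ with quench efficiency $q_e = 0.4$,
   chosen so the maximum $F_0/F$ reaches about 1.7 — the depth typical of
   a moderate-affinity albumin ligand at these concentrations. This
   occupancy-to-quench mapping is a simulator convention, the simplest
   single-channel static model, and is what makes intensity- and
   area-mode analyses agree exactly (itself a tested property);
4. observation through the inverse inner-filter factor, with a ligand
   absorbance band (split Gaussian, peak 326 nm, blue width 22 nm, red
   width 34 nm, $\varepsilon = 18700\ \mathrm{M^{-1}cm^{-1}}$) whose red
   tail overlaps the emission band asymmetrically — widths chosen so the
   apparent red shift of the observed maximum reaches several nanometres
   at the top of the ladder while the hidden true peak stays at 340 nm;
5. optional additive Gaussian noise, specified relative to the
   zero-ligand peak and clamped at zero counts.

The emission band is a log-normal (peak 340 nm, FWHM 60 nm, mild red
asymmetry 0.1), the natural shape for a tryptophan band. Because the
observation model is exactly the inverse of the correction formula,
correcting the noiseless observed spectra with the generator's own
absorbances reproduces the hidden truth to round-off — the identity that
closes the loop between the spectra and simulator modules.

What the generator does *not* emulate: detector nonlinearity, Raman and
Rayleigh scatter, photobleaching, wavelength-dependent quenching,
instrument response functions, and ligand fluorescence. Passing tests on
generated data therefore demonstrate the correctness of the estimators
under the stated model, not robustness to every artefact of real
instruments.

```{r example}
sim <- simulateTitration(groundTruth())
corrected <- lapply(sim$observed, correctTitration)
levels <- matchLevels(corrected, nLevels = 20)
fit <- hillFit(bindingDensityCurve(levels), maxClasses = 3)
fit
```

## Problem sizes and determinism

The validation suite runs the full titration design (three proteins, 17
steps, 196 wavelengths) in well under a second; the noisy-recovery study
uses 100 generator seeds at 1% relative noise, a size at which the median
recovery error of the Hill parameters is stable to re-seeding. All
randomness flows from the single integer seed in the ground-truth record;
noiseless runs are seed-independent by construction.

## Known limitations

* The double-log model is first-order by construction; its $K_a$ is an
  effective constant and disagrees with the site-resolved IDF constants
  by design, not by error.
* IDF needs overlapping quench ranges across protein concentrations;
  designs whose ranges barely overlap yield few usable levels.
* Hill-model standard errors come from the local curvature at the
  optimum; for strongly cooperative classes ($w \gtrsim 8$) they are
  optimistic. No bootstrap is provided.
* The Stern-Volmer fit assumes the corrected ratios are linear in ligand;
  upward curvature (combined static and dynamic quenching) is reported
  only through poor $r^2$, not modelled.
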