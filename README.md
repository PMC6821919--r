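# quenchfit

Fluorescence quenching titration analysis of protein–ligand binding, for
spectroscopists characterising how a small molecule (a drug candidate, a
natural product) binds a protein such as serum albumin. The package covers
the full steady-state workflow — whole-spectrum inner-filter-effect
correction, Stern–Volmer and double-log quenching analysis in intensity
and band-area modes, Van't Hoff thermodynamics — plus the model-free
**interaction density function (IDF)** route to cooperative multi-site
binding, time-resolved (TCSPC) decay fitting, and circular dichroism unit
conversion. A ground-truthed synthetic titration generator backs every
estimator with recoverable simulations.

## The models

Observed fluorescence through an absorbing sample is attenuated by the
inner filter effect; it is corrected at every emission wavelength by

$$F_{corr}(\lambda) = F_{obs}(\lambda)\cdot 10^{(A_{ex}+A(\lambda))/2},$$

which also removes the spurious red shift of the band maximum that an
asymmetrically overlapping ligand absorbance produces. Quenching is
quantified by $F_0/F = 1 + K_{SV}[L]$ (intensity at 340 nm or band area
over 305–400 nm), with $k_q = K_{SV}/\tau_0$ diagnosing the mechanism,
and by the double-log binding model giving $K_a$ and $n$. Binding
constants across temperatures decompose through the Van't Hoff relation
$\ln K_a = -\Delta H/RT + \Delta S/R$.

The IDF method matches equal-quench points across titrations at several
protein concentrations; the mass-conservation line
$[L]_{total} = [L]_{free} + (\sum\nu_i)[P]$ at each quench level yields
binding density and free ligand with no model assumed. Scatchard
convexity then diagnoses cooperativity, and the multi-class Hill model

$$\sum\nu = \sum_j \frac{n_j\,(k_j[L]_{free})^{w_j}}{1+(k_j[L]_{free})^{w_j}}$$

is fitted with information-criterion selection of the number of site
classes.

## Worked example

Simulate the standard study design (protein 2/4/8 µM, ligand 0–32 µM in
2 µM steps, 288 K, two cooperative site classes as ground truth), correct
the inner filter effect, and run the analyses:

```r
library(quenchfit)

sim       <- simulateTitration(groundTruth())
corrected <- lapply(sim$observed, correctTitration)

## Stern-Volmer on the 4 uM series, band-area mode
sternVolmerFit(buildCurve(corrected[["P_4e-06"]], mode = "area"),
               tau0 = 6.71e-9)
#> Stern-Volmer fit (area mode, T = 288 K)
#>   Ksv = 2.541e+04 +/- 1e+03 1/M (r2 = 0.9740)
#>   kq  = 3.788e+12 1/(M s) with tau0 = 6.71e-09 s
```

The fitted $K_{SV}$ is an effective Stern–Volmer constant for the
cooperative ground truth (the curve is not exactly linear, hence
$r^2 < 1$), and $k_q \sim 10^{12}\,\mathrm{M^{-1}s^{-1}}$ — far above the
diffusion limit of $10^{10}$, the signature of static quenching.

```r
## Van't Hoff decomposition of binding constants measured at 288/298/308 K
vantHoffFit(c(288, 298, 308), c(1.72e4, 2.24e4, 2.54e4))
#> Van't Hoff decomposition
#>   deltaH = 14.43 +/- 2.67 kJ/mol
#>   deltaS = 131.34 +/- 8.96 J/(mol K)   (r2 = 0.9669)
#>  T_K deltaG_kJmol deltaG_direct_kJmol TdeltaS_kJmol
#>  288       -23.40              -23.35         37.83
#>  298       -24.71              -24.82         39.14
#>  308       -26.03              -25.97         40.45
```

Binding is spontaneous ($\Delta G < 0$) and entropy-driven
($T\Delta S \gg \Delta H > 0$), pointing to hydrophobic contacts.

```r
## IDF -> Scatchard -> Hill across the three protein concentrations
levels <- matchLevels(corrected, nLevels = 20)
curve  <- bindingDensityCurve(levels)
scatchard(curve)
#> Scatchard transform: 20 points, verdict: positive-cooperative
hillFit(curve, maxClasses = 3)
#> Hill model: 2 site class(es), RSS = 0.00857, AICc = -140.82
#>   class 1: n = 1, k = 2.36e+05 +/- 4.1e+03 1/M, w = 2.672 +/- 0.154
#>   class 2: n = 1, k = 1.31e+05 +/- 1.6e+03 1/M, w = 7.400 +/- 0.300
```

The pipeline recovers the generator's two cooperative classes
($k = 2.3\times10^5$ and $1.3\times10^5\ \mathrm{M^{-1}}$) within a few
percent, with affinity indices $w > 1$ confirming positive cooperativity.

Orchestrated runs over files — `runQuenching()`, `runThermo()`,
`runIDF()` — take a validated configuration list (or YAML file), write
delimited tables and JSON summaries with a provenance block, and return
the same objects as the direct calls above.

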