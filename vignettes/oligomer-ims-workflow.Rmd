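---
title: "Oligomer order, distribution and shape from native ESI-IM-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligomer order, distribution and shape from native ESI-IM-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoIMS)
```

This vignette is the package's account of its science: the models it fits,
the parameters that matter, what the synthetic-data generator does and does
not emulate, the numerical choices, and the limits of what passing tests
demonstrate.

## The measurement problem

A low-molecular-weight amyloid-β preparation is a dynamic mixture of
monomers (M) and low-order oligomers (dimers D through hexamers Hx).
Electrosprayed natively, each n-mer appears at several charge states z, at

$$ m/z = \frac{n\,M - 2\,b\,m_{\mathrm H} + z\,m_{\mathrm{H^+}}}{z}, $$

where $b$ is the number of covalent cross-links (photo-induced
cross-linking removes two hydrogen atoms per bond formed; $b = 0$ for
non-covalent assemblies). Ions with equal $n/z$ are *degenerate*: M+2, D+4,
Tr+6 and Te+8 of one peptide co-locate within 1 Th on the average-mass
basis. Disentangling them is the whole game, and the package follows the
two-rule discipline used in careful native-MS work on Aβ:

1. **Isotope spacing.** Adjacent isotopologues sit $1.003355/z$ Th apart
   (the ¹³C–¹²C mass difference over the charge). A resolvable spacing
   fixes $z$, and with it the species among the candidates at that m/z.
2. **Consecutive charge states.** Where resolution fails, a species is
   accepted only if ions of at least two consecutive charge states of that
   species match within tolerance somewhere in the spectrum. A species seen
   at a single charge state with no spacing is left unassigned.

When several *distinct* species remain compatible with one channel, no
amount of m/z evidence can split them; the pipeline demands mobility
evidence (below) and otherwise excludes the channel from the population
statistic, reporting the excluded intensity.

## Mobilogram model

Each ambiguous channel's drift-time projection is fitted to

$$ f_{\mathrm{im}}(x) = k_{\mathrm{im}} + \sum_{N} g(x_{c,N}, w_N, A_N), \qquad
   g(x) = A\,\frac{2\sqrt{\ln 2/\pi}}{w}\, e^{-4\ln 2\,(x - x_c)^2/w^2}, $$

a constant baseline plus Gaussians parameterised by centre $x_c$ (ms), full
width at half height $w$ (ms) and area $A$ (counts·ms). The FWHM–area form
is chosen so the three named parameters are exactly the centre, the width
at half-height and the area; the integral of $g$ is $A$ by construction.
The relative contribution of component $i$ to its channel is $A_i/\sum A$,
and a species' population is its fraction-weighted intensity summed over
all charge states, divided by the total intensity of all assigned charge
states in the spectrum. Both statistics are scale-invariant: intensity
units are arbitrary counts, only ratios propagate.

Component *labels* (which mobility peak is which species) cannot come from
the fit itself. On the instrument they come from the m/z spectrum associated
with each mobility peak, whose isotope spacing reveals the charge. The
package mirrors this: a mobilogram file may carry a `# labels:` header
giving the species of each component in drift-time order, and the pipeline
maps fitted components (sorted by centre) onto those labels. The synthetic
generator writes those labels from its ground truth, standing in for the
per-peak isotope evidence.

### Fitting choices

* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), with
  non-negativity on baseline, widths and areas. The convergence flag is the
  optimizer's own criterion, and a refit from the returned solution must not
  improve the optimum; non-convergence is returned, never hidden.
* **Initialization.** Deterministic greedy residual subtraction: place a
  component at the maximum of the lightly smoothed residual, subtract it,
  repeat. This finds shoulder peaks that are not local maxima and breaks
  ties toward earlier drift times, so runs are reproducible.
* **Minimum width.** Component FWHM is bounded below by the larger of two
  samples and 1% of the axis span. Mobility peaks are instrument-broadened;
  without the bound, sub-sample Gaussians chase single noisy points and
  corrupt model selection.
* **Component count.** When not fixed by the caller, N is chosen by minimum
  corrected AIC over 1..4, restricted to *admissible* fits: converged, and
  every component's apex at least three residual standard deviations above
  zero. The admissibility screen exists because with several hundred
  samples AICc alone under-penalises a noise-chasing extra component. On
  generated suites with N ∈ {1..4} at signal-to-noise 50 this selects the
  generating N in ≥ 90% of cases.
* **Data support.** A fit of N components (3N+1 parameters) requires at
  least 4 data points per free parameter, otherwise it is rejected rather
  than attempted.
* **Line widths.** Group comparisons of fitted w (e.g. non-covalent vs
  cross-linked oligomers, whose frozen conformational ensemble narrows the
  peak) use the unpaired two-tailed Student's t-test, matching the
  replicate structure of the experiments the pipeline emulates.

## Population statistics

Populations from a single acquisition are exact ratios; uncertainty comes
from independent replicate acquisitions (the emulated protocol averages
three). Replicates are summarised as mean ± sample s.d., and two samples
are compared per species by unpaired two-tailed t-tests. Raw p-values are
reported alongside Holm-adjusted ones — the emulated protocol reports raw
t-tests, but with six species a family-wise guard is cheap honesty.
Channels whose contributors cannot be established are excluded from both
numerator and denominator, and their summed intensity is carried in the
report; whether such intensity belongs in the denominator is genuinely
ambiguous, so the choice is explicit and logged rather than silent.

## Drift-time → CCS calibration

Traveling-wave drift times have no first-principles inversion; the package
follows the calibrant-protein protocol. Measured drift times are corrected
for the mass-dependent transit delay, $t_d' = t_d - c\sqrt{m/z}/1000$ (the
EDC delay coefficient $c$ is an instrument setting, default 1.41;
mass-independent offsets are absorbed by the fit). Reference cross-sections
of denatured calibrants are normalised as
$\Omega' = \Omega_{\mathrm{ref}}/(z\sqrt{1/\mu})$, with $\mu$ the ion–gas
reduced mass, and $\ln\Omega'$ is regressed on $\ln t_d'$ to give
$\Omega' = A\,t_d'^{\,X}$. Unknowns are inverted through the same
normalisation — but only inside the calibrant $t_d'$ range: extrapolated
CCS values are refused, since reported values must interpolate the
calibration curve.

The shipped table enumerates the protocol's 19 calibrant ions (ubiquitin
+9..+11, myoglobin +15..+22, cytochrome c +11..+18). Its reference Ω values
are literature-derived defaults at literature scale, flagged as replaceable:
reference tables differ by drift gas and source, so the table is data, not
physics. The drift gas (default N₂, 28.0134 Da; He 4.0026 configurable) is
part of the calibration record. Wave-height replicates are treated as
independent calibrations whose Ω estimates are averaged with s.d.

## Theoretical CCS from coordinates

Two hard-sphere estimators over atoms inflated by a probe radius:

* **Projection approximation (PA):** the orientation-averaged shadow area,
  estimated by Monte Carlo — uniform random rotations (quaternion method),
  impact points uniform on a bounding disk. A lower bound on the true
  momentum-transfer cross-section.
* **Exact hard-sphere scattering (EHSS):** trajectories reflect specularly
  off the spheres (nearest positive ray–sphere intersection, exit when
  none), and each contributes $1 - \cos\chi$ with $\chi$ the total
  deflection. For a convex body EHSS equals PA (for a single sphere, both
  equal $\pi (r + r_g)^2$ analytically); concave bodies re-scatter and EHSS
  exceeds PA.

Atom radii default to Bondi van der Waals values by element and the probe
radius defaults to 1.0 Å (helium-probe scale); both are configurable and
recorded, because published hard-sphere parameterisations differ and
model-vs-experiment comparisons should be read as rankings, not absolute
matches. Seeds are mandatory in every record; standard errors come from the
spread across orientations and scale as $1/\sqrt{n}$. Trajectories
exceeding the bounce cap (default 30) are counted with their accumulated
deflection and tallied. Building the structural models themselves
(molecular dynamics, replica exchange) is out of scope: the module consumes
coordinates from any source.

## The synthetic instrument

The generator produces every input with recorded ground truth and is
deterministic given its seed:

* **Spectra.** For each (species, charge) with positive weight, an
  isotopologue cluster from the exact aggregated isotope distribution,
  each isotopologue a Gaussian of FWHM $m/z / R$, cluster integral
  proportional to the pair's weight; additive white noise. Defaults:
  resolving power R = 10000 (quadrupole-TOF class, resolving z ≤ 3 combs
  and the z = 5 comb near 1732 marginally, as on the emulated instrument),
  acquisition window m/z 500–5000, noise s.d. 0.1% of the base peak (an
  averaged 2-minute acquisition; the weakest hexamer channel then sits at
  ~7× noise, i.e. near but above detection — deliberately, since hexamers
  are near the detection limit in the emulated experiments).
* **Ground truth.** The default distribution (M 0.45, D 0.30, Tr 0.15,
  Te 0.07, P 0.02, Hx 0.01) is monomer-dominated with dimers and trimers
  dominating among oligomers, mirroring the qualitative finding the
  pipeline exists to detect without encoding any figure's exact values.
  Charge-state weights deliberately place M+2/D+4/Tr+6/Te+8 on the shared
  2166 channel and give every species a second charge state so the
  consecutive-charge-state rule is exercised.
* **Mobilograms.** Emitted for every channel that the downstream grid
  flags as ambiguous, with components at a smooth drift-time law
  ($x_c = 1 + 40\sqrt{n}/z$ ms, FWHM 0.9 ms), areas proportional to the
  true contributions, 1% (of channel apex) noise, and truth labels in
  drift order.
* **Calibrants.** Drift times generated by inverting the power law
  (A = 450, X = 0.55, c = 1.41 defaults), multiplicative noise on $t_d$.
* **Toy clouds.** A single sphere (analytic Ω), a near-convex shell
  (EHSS ≈ PA), and a concave two-lobe dumbbell (EHSS > PA).

What the generator does *not* emulate: ionisation-efficiency differences
across oligomer orders (populations are read as intensity fractions, a
known caveat of native MS), detector saturation, transmission profiles,
wave-height physics, chemical noise and background peptides, and spectral
drift. Passing recovery tests therefore demonstrates that the estimators
invert the stated forward model faithfully — not that real instrument data
are free of these further effects.

## Tolerances and numerical safeguards

* Assignment tolerance is 20 ppm for exact peak lists (Q-TOF-class
  accuracy). The profile pipeline defaults to 40 ppm because integrated
  envelope centroids of unresolved kDa clusters carry window bias of
  10–30 ppm that exact stick positions do not; observed m/z is matched
  against the nearer of the monoisotopic and average positions, since a
  resolved cluster is reported near its monoisotopic peak and an unresolved
  one near its envelope centroid.
* A measured spacing implying a charge more than 15% from an integer is
  treated as unmeasurable rather than rounded.
* Cross-linked n-mers default to n−1 bonds (minimally connected topology),
  configurable, since only the per-bond mass rule is physically fixed.
* Centroiding thresholds are noise-aware (multiples of the trace's median
  absolute deviation) with a floor as a fraction of the base peak; cluster
  grouping uses a 10 Th gap, above the span of one isotopologue envelope
  and far below the spacing of adjacent oligomer channels.
* Parsimony tie-break: when several candidates match and no spacing is
  available, the lowest oligomer order is accepted and recorded — the
  conservative reading of a degenerate channel.
* Isotope patterns use exact element-wise convolution (exponentiation by
  squaring) with a 10⁻⁴ relative-abundance floor; spacings are exact by
  construction.

## Problem sizes

The test suite and the analysis scripts run on deliberately modest sizes
chosen to exercise every code path with comfortable statistical margins:
profile spectra of ~2×10⁵ points, three replicate acquisitions per sample,
50-seed parameter-recovery loops, Monte Carlo CCS with 16–64 orientations
and a few thousand rays, and 1000-trial type-I simulations. All are the
package's own choices of demonstration scale; every routine accepts larger
inputs.

## Known limitations

* Populations are intensity fractions; absolute concentrations would need
  ionisation-efficiency calibration the emulated protocol does not provide.
* The Gaussian component model does not cover tailing or fronting peaks,
  and baselines are constant per mobilogram by construction of the model.
* Widths are fitted independently per replicate; replicate-shared-width
  fitting would be a natural extension.
* PA/EHSS are hard-sphere methods; long-range ion–neutral interactions
  (trajectory-method CCS) are out of scope, another reason model
  comparisons are rankings.
* Negative-ion mode is a sign convention the package does not model
  explicitly.
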