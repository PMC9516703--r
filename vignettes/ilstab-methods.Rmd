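---
title: "Melt thermodynamics and preferential interaction analysis with ilstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melt thermodynamics and preferential interaction analysis with ilstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilstab)
```

## The problem

Biologic formulations — here an IgG4 antibody in water and in aqueous
choline chloride ([Cho]Cl) at 10, 30 and 50 wt % — must stay folded and
monomeric over long storage. `ilstab` implements a screening strategy that
quantifies thermodynamic stability and aggregation propensity from
variable-temperature circular dichroism (CD) melts, and complements it with
toy-scale trajectory analysis of how the ions distribute around the
protein. Every stage is paired with a synthetic generator with known ground
truth, so the whole pipeline is testable without instrument or simulation
data.

## From ellipticity to free energy

A melt experiment records ellipticity over a temperature-by-wavelength
grid (typically 25-97 °C in 2 °C steps over 200-260 nm). `compute_mre()`
applies the standard conversion to mean residue ellipticity,

$$\mathrm{MRE} = \frac{\theta_\mathrm{mdeg}\,\cdot\,\mathrm{MRW}}
{10\,\cdot\,l_\mathrm{cm}\,\cdot\,c_\mathrm{mg/mL}},$$

which requires the mean residue weight, path length and protein
concentration in the sample metadata — there are no silent defaults for
the MRW. The β-sheet band near 218 nm is then extracted
(`extract_trace()`; ties between equally near grid wavelengths break
toward the lower wavelength) and normalised to a fractional β-sheet
content between two anchors: the minimum-magnitude signal $y_0$ (fraction
0) and the strongest negative-band signal $y_\mathrm{max}$ (fraction 1),

$$f = \frac{y - y_0}{y_\mathrm{max} - y_0}.$$

Under a two-state (initial/final ensemble) model the equilibrium constant
and free energy follow as

$$K = \frac{f}{1-f}, \qquad
\Delta G = -RT\ln K, \quad R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}},$$

with $T$ in kelvin and $\Delta G$ reported in kJ/mol. Fractions are
clipped to $[10^{-6}, 1-10^{-6}]$ so the logarithm stays finite; clipped
points are excluded from all downstream fits.

## Segmenting multi-transition melts

Real melts show two (fresh samples) or three (some stored samples)
sigmoidal transitions. `segment_transitions()` fits sums of
$k = 1 \ldots 3$ logistic components to $f(T)$ by nonlinear least squares
(`minpack.lm::nls.lm`) from a fixed, deterministic grid of starting
centers (the 15/30/50/70/85 % temperature quantiles, all $k$-subsets), and
selects $k$ by the small-sample-corrected Akaike criterion (AICc). Two
identifiability guards matter in practice:

* a candidate $k$ is discarded when its best fit contains a component
  with amplitude below 2 % of the data range or two centers closer than
  5 °C — such components are not resolvable transitions on a 2 °C grid;
* the RSS entering the AICc is floored at $10^{-3}$ of the data range per
  point. Without the floor, noiseless model data (RSS $\to 0$) always
  selects the largest $k$, because the log-likelihood of an exact fit is
  unbounded.

The trace is split at midpoints between adjacent fitted centers. Within
each region the fraction is renormalised so the local fraction runs 0 to 1
across that transition. We anchor this renormalisation on the
*component-isolated* signal — subtract the fitted baseline and the other
components, then normalise between the isolated signal's extrema over the
full grid — rather than on the raw extrema inside the region window. Raw
within-region extrema are truncated wherever transitions overlap, which we
measured to bias recovered midpoints by more than 1 °C for transitions
14 °C apart; isolation reduces that bias below 0.2 °C while leaving the
single-transition case numerically unchanged.

## Transition thermodynamics

Within a transition, two-state theory makes $\Delta G(T)$ exactly linear:
for data generated by a van't Hoff transition with parameters
$(T_m, \Delta H)$,
$\Delta G = \Delta H (1 - T_K / T_{m,K})$. `fit_transition()` performs
ordinary least squares of $\Delta G$ (kJ/mol) on $T$ (°C) restricted to
the window $|\Delta G| < 5$ kJ/mol, and reports

* $T_m$: the zero crossing of the fitted line (equal populations),
* $\Delta S = -\mathrm{slope} \times 1000$ (J K$^{-1}$ mol$^{-1}$),
* $\Delta H$: **Celsius-axis convention** $T_m(°\mathrm{C}) \cdot \Delta S$,
  reported in kJ/mol, with the thermodynamically standard Kelvin product
  stored alongside as `dH_kelvin`.

The Celsius convention is deliberate: published melt tables for this
system satisfy $T_m(°\mathrm{C}) \cdot \Delta S \approx \Delta H$ on every
row (e.g. $69.8 \times 1.370 \approx 96$), whereas the Kelvin product does
not. To compare like with like, the package's primary outputs follow that
convention, clearly labelled, and both values are always available. Note
the consequence: the *generative* van't Hoff enthalpy of a transition
equals $T_{m,K} \cdot \Delta S$, so Celsius-convention $\Delta H$ values
are smaller than the van't Hoff enthalpies by the factor
$T_m(°\mathrm{C}) / T_{m,K}$.

Two $T_m$ estimates exist per transition — the $\Delta G$-line zero
crossing (primary) and the logistic center from segmentation (stored as
`center` on each region). They agree to well under 1 °C on clean two-state
data; the noisier $\Delta G$-line estimate uses only the window points, so
on noisy data the center is often tighter.

## The free-energy landscape and the aggregation flag

Over the full temperature range $\Delta G(T)$ traces a well: stability
rises, dips to a minimum and recovers. `fit_gaussian_landscape()` fits

$$\Delta G(T) = \mathrm{offset} - A\,
e^{-(T - T_c)^2 / 2\sigma^2},$$

with deterministic initialisation (center at the data extremum, amplitude
from the range, $\sigma$ a quarter of the span). The well depth
$\Delta G_\mathrm{min} = \mathrm{offset} - A$ is the stability metric;
width is reported as FWHM ($2\sqrt{2\ln 2}\,\sigma$) and area as the
closed-form integral $A\sigma\sqrt{2\pi}$ — both fixed definitions so that
fresh/stored comparisons are internally consistent.

Deviation from Gaussian behaviour at high temperature — an extra sigmoid
above ~80 °C — marks enhanced aggregation propensity.
`detect_deviation()` flags it when a run of ≥ 3 consecutive, same-signed
standardized residuals exceeds 2 within the upper temperature quartile
(onset = first such temperature), or when the RSS exceeds twice a supplied
reference. Residuals are standardized by the residual SD of the *lower*
75 % of temperatures so the deviation region cannot inflate its own
yardstick; a floor of $10^{-8}$ of the data range prevents flagging
numerically exact fits. The same-sign run requirement keeps the
false-positive rate at 2 % instrument noise effectively zero
(per-start probability $\approx 2 \times 0.023^3$) while a genuine third
sigmoid is detected with probability 1 in our simulations.

`compare_fresh_stored()` reports percentage changes relative to the fresh
sample; for $\Delta G_\mathrm{min}$ the change is on the magnitude, so a
deeper (more negative, more stable) stored well gives a positive
percentage. `rank_stability()` orders formulations: non-deviating before
deviating, then deeper $\Delta G_\mathrm{min}$, then higher final $T_m$,
then sample id.

## Synthetic melts

`melt_spec()`/`generate_melt()` build melts from van't Hoff populations

$$f_i(T) = \frac{1}{1 + \exp\!\big[\tfrac{\Delta H_i}{R}
(\tfrac{1}{T_K} - \tfrac{1}{T_{m,i,K}})\big]}, \qquad
y(T) = \mathrm{baseline} + \textstyle\sum_i s_i A_i f_i(T) +
\mathcal{N}(0, \sigma_\mathrm{noise}),$$

with a per-spec seed (bit-identical reruns; the global RNG stream is left
untouched). Opposite signs on successive amplitudes emulate the observed
band deepening followed by loss of structure, which is what produces the
peak in $f_\beta(T)$ and the well in $\Delta G(T)$.

Defaults are fixed at the measured conditions of the concentrated-IL
formulation: grid 25–97 °C step 2; baseline −3000 deg cm² dmol⁻¹ with
amplitudes 4000/−3000 (the observed initial MRE and the 3000–4500 absolute
MRE change); transitions at 69.2 and 82.9 °C with van't Hoff enthalpies
370 and 590 kJ/mol — the Kelvin products $T_{m,K}\Delta S$ of the measured
transition entropies (1080 and 1650 J K⁻¹ mol⁻¹). Noise is homoscedastic
Gaussian; no instrument noise model beyond that is assumed. What the
generator does *not* emulate: baseline drift, temperature-dependent
amplitudes, heat-capacity effects, smoothing artefacts — so passing
recovery tests demonstrate correctness of the estimator chain, not
robustness to every instrument pathology.

## Toy trajectories and preferential interaction

`trajectory_spec()`/`generate_trajectory()` place a rigid 8-bead solute at
the center of a periodic orthorhombic box (default 60 Å cube) with
point-bead cation/anion/water molecules re-placed each frame: uniformly,
except that acceptance inside a spherical shell (default 4–9 Å minimum
distance from the solute) is multiplied by a per-species enrichment
factor. The generator also exposes `gamma_direct_count()`, a deliberately
plain counting loop that serves as the oracle the vectorised pipeline is
tested against, frame by frame.

`gamma_species()` computes, per frame,

$$\Gamma_s = n_s(\le R) - \frac{N_s^\mathrm{bulk}}{N_w^\mathrm{bulk}}\,
n_w(\le R),$$

where $n(\le R)$ counts molecules whose any-atom minimum-image distance to
the solute is within the cutoff (default $R = 12$ Å) and bulk counts come
from beyond $R$ — estimating bulk ratios per frame keeps small boxes
usable. The standard error uses block averaging (5 blocks). For an ionic
co-solute, `combine_ion_gammas()` merges the separately computed cation
and anion values; the default charge-corrected mean
$(\Gamma_+ + \Gamma_-)/2 - Z_2/2$ (protein net charge $Z_2$, here +22 e at
the formulation pH) is one convention among the selectable forms
(`sum`, `mean`) because the combining equation's exact printed form is a
convention in the indistinguishable-ion literature; no form is presented
as canonical. Negative $\Gamma_{23}$ means preferential exclusion —
protectant-like behaviour — and a three-level loading design with
surface-excluded ions yields monotonically decreasing $\Gamma_{23}$, the
direction observed experimentally with increasing [Cho]Cl.

`mddf()` histograms per-molecule minimum distances and normalises each
shell by the uniform-placement expectation. Because min-distance shells
around a bead cluster are not spherical, their volumes are estimated by a
fixed-seed Monte Carlo integration (2×10⁵ points); the bulk density comes
from the outer 25 % of the histogram range. `superpose_rmsd()`/`rmsf()`
use the Kabsch (SVD) superposition with the proper-rotation determinant
correction; `domain_distances()` classifies Y- versus λ-shaped antibody
conformers from Fab/Fc center-of-mass geometry — a frame is λ-like when
$\min(d_{\mathrm{Fab1-Fc}}, d_{\mathrm{Fab2-Fc}}) < 0.75\,
d_{\mathrm{Fab1-Fab2}}$, and the trajectory label needs 60 % of frames
(λ) or 40 % (Y); these thresholds are package conventions, as published
conformer preferences are qualitative.

## Numerical choices and degenerate inputs

* Fraction clip $\varepsilon = 10^{-6}$; clipped points never enter
  transition-window fits.
* Transition window $|\Delta G| < 5$ kJ/mol, at least 3 points; a
  non-negative fitted slope returns a result with a
  non-cooperative-transition warning.
* Gaussian fits on constant traces return a degenerate flag (amplitude
  below $10^{-9}$ of the range) instead of a spurious well.
* Nearest-wavelength ties break toward the lower wavelength.
* Orthorhombic boxes and minimum-image distances only; `mddf()` refuses
  `r_max` beyond half the smallest box edge, and `gamma_species()` errors
  when no water remains beyond the cutoff.
* The molarity helper assumes full dissociation and unit density by
  default; the density is an argument because printed low-concentration
  ionic strengths are not always consistent with unit density (at 10 wt %
  the rule gives 0.72 M, not the published 0.76 M) — no attempt is made to
  force agreement there.

## Problem sizes used in the test and acceptance suites

Synthetic melts use the 37-point acquisition grid; noisy recovery studies
use 50 seeded replicates at 2 % noise; deviation-flag calibration uses 100
seeds per arm; toy trajectories use 8–20 frames of ~1000 beads in a 60 Å
box. These sizes give Monte Carlo errors comfortably inside the asserted
bounds while keeping a full run to about a minute.

## Known limitations

Two-state, equilibrium analysis only: no three-state or kinetic models, no
ΔCp correction, no global multi-wavelength fitting. The landscape fit
describes, it does not explain — deviation flags indicate aggregation
propensity but carry no mechanism. Toy trajectories have no physical
solvent structure, no internal solute dynamics and no force field; they
exist to validate the counting estimators, and published
preferential-interaction values from full-scale simulations are explicitly
out of reach at this scale.
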