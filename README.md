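# ilstab

Quantify and predict protein thermodynamic stability and aggregation
propensity in ionic-liquid co-solute formulations, from
variable-temperature circular dichroism (CD) melts and toy-scale
trajectory analysis.

Biologics such as IgG4 antibodies are screened in aqueous choline
chloride ([Cho]Cl) formulations by heating them (typically 25–97 °C) and
following the β-sheet CD band near 218 nm. `ilstab` turns those melts
into thermodynamic quantities under the two-state model

```
f = (y − y0)/(ymax − y0),   K = f/(1 − f),   ΔG = −RT ln K,
```

where `y` is the CD signal, `y0` the minimum-magnitude signal and `ymax`
the strongest negative-band signal. Each sigmoidal transition gets a
melting temperature `Tm` (zero crossing of the linear `ΔG(T)` fit in the
`|ΔG| < 5 kJ/mol` window), an entropy `ΔS = −slope` and an enthalpy
`ΔH = Tm·ΔS`. The full-range `ΔG(T)` is fitted to an inverted Gaussian
whose minimum `ΔG_min` ranks formulation stability, and deviation from
Gaussian behaviour at high temperature flags aggregation propensity.
On the trajectory side, the package computes minimum-distance
distribution functions, preferential interaction coefficients

```
Γs = n_s(≤R) − (N_s_bulk/N_w_bulk)·n_w(≤R)      (default R = 12 Å)
```

with the indistinguishable-ion combination for ionic co-solutes, Kabsch
superposition RMSD/RMSF, and Y- versus λ-conformer calls from Fab/Fc
center-of-mass geometry. Seeded synthetic generators (multi-transition
van't Hoff melts; biased-shell bead trajectories) provide ground truth
for every estimator.

## Worked example

```r
library(ilstab)

# a synthetic fresh 50 wt% [Cho]Cl melt at realistic instrument noise
fresh <- generate_melt(melt_spec(noise_sigma = 140, seed = 42),
                       meta = sample_meta("igg4_50wt_fresh",
                                          "50 wt% [Cho]Cl", 50))
res <- analyze_melt(fresh$trace)
res$regions
#> <sigmoidal_regions> 2 region(s) selected by AICc
#>   region 1: 25.0-75.0 degC, center 70.4 degC
#>   region 2: 77.0-97.0 degC, center 82.4 degC
as.data.frame(res)
#>   region   tm    dH   dS r_squared n_points
#> 1      1 70.2  48.8  695     0.988        6
#> 2      2 82.2 119.2 1450     0.992        4

landscape_from_melt(res)
#> <landscape_fit> well: center 77.4 degC, sigma 8.45 degC, amplitude 13.4, offset 6.94
#>   dg_min -6.47 kJ/mol, fwhm 19.89 degC, area 284, rss 128
```

The two transitions of this generated melt sit at 69.2 and 82.9 °C; the
pipeline segments them, recovers their midpoints within the noise, and
reports per-transition `Tm` (°C), `ΔH` (kJ/mol) and `ΔS` (J/K/mol) in
the layout of a conventional melt table. The landscape fit summarises
the full-range free-energy well: its minimum (−6.5 kJ/mol here) is the
stability metric compared across formulations, and no deviation flag is
raised because the trace stays Gaussian to 97 °C. With noise-free input
the same pipeline reproduces the generating parameters to fractions of
a percent (see `tests/testthat/`).

```r
ionic_strength_from_wt(50, 139.62)   # 3.58 M choline chloride at 50 wt%

traj <- generate_trajectory(trajectory_spec(
  n_frames = 15, seed = 7, shell_bias = c(cation = 0.6, anion = 0.6)))
gamma_species(traj, "cation")
#> <preferential_interaction> cation: Gamma = -2.539 +/- 0.765 (R = 12 A, 15 frames)
```

A negative coefficient means the ion is preferentially excluded from the
protein surface — protectant-like behaviour.

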