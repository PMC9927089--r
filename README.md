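# biofilmmech

Dental plaque owes much of its resistance to brushing and rinsing to the
mechanics of its extracellular polymeric substance (EPS) matrix. Oral-care
actives such as zinc salts and L-arginine are thought to weaken that matrix,
and the combination ("dual zinc plus arginine") is used in dentifrices.
`biofilmmech` implements the quantitative analyses needed to test such claims
on instrument data from oral biofilms:

- **Rotating-disc detachment rheometry.** A biofilm-coated coupon spun through
  an angular-velocity ramp (0.1–300 rad/s) experiences drag beyond the
  smooth-disc baseline. The package computes the *biofilm momentum
  coefficient* `Cf = mean[Cm(ω) − Cm_s(Re)]` with `Cm = T/(½ρω²R⁵)` and the
  von Kármán smooth-disc baseline `Cm_s`, the trapezoidal torque-curve area
  (AUC), a linearised slope transform that exposes step torque drops, robust
  detachment-event detection (median − 3×1.4826·MAD), and the *critical
  detachment shear stress* `τ* = 0.800·ρR√(νω³)` at the first event.
- **Uniaxial flat-probe indentation.** Contact and substratum detection on
  force–displacement curves give the biofilm thickness; the slope of the
  0–20 % strain region gives the Young's modulus via the flat-punch relation
  `E = slope·(1 − v²)/(2r)` with `r = 0.004 m` and `v = 0.5`.
- **Interaction index.** A modified fractional-inhibitory-concentration (FIC)
  index with moduli in place of MICs:
  `IAI = E_DZA/E_Arg + E_DZA/E_Zn`, classified as synergism (`≤ 0.5`),
  additive (`0.5 < IAI < 4`) or antagonism (`≥ 4`).
- **COMSTAT-style confocal quantification.** Whole-volume Otsu thresholding,
  biomass (biovolume per substratum area, µm³/µm²) and the roughness
  coefficient `Ra = Σ|h_i − h̄|/(N·h̄)` of column heights per channel.
- **Synthetic-data generators** for all three instruments with known ground
  truth, and a pipeline driver with one-way ANOVA + Tukey HSD group
  comparisons.

## Worked example

```r
library(biofilmmech)

# an untreated-like coupon: drag excess 0.063, detachment at ~150 rad/s
g <- generate_torque_curve(cf0 = 0.063,
                           events = data.frame(omega = 150, drop = 0.5),
                           noise_sd = 0.01, seed = 42, treatment = "untreated")
rheology_fit(g$curve)
#> Rotating-disc detachment analysis
#>   treatment: untreated
#>   biofilm momentum coefficient: 0.05259
#>   torque AUC: 0.601 N.m rad/s
#>   1 detachment event(s); critical shear stress 27.7 Pa (first event at 144 rad/s)
```

The momentum coefficient (0.053) sits below the injected 0.063 because half
the biofilm's drag is shed at the 150 rad/s detachment event inside the
30–300 rad/s measurement window; the event itself is localised one grid
interval below 150 rad/s and converted to the 27.7 Pa shear stress at which
detachment began.

```r
gi <- generate_indentation_curve(E = 27.28e3, noise_sd = 0.02, seed = 42)
indentation_fit(gi$curve)
#> Uniaxial indentation analysis
#>   contact 55.51 um, thickness 189.9 um
#>   slope 290.9 N/m over 0-20% strain (R^2 = 0.9958)
#>   Young's modulus 2.727e+04 Pa (27.27 kPa)

interaction_index(9.29, 15.38, 11.14)   # group-mean moduli, kPa
#> Interaction index: 1.438 (arginine term 0.604 + zinc term 0.8339) -> additive
```

The indentation fit recovers the generating 27.28 kPa modulus to 0.04 % and
the 200 µm thickness to 5 %. The interaction index computed from the
group-mean moduli of combination-, arginine- and zinc-treated biofilms falls
in the additive range: the two agents neither potentiate nor antagonise each
other's mechanical weakening.

A full synthetic study (four treatment groups at the published group means
and SDs, with the published replicate structure) runs end to end with:

```r
report <- run_pipeline(generate_study(study_spec(seed = 1)), out_dir = "report")
report$comparisons$E      # ANOVA + Tukey on Young's modulus
report$interaction        # replicate-level interaction index, mean ± SD
```

or from a shell via `Rscript inst/scripts/biofilm-mech.R --synthetic --seed 1
--out report/`.

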