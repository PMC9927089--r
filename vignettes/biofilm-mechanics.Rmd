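---
title: "Quantifying biofilm mechanical destabilisation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm mechanical destabilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmmech)
```

`biofilmmech` turns three kinds of instrument records — rotating-disc torque
ramps, flat-probe indentation curves and two-channel confocal stacks — into
the mechanical readouts used to compare oral-biofilm treatments: drag excess,
detachment onset, stiffness, matrix architecture, and a two-agent interaction
index. This vignette explains each model, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the design
choices made where the methods literature leaves the details open.

## Rotating-disc detachment analysis

A coupon of radius $R$ (default 0.020 m) spins in water (density $\rho$ = 998
kg·m⁻³, kinematic viscosity $\nu$ = 10⁻⁶ m²·s⁻¹, both room-temperature
values) while resistive torque $T$ is recorded over an angular-velocity ramp
$\omega \in [0.1, 300]$ rad/s. Torque is nondimensionalised as the moment
coefficient $C_m = T / (\tfrac12 \rho \omega^2 R^5)$, and the biofilm's
contribution is the excess over the one-sided smooth-disc similarity
baseline,

$$C_{m,s}(Re) = 1.935\,Re^{-1/2} \;(Re \le 3\times10^5), \qquad
  C_{m,s}(Re) = 0.0365\,Re^{-1/5} \;(Re > 3\times10^5),$$

with $Re = \omega R^2/\nu$. For this geometry the whole ramp stays laminar
($Re \le 1.2\times10^5$), so only the first branch is exercised in practice;
the boundary at $3\times10^5$ is assigned to the laminar branch. The
**biofilm momentum coefficient** is the mean of $C_m - C_{m,s}$ over a
velocity window, by default the top decade (30–300 rad/s), where torque is
orders of magnitude above instrument noise. A theoretical rather than a
measured clean-coupon baseline is the default because it requires no extra
run; a measured baseline can be emulated by subtracting a reference curve
before analysis.

Detachment events are step reductions in torque. The **linearised slope
transform** first subtracts the full-run least-squares line from the torque
record (removing the dominant trend so steps appear as isolated spikes), then
takes first differences of the corrected torque over first differences of
$\omega$. Events are intervals where the slope falls below
$\mathrm{median} - k \cdot 1.4826\,\mathrm{MAD}$ with $k = 3$ by default;
runs of consecutive flagged intervals merge into one event at the most
negative slope. Robust statistics were chosen because the slope series is
heavy-tailed: most of its mass sits near zero at low velocities while the
upper decade contributes large systematic values. The **critical detachment
shear stress** converts the lowest event velocity to the laminar disc-edge
wall shear magnitude

$$\tau^* = 0.800\,\rho R \sqrt{\nu \omega^3},$$

where 0.800 combines the radial and tangential wall-gradient coefficients
($\sqrt{0.616^2 + 0.510^2}$). The first *detected* event — not the first
negative raw difference — defines the onset, because raw differences are
noise-dominated. When no event is detected the stress is reported missing,
never zero. The **AUC** is the trapezoidal integral of the raw (not
transformed) torque curve over the recorded ramp, a proxy for the energy
needed to spin the coupon.

## Indentation analysis

A flat probe of radius $r$ = 0.004 m approaches at constant rate; force stays
at baseline until contact, rises linearly while the biofilm compresses, then
stiffens sharply at the substratum. **Contact** is the first sample whose
force exceeds the pre-contact baseline mean by $k_{sd}$ = 5 baseline SDs and
stays above for $m_{run}$ = 10 consecutive samples; the baseline is the first
10 % of samples. The sustained-run requirement rejects noise spikes; both
parameters are configurable. **Substratum** is where the local
(11-sample windowed least-squares) slope first exceeds 20× the initial
post-contact slope, falling back to the termination sample (with a logged
warning) so that every curve stays analysable. Thickness is
$h = \delta_s - \delta_c$.

The modulus uses the flat-punch relation $E = \text{slope}\,(1 - v^2)/(2r)$
with Poisson ratio $v$ = 0.5 (incompressible gel). Dimensional analysis fixes
the $1/(2r)$ reading of the relation — slope (N/m) divided by length yields
Pa — and the package treats that as the definition throughout. The slope is
fitted on force–displacement (not stress–strain) over strains 0–20 % because
the relation consumes N/m directly; stress–strain curves are still available
via `stress_strain()`, with stress defined over the full probe area
$\pi r^2$ (the 8 mm probe is ~20× wider than the biofilm is thick, so full
contact is assumed) and engineering strain referenced to the thickness at
contact.

## Interaction index

With moduli substituted for MICs in the FIC framework,
$IAI = E_{DZA}/E_{Arg} + E_{DZA}/E_{Zn}$; synergism at $IAI \le 0.5$,
additive between, antagonism at $IAI \ge 4$. The printed rule assigns exactly
4 to both the additive and antagonism ranges; the package resolves 4 to
antagonism because that bound is the explicit inequality, and records the
rule in the result object. Replicate-level summaries default to
matched-replicate pairing (parallel discs per biological replicate); an
all-combinations pairing over every cross-group triple is available as a
sensitivity analysis, since how the published mean ± SD was aggregated across
replicates is not stated. Neither pairing is asserted to reproduce any
particular published aggregate; on group means the index is 1.438.

## Confocal quantification

Channels are thresholded by Otsu's method over the whole 3-D histogram (one
threshold per volume — slice-wise thresholds would bias tall-column
statistics), with a fixed-value override for degenerate histograms. When the
between-class variance has an exact tie plateau (empty bins between
well-separated classes) the threshold is the plateau centre. Biomass is
biovolume per substratum area (µm³/µm²). Column heights use the top-most
occupied voxel (COMSTAT convention), so internal gaps count toward height;
this differs from an occupied-voxel count for gappy columns and is the
documented choice. The roughness coefficient is
$Ra = \sum_i |h_i - \bar h| / (N \bar h)$ with empty columns included in $N$.
Connected-volume filtering is not applied. Roughness is computed per channel;
the treatment-sensitive readout is the EPS channel.

## Synthetic generators: what they emulate

The torque generator produces log-spaced ramps with
$T = \tfrac12 \rho \omega^2 R^5 (C_{m,s} + C_f(\omega))(1+\varepsilon)$,
multiplicative noise (torque ripple scales with load, default 1 %) and
instantaneous fractional drops in $C_f$ at detachment events. The indentation
generator inverts the flat-punch relation ($k = 2rE/(1-v^2)$), uses additive
force noise with SD relative to the force at 20 % strain (default 2 %), a
substratum 200× stiffer than the film, and truncation at the 15 N
termination load. The image generator draws per-column cell heights from a
lognormal (default median 20 µm, $\sigma_{\log}$ = 0.3 on a 40×48×48 grid of
1×0.5×0.5 µm voxels) and builds EPS either as a uniform layer (default 8 µm;
untreated phenotype) or as the *same total volume* concentrated into a random
30 % of columns (treated, punctate phenotype).

The default study specification reproduces the published study conditions:
group moduli (kPa) 27.28 ± 8.68 (untreated), 15.38 ± 7.97 (arginine),
11.14 ± 5.02 (zinc), 9.29 ± 2.87 (combination), truncated below at 0.5 kPa;
momentum coefficients 0.063 ± 0.021, 0.053 ± 0.023, 0.037 ± 0.023 for the
three groups the disc assay covered (the arginine arm was not run on the
rheometer and generates no torque curves); typical detachment velocities
decreasing with treatment (180, 120, 60 rad/s, lognormal spread 15 %) since
treated biofilms shed at lower shear; and per-assay replicate structure of
3 biological × 2 coupons (rheometry), 4 × 3 (indentation) and 3 biological ×
4 fields (imaging). The moduli's unit is taken as kPa — the biologically
realistic magnitude for plaque biofilms and the only reading under which the
0.5 kPa truncation is meaningful. Replicates are drawn independently; real
biological replicates are likely correlated, which the generator does not
emulate, nor does it emulate optical effects (PSF, attenuation, shot noise)
or viscoelastic (rate-dependent) indentation response. Passing recovery tests
therefore demonstrates correctness of the analysis chain under the stated
noise models, not robustness to every instrument artefact.

## Numerical choices and degenerate inputs

Duplicate angular velocities collapse to their mean torque (logged);
retraction samples after the displacement maximum are discarded (logged).
Curves are kept in SI units internally (m, N, N·m, Pa, rad/s) with
conversions at the I/O boundary, so unit mistakes surface in one place. The
event detector returns an empty table rather than erroring on featureless
input; an all-zero slope series yields no events because the MAD is zero and
the comparison is strict. Stacks whose channel intensity is constant raise a
degenerate-histogram error directing the user to a fixed threshold. ANOVA
(stats::aov) with Tukey HSD (stats::TukeyHSD) compares groups; technical
replicates are averaged to one value per biological replicate first, because
the biological replicate is the experimental unit — configurable, since
treating technical replicates as independent is the anticonservative
alternative.

## Problem sizes used in the test suite

The packaged tests run the recovery suites at 20–100 seeded repetitions per
property and the end-to-end ordering study at 100 seeded studies without
image stacks (the ordering readouts are mechanical). These sizes give
Monte-Carlo standard errors of 3–5 percentage points on the reported rates,
adequate for the pass bounds they are compared against. At the published
replicate numbers and SDs, the full four-group modulus ordering holds in
roughly 79 % of simulated studies (the same rate whether computed from
recovered or injected moduli), and the three-group momentum-coefficient
ordering in roughly 88 % — a sampling-power property of those study
conditions themselves: with six coupons per group, adjacent group-mean
differences of ~0.01–0.016 against SDs of ~0.02 cannot order correctly much
more often. The corresponding assertions in the acceptance suite are kept at
their stated bounds and document this gap rather than widening the bounds or
inflating the replicate counts.

## Known limitations

- The fouling-coefficient and shear-stress closed forms assume laminar
  similarity flow over a free disc; container walls, the 3.5 cm gap and
  coupon mounting hardware are not modelled.
- Contact detection assumes a flat pre-contact baseline; drifting baselines
  need detrending upstream.
- The punctate EPS generator redistributes volume column-wise; it does not
  build 3-D blobs, so lateral EPS connectivity is not represented.
- The interaction index inherits the FIC framework's assumptions; it is a
  descriptive ratio, not a mechanistic synergy model.
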