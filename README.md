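# flapflow

Quantitative analysis of indocyanine-green (ICG) fluorescence angiography
videos recorded during DIEP-flap breast reconstruction, for reconstructive
surgeons and imaging researchers who want the perfusion numbers produced by
proprietary clinical software (ingress, ingress rate, dynamic color maps,
perfusion patterns) from an open, testable implementation.

## What it computes

After an intravenous ICG bolus, tissue fluorescence `F(t)` in a region of
interest rises as dye-carrying blood arrives. From the regional
time–intensity curve, standardized to the first 20 s of recording, the
package reports:

- **ingress** (APU) = `max(F) − baseline`, with baseline the mean of the
  first frames (1 s) that precede any bolus arrival;
- **ingress rate** (APU/s) = ingress / (t_peak − t_onset), onset detected at
  baseline + 3 sd of the baseline window;
- both parameters over the **whole flap** (its brightest 20%, the "bright
  zone") and over the four **Hartrampf zones** around the perforator
  (ROI 2 = zone I at the perforator emergence, ROI 3 = zone II across the
  midline, ROI 1 = zone III ipsilateral end, ROI 4 = zone IV contralateral
  end);
- a **per-pixel perfusion map** (ingress and time-to-peak images, rendered
  blue→red), classified into one of three perfusion **patterns**: (1)
  ipsilateral perfusion stopping at the midline, (2) perfusion confined to
  the perforator area, (3) midline-crossing perfusion with poor peripheral
  ends;
- **univariate cohort statistics** relating perfusion parameters to clinical
  covariates: Student t / one-way ANOVA for continuous outcomes, chi-square
  (expected counts ≥ 5) or Fisher's exact test for categorical pairs, at
  α = 0.05 with no multiplicity correction (exploratory design).

A synthetic generator produces videos with closed-form gamma-variate
kinetics — per-pixel amplitude
`A(x,y) = A0 · exp(−d/λ) · m^[crosses midline] · p^[peripheral band]` around
the perforator, arrival `t0 + d/v` — plus cohort tables with configurable
multiplicative covariate effects, so every stage is validated against known
ground truth.

## Worked example

```r
library(flapflow)

geom <- defaultFlapGeometry()                    # 128 x 256 elliptical flap
sim  <- simulateFlapVideo(geom, preset = 1, seed = 42)
stack <- trimToDuration(sim$stack)               # 20-s standardization

quantifyZones(stack, geom)
#>       region baseline_apu ingress_apu ingress_rate_apu_s t_onset_s t_peak_s
#> 1 whole_flap         5.02      124.20              20.70      2.50     8.50
#> 2       roi1         4.97       96.59              13.80      3.25    10.25
#> 3       roi2         5.01      115.35              17.75      2.50     9.00
#> 4       roi3         5.00       27.02               4.16      4.25    10.75
#> 5       roi4         4.99       19.17               3.33      7.50    13.25
```

ROI 2 (Hartrampf zone I, over the perforator) shows the highest ingress and
rate and ROI 4 (zone IV) the lowest, the expected perfusion hierarchy; for
this preset-1 flap the contralateral zones (ROI 3/4) carry ~30% of the
ipsilateral signal because the simulated perfusion does not cross the
midline.

```r
classifyFlap(sim$stack, geom)
#> PatternLabel: type 1 (tauCross = 0.5, tauPeriph = 0.5)
#> PatternFeatures: r1 = 0.839, r3 = 0.254, r4 = 0.187, crossing index = 0.284
```

The crossing index (contralateral/ipsilateral ingress in bands at the
midline) is well below 0.5 while the ipsilateral periphery ratio r1 is above
it: pattern type 1, matching the preset that generated the video.

Cohort level:

```r
tab <- simulateCohort(cohortEffectConfig(n = 40, seed = 1))
univariateTable(tab)    # per-group means + p per perfusion outcome x covariate
```

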