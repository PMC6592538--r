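---
title: "Quantifying DIEP-flap perfusion from fluorescence angiography: models and design choices"
author: "flapflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DIEP-flap perfusion from fluorescence angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapflow)
```

## The measurement problem

During autologous breast reconstruction with a deep inferior epigastric
perforator (DIEP) flap, the surgeon needs to know how well the harvested
abdominal tissue is perfused through the single dissected perforator before
committing to the transfer. Indocyanine green (ICG) fluorescence angiography
answers this in real time: after an intravenous dye bolus, an infrared camera
records tissue fluorescence, whose rise tracks blood inflow. Clinical systems
report two regional parameters from the time–intensity curve of a region of
interest (ROI):

* **ingress** (APU, "absolute perfusion units" — the device's relative
  intensity scale): the difference between the region's initial mean
  fluorescence and its maximal value;
* **ingress rate** (APU/s): the speed of the fluorescence rise ("blush
  rate").

`flapflow` reimplements this analysis openly: frame-stack I/O and the
standardization of every video to a common 20-second window, the partition of
the flap into the four Hartrampf perfusion zones around the perforator,
regional and per-pixel quantification, a reproducible three-pattern
classification of the per-pixel map, and the univariate cohort statistics
used to relate perfusion parameters to clinical covariates. Because clinical
recordings cannot be redistributed, the package also contains a synthetic
video and cohort generator with closed-form ground truth; every stage of the
pipeline is validated against it.

## The kinetic model behind the simulator

Each pixel follows a **normalized gamma-variate** bolus curve:

$$ f(t) = B + A \left(\frac{t - t_0}{t_p}\right)^{\alpha}
   \exp\!\left\{\alpha\left(1 - \frac{t - t_0}{t_p}\right)\right\},
   \qquad t \ge t_0, $$

with $f(t) = B$ before arrival. The normalization makes the peak value
exactly $B + A$ at $t = t_0 + t_p$, so the true ingress of a pixel *is* its
amplitude $A$ — ground truth is closed-form rather than numerical. No washout
term is modelled: analysis windows are 20 s, within which clinical
fluorescence is still rising or plateauing, and a washout term would destroy
the closed-form peak.

Spatial structure (see `kineticsParams()`):

| parameter | meaning | default | units |
|---|---|---|---|
| `baseline` ($B$) | tissue background fluorescence | 5 | APU |
| `amplitude` ($A_0$) | amplitude at the perforator | 150 | APU |
| `tArrival` ($t_0$) | bolus arrival at the perforator | 2 | s |
| `timeToPeak` ($t_p$) | rise time | 5 | s |
| `shape` ($\alpha$) | gamma-variate shape | 2 | — |
| `speed` ($v$) | propagation speed; arrival at distance $d$ is $t_0 + d/v$ | 20 | mm/s |
| `decayLength` ($\lambda$) | amplitude decay $e^{-d/\lambda}$ | preset | mm |
| `midlineFactor` ($m$) | attenuation across the midline | preset | — |
| `peripheralFactor` ($p$) | attenuation in the peripheral end bands | preset | — |

The default geometry is a 128×256 elliptical flap at 1 mm/pixel, recorded at
4 Hz for 25 s — desk-scale sizes that exceed the 20-s analysis window while
keeping a full simulate–quantify–classify cycle around a second. The APU
scale is real-valued and clipped to $[0, 255]$; clinical devices do not
document their scale, so it is configurable. Noise is additive Gaussian
(default sd 2 APU); shot noise, camera vignetting and motion are deliberately
out of scope, so passing tests demonstrate correctness of the *estimators*,
not robustness to every artifact of clinical video.

Two numerical choices matter:

* **Arrival times are quantized to the frame grid.** The camera only samples
  at frame times; without quantization the sampled maximum would miss the
  analytic peak by $O((\Delta t/t_p)^2) A$ and ground truth would hold only
  approximately. Snapping $t_0 + d/v$ to the nearest frame keeps the
  ground-truth identity "per-pixel ingress $= A(x,y)$" exact to machine
  precision.
* **True per-zone ingress is defined on the zone-mean curve**, i.e.
  $\max_t \overline{f}(t) - B$ computed from the noiseless signal over the
  trimmed window. With heterogeneous arrivals the maximum of a mean curve is
  below the mean of the pixel maxima (Jensen gap), and the regional estimator
  measures the former, so that is the honest comparison target.

The three perfusion-pattern presets translate the qualitative clinical
phenotypes into the spatial parameters, chosen from the zone geometry of the
default flap (distances of each zone from the perforator) so that each preset
sits far from the classification thresholds:

| preset | phenotype | $\lambda$ (mm) | $m$ | $p$ |
|---|---|---|---|---|
| 1 | homogeneous ipsilateral perfusion, stops at the midline | 150 | 0.3 | 1 |
| 2 | perfusion confined to the perforator area | 30 | 0.3 | 1 |
| 3 | homogeneous across the midline, poor peripheral ends | 200 | 1 | 0.1 |

## From video to parameters

**Standardization.** `trimToDuration()` keeps the half-open window
$[0, 20)$ s — at 4 Hz, exactly 80 frames — so that all videos are compared
over the same duration; a shorter recording is a quality-criteria error, not
a silently padded input. Retained frames are untouched, making the operation
idempotent.

**Zoning.** `partitionZones()` splits each hemi-flap (relative to the
midline) at the midpoint of its column extent: ROI 2 is the
perforator-containing central region (Hartrampf zone I), ROI 1 the
ipsilateral peripheral end (zone III), ROI 3 the contralateral central region
(zone II), ROI 4 the contralateral end (zone IV). Clinical software places
these ROIs freehand; the equal-width rule is the reproducible surrogate, and
the label image is exportable/editable for irregular flaps. A perforator
sitting exactly on the midline has no defined side and is rejected.

**Whole-flap region.** Clinical "whole flap" parameters are computed on the
brightest part of the flap. `brightZone()` keeps the flap pixels whose peak
fluorescence lies in the top 20% (configurable) of the flap's
peak-fluorescence distribution. The threshold is an order statistic with an
inclusive tie rule, so the selection is invariant under any strictly
increasing intensity rescaling and a uniform image keeps the whole flap. The
true clinical selection criterion is proprietary; 0.2 is a package default
and its effect should be checked when comparing absolute values across
software.

**Ingress.** `computeIngress()` implements the definition directly:
baseline = mean of the first `window` frames (default 4, i.e. 1 s at 4 Hz —
recording starts at injection, so the earliest frames precede any arrival),
ingress = raw maximum − baseline, floored at 0 (a noisy region at baseline
must not return a negative). The peak *time* is read from a width-3 moving
average to stabilize it under noise, while the ingress *value* stays the raw
scan so that it agrees exactly with a brute-force maximum over frames.

**Ingress rate.** Clinical documentation never defines "blush rate"
mathematically. The package defines it as ingress divided by the rise time
from onset to peak, with onset the first time the smoothed curve exceeds
baseline $+ 3\,\mathrm{sd}$ of the baseline window (falling back to the first
frame when the curve never sits below the threshold). On a dense noiseless
gamma-variate this converges to $A/t_p$. The plausible alternative — maximum
smoothed derivative — is available as `rateMethod = "deriv"`. A cohort with
median ingress around 127 APU rising over roughly 13.5 s is consistent with
the rise-time definition, but no published numbers uniquely determine the
vendor's formula; rates from different software should not be mixed without
calibration. Both ingress and rate are affine-equivariant: rescaling
intensities by $a \cdot F + b$ scales them by $a$ and moves no time.

**Per-pixel maps.** `perfusionMap()` applies the same definitions pixel-wise,
yielding the ingress and time-to-peak images that a blue-to-red dynamic color
overlay renders (`renderPerfusionMap()`; red = best perfused). Under noise
the per-pixel raw maximum is biased upward by the extreme-value statistics of
~80 noise draws (about $+2.4\sigma$), which is why regional parameters are
always computed from the region's mean curve first, never by averaging the
per-pixel map.

## Pattern classification

The three clinical patterns are read by eye from the color overlay; the
package replaces the eye with two scale-free features of the per-pixel
ingress map: the zone ratios $r_k = \mathrm{ROI}_k/\mathrm{ROI}_2$ of mean
per-pixel ingress, and a **midline-crossing index** — mean ingress in a band
adjacent to the midline on the contralateral side divided by the mirror
ipsilateral band (band width 10% of flap length per side). The decision rule,
with both thresholds defaulting to 0.5:

1. crossing index ≥ 0.5 and $\min(r_1, r_4) < 0.5$ → **type 3**;
2. crossing index < 0.5 and $r_1 \ge 0.5$ → **type 1**;
3. otherwise → **type 2**.

The rule is total (every feature vector gets exactly one label),
deterministic, and invariant to rescaling the map. The thresholds are not
calibrated to any clinical dataset — none with labels is available — but the
simulated recovery experiment (300 flaps, 100 per preset, default noise)
recovers ≥ 95% of labels, with noiseless preset features sitting at 0.15–0.2
distance from each threshold. Only the spatial distribution of ingress is
used; the temporal arrival order (available as the time-to-peak map) could
support a dynamic variant, but no published rule exists to implement.

## Cohort statistics

`compareMeans()` uses the classical pooled-variance Student t test for two
groups (Welch by flag) and one-way ANOVA beyond, two-sided, $\alpha = 0.05$.
`compareCategorical()` applies the chi-square test when all expected counts
are ≥ 5 — the conventional "conditions of validity" — and Fisher's exact test
otherwise, reporting which was used. The chi-square is computed *without*
Yates continuity correction: the corrected 2×2 statistic is conservative
(type-I error near 3%), while the uncorrected classical statistic calibrates
at the nominal 5%, which is what the package's 2000-replicate null
simulations check. Fisher p-values are verified in the test suite against an
exhaustive hypergeometric enumeration over all 2×2 tables with margins ≤ 15.
`univariateTable()` assembles per-group means and p values for each
perfusion outcome × clinical covariate; comparisons are complete-case and
deliberately uncorrected for multiplicity (exploratory design), which the
report's `note` attribute states.

The cohort simulator draws perfusion parameters lognormally around
clinical-scale centers (whole-flap ingress 127 APU, rate 9.4 APU/s, zone-I
ingress 65 APU, rate 3.4 APU/s; log-sds matched to clinical interquartile
ranges), correlated within patient (shared factor, $\rho = 0.6$), and
multiplies in configurable covariate effects. Default effect directions
encode impaired perfusion under diabetes and tamoxifen and better zone-I
perfusion over age 60. At $n = 10{,}000$ the stratum-mean ratios recover the
configured multipliers within sampling error, which is the simulator's own
acceptance check.

## Problem sizes and limitations

Validation experiments run at: 300 flaps for pattern recovery, 100 noisy
flaps for ROI-ingress recovery (median relative error, mixed presets — note
that a preset-2 flap has almost no true signal in ROI 4, where relative error
is therefore dominated by noise), a 40-flap mixed cohort for zone ordering,
and 2000 null replicates per test family for type-I calibration. These sizes
were chosen to keep a full validation run within minutes on one core.

Known limitations: the simulator's noise model is additive Gaussian only; no
motion, ambient-light or vignetting artifacts; ROI placement is axis-aligned
columns rather than freehand polygons; the ingress-rate and bright-zone
definitions are documented surrogates for proprietary, undocumented vendor
algorithms, so absolute agreement with vendor numbers on the same video is
not guaranteed; and APU are relative units — none of the parameters is a
calibrated blood-flow measurement.
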