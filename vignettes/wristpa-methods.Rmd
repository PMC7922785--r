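---
title: "Methods: validating a wrist accelerometer against criterion devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a wrist accelerometer against criterion devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristpa)
```

## The problem

Consumer- and research-grade wrist accelerometers estimate how much time a
person spends sedentary (SED) or in light (LPA) and moderate-to-vigorous
(MVPA) physical activity. Before such a device can be used in studies, its
estimates must be compared against criterion measures: a validated
research accelerometer worn on the same wrist for free-living days, and
portable indirect calorimetry (breath-by-breath VO~2~) during a scripted
lab session. `wristpa` implements that validation chain end to end and
ships a synthetic-data module so every stage is testable with known
ground truth, without any proprietary recordings.

## Accelerometer processing

Raw tri-axial samples (g units) are first calibrated against gravity:
seconds whose per-axis standard deviation falls below 13 mg are treated as
static postures, and per-axis gain/offset are fit by iterative least
squares so that static vector norms approach 1 g. This is a deliberately
simplified static calibration, not a full ellipsoid/temperature model: it
needs static windows in several orientations (per-axis range of at least
0.25 g by default) to be identifiable, and degrades gracefully — too few
or too-clustered windows leave the stream unchanged with an
`uncalibrated` flag.

Movement intensity is ENMO, the Euclidean norm minus one:
$\mathrm{ENMO} = \max(\sqrt{x^2+y^2+z^2} - 1, 0)$, in milli-g, averaged
within each wall-clock second. Seconds with less than half their expected
samples (configurable) are missing. Per-second values are classified with
wrist cut-points, by default 44.8 mg (SED/LPA) and 100.6 mg (LPA/MVPA),
the adult non-dominant-wrist values from the Hildebrand regression
equations. The bands are half-open with the upper class winning at the
threshold, matching the ">= cut-point" reading of the cut-point
literature; this is asserted by tests. Cut-points live in the
configuration object, never in the algorithm, so switching reference
equations cannot silently change results. Vigorous activity is not split
out on the accelerometer side; the validation compares MVPA as one band.

Seconds collapse into 60-s epochs aligned to wall-clock minute boundaries
(alignment is what makes cross-device merging a join rather than an
interpolation). An epoch records seconds per class, its mean ENMO and a
validity flag; by default a single missing second invalidates the epoch.

## Non-wear, sleep, and invalid time

Wear detection uses the Choi rule on a per-minute movement series: any
maximal run of zero (or artifactual) minutes totalling at least 90
minutes is non-wear, where a nonzero run of at most 2 minutes is
artifactual iff flanked on both sides by at least 30 consecutive zero
minutes. Because the criterion counts of the original algorithm are not
available from ENMO epochs, the package uses a documented proxy: rounded
per-minute mean ENMO, floored to zero below 1 mg. The implementation is
checked minute-for-minute against a brute-force oracle on a thousand
random series.

Three design choices matter here:

* wear is detected on the **criterion** stream only and the resulting
  mask applies to both devices, so exclusions can never differ between
  methods;
* sleep comes from the self-report log, not an algorithm;
* minutes where the test device recorded nothing (Bluetooth dropout) are
  *invalid* for both devices, mirroring how disconnection gaps were
  treated in the original processing. The analysis set is
  `wear & !sleep & !invalid`.

## Calorimetry

Breath-by-breath VO~2~ is collapsed to 10-s bins by sample-and-hold time
weighting (a breath's value is held until the next breath, at most 10 s,
so silent gaps become missing time rather than stale readings), then
minutes average their available bins, requiring 3 of 6. METs are
`VO2 / (3.5 * body mass)`. The printed MET band tables in the literature
leave gaps (1.5–1.6, 2.9–3.0, 5.9–6.0); the package uses continuous
half-open bands with breakpoints 1.5, 3.0, 6.0 so every value is
classified — a package decision, flagged rather than attributed to any
source. When compared with accelerometer MVPA, calorimetry MVPA is
MPA + VPA.

## Merging and summaries

Sources are inner-joined on epoch start, restricted to the analysis set:
a minute contributes only if every requested source has a valid epoch
there. Summaries report minutes per class per source; free-living days
average into min/day over days meeting a configurable valid-day rule
(default: any day with valid time counts, reproducing a permissive
inclusion; a standard 600-min rule can be imposed via
`valid_day_min`).

## Agreement statistics

For each intensity class, paired per-participant estimates feed:
Pearson r (two-sided p, n − 2 df), mean difference with the
criterion − test sign convention, participant-level MAPE
$\frac{1}{n}\sum |c_i - t_i| / c_i \times 100$ (pairs with a zero
criterion are dropped with a warning), Bland–Altman bias with 95% limits
of agreement (±1.96 sample SD of differences), and the t-based 90% CI of
the test-method mean.

The equivalence-zone statistic asks: how wide, as a percentage of the
criterion mean, must a symmetric zone around that mean be before it
contains the whole 90% CI of the test method? The minimum such zone is

$$\mathrm{EZ\%} = \left\lceil \frac{100 \cdot
\max(\bar c - \mathrm{CI}_{lo},\ \mathrm{CI}_{hi} - \bar c)}
{\bar c} \right\rceil_{0.1}$$

with a 0.1-percentage-point ceiling. The operation takes the CI bounds as
explicit inputs rather than recomputing them, which decouples the
statistic from any particular CI construction. Minimality (containment at
EZ, failure at EZ − 0.1) is property-tested on 10,000 random inputs.
A numerical note: the ceiling subtracts 10⁻⁹ before rounding so a ratio
that is exactly a multiple of the step is not pushed one step up, and
containment checks use a 10⁻⁹-scaled tolerance so the minimality property
is stable in floating point.

## The synthetic study

The generator emulates the full study: a 62-minute lab protocol (twelve
5-minute activities in three intensity categories with two 1-minute
transit breaks) and a multi-day free-living week, recorded by a 25 Hz
test device and a 100 Hz criterion device worn together, plus
breath-by-breath VO~2~ for the protocol session.

Movement is synthesized as a half-rectified oscillation of the
acceleration norm riding on a slowly rotating gravity unit vector:
$|\mathbf a(t)| = 1 + A\sin(2\pi f t)$ with $f$ 1–2 Hz. Because the
cycle-mean of the positive part is $A/\pi$, setting
$A = \pi\,\mathrm{ENMO}_{target}/1000$ makes the expected per-second ENMO
equal the target analytically — ground truth is exact by construction,
not fitted. Per-block ENMO/MET targets are chosen comfortably inside
their class bands (SED ≈ 5 mg / ≤ 1.4 MET, LPA 60–95 mg / 1.7–2.8 MET,
MVPA 130–400 mg / 3.2–8 MET), since no per-activity accelerations are
published; the transit breaks are treated as light walking.

The free-living plan places, per day, an off-wrist night matching the
sleep log (08:00–22:00 waking window by default), one daytime non-wear
gap of 95–150 minutes (long enough for the Choi rule to find), random
whole-minute activity bouts filling the rest, and minute-aligned
test-device dropout gaps on two days. Defaults for noise were chosen once
as bench-realistic: 10 mg per-axis noise while worn, 1 mg electronic
noise while the device lies still (so off-wrist minutes fall under the
1 mg stillness floor), a 2 mg inter-device bias, and 8% CV on breath VO~2~
with a 30-s first-order onset lag; body mass defaults to the cohort mean
of 90.1 kg. All intervals are whole minutes so epoch-level truth is exact.

What the generator does **not** emulate: real wrist kinematics
(frequency content is a single tone, not gait spectra), posture-specific
gravity signatures, device clock drift, temperature effects, or
behavioural correlation between days. Passing recovery tests therefore
demonstrates the correctness of the processing chain, not the field
accuracy of any physical device.

One subtlety: the VO~2~ onset lag is deterministic physiology, not noise,
but it smears MET classes across block transitions. Exact-recovery tests
therefore run with the lag disabled (`lag_tau = 0`) while keeping it on
by default for realism.

## Problem sizes and reproducibility

The test suite simulates full-rate (25/100 Hz) seven-day recordings for
the recovery checks and uses reduced sampling rates for end-to-end I/O
round-trips; the Choi oracle comparison uses 1,000 random series of up to
600 minutes. Every stochastic step is seeded through the configuration
objects, and fixture writes are verified byte-identical across reruns via
MD5 manifests. `scripts/acceptance.R` recomputes the package's headline
quantities from scratch with `--seed` controlling all randomness.

## Known limitations

* The minimum-EZ statistic is reported descriptively; no TOST p-value is
  attached.
* Calibration is static-window least squares; streams without orientation
  diversity stay uncalibrated by design.
* Only one non-wear proxy (mean-ENMO based) is provided; count-based
  proxies from vendor software will differ in borderline minutes.
* Published equivalence-zone tables derived from unrounded source data
  cannot always be reproduced to the printed 0.1% from their own rounded
  inputs; the package reports what its inputs imply.
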