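---
title: "Methods: ERG decomposition, OCT sectors and longitudinal drug-effect statistics"
author: "ergoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERG decomposition, OCT sectors and longitudinal drug-effect statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergoct)
```

# Scope

`ergoct` implements the analysis chain used to screen acute drug effects on
retinal function and structure in rodent models: decomposition of
dark-adapted full-field flash electroretinograms (ERG) into a
photoreceptoral component (P3, summarised by its saturated amplitude RmP3)
and an ON-bipolar-cell component (P2, summarised by its peak amplitude);
ETDRS outer-ring sector means from segmented OCT layer-thickness maps; and
the longitudinal statistical layer that connects them — baseline
normalisation, robust (ROUT) outlier removal, two-way repeated-measures
ANOVA and Sidak-adjusted post hoc contrasts at specific times. A seeded
synthetic-cohort generator with exact ground truth makes every stage
testable without animal data.

# The P3 model and its fit

The photoreceptoral leading edge of the a-wave is modelled by the
delayed-Gaussian saturation function

$$P3(t) = -R_{mP3}\,\bigl[1 - e^{-E\,S\,(t-t_d)^2}\bigr], \qquad t > t_d,$$

and 0 at or before the delay $t_d$. $E = 10^{\,\mathrm{flash\ log}}$
linearises the flash energy from log cd·s/m² (default 2.07), $S$ is a
sensitivity with units (cd·s·m⁻²)⁻¹·s⁻², and $R_{mP3}$ (µV) — the
saturated amplitude — is the acceptance-bearing output. The trace is
monotone non-increasing and bounded below by $-R_{mP3}$; both properties
are asserted by property tests over random parameter draws.

Fitting choices that matter:

* **Baseline reference.** The acquisition chain is AC-coupled, so absolute
  DC is arbitrary; `fit_p3()` re-references the record to its pre-stimulus
  mean and stores that baseline in the fit object, which
  `subtract_p3()` honours.
* **Fit window.** Leading edge only: 3 ms after the flash to the a-wave
  trough, **capped at 11 ms**. At this flash energy the modelled rod
  response is ~98% saturated by 11 ms while the rising b-wave is still
  under ~1.5% of its peak; letting the window run to the trough itself
  admits enough b-wave intrusion to bias $R_{mP3}$ by about −3%, which we
  verified directly on noiseless synthetic records. The window is a
  user-visible parameter.
* **Optimisation.** $R_{mP3}$ enters the model linearly and is profiled in
  closed form; the search runs over $(\log S,\ t_d)$ from a multi-start
  grid ($t_d \in \{2,\dots,8\}$ ms crossed with five $S$ decades),
  followed by bounded quasi-Newton polishing of the three best starts. The
  returned SSE is never worse than the best grid start, and an acceptance
  test checks it against an exhaustive coarse grid oracle on random
  fixtures.
* **Single-flash identifiability.** With one flash energy, $S$ and $t_d$
  are only weakly identified; bounds ($S \in [1, 10^5]$,
  $t_d \in [1, 12]$ ms), the multi-start and the reported SSE mitigate
  this. $R_{mP3}$ itself is well identified because the capped window
  reaches deep saturation.

# P2 isolation and the b-wave refinement

Subtracting the fitted P3 from the raw record yields the P2-OP complex:
the b-wave plus high-frequency oscillatory potentials (OPs, ~70–200 Hz).
The P2 is isolated by a **zero-phase frequency-domain low-pass**: forward
DFT, multiplication by a real raised-cosine transfer with unit DC gain and
gain exactly $1/\sqrt2$ (−3 dB) at 46.9 Hz, inverse DFT. The transition
band (default width 50 Hz, so the response reaches zero at ~79 Hz) is a
config parameter; the historical instrument convention behind "46.9 Hz"
fixes only the −3 dB point, not the transition shape. Zero-phase filtering
leaves peak times untouched (verified by a symmetric-pulse
centre-of-mass test), and the filter is linear to machine precision.
P2 peak amplitude is measured baseline-to-peak over 0–250 ms — not
trough-to-peak, because the P3 has already been removed.

`decompose_erg()` adds one **refinement pass**: a descriptive gamma kernel
(plus an intercept that absorbs low-frequency leakage of any P3 misfit) is
fitted to the filtered P2 over 12–350 ms, and the fitted kernel's small
leading-edge tail is subtracted from the raw record before the P3 is
refitted. This removes most of the residual b-wave intrusion bias
(noiseless RmP3 error −2.9% → −1.1% on the default synthetic record).
Directly subtracting the filtered complex does *not* work: the low-pass
passes the P3 misfit itself, so pure alternation self-confirms the first
fit. On synthetic data the refinement model is exact by construction
(the generator's P2 *is* a gamma kernel); on real data it is an
approximation, which is why the refinement only ever corrects the
< 2% leading-edge tail and never the measured P2 itself.

# The acquisition emulation

Records are sampled over 640 ms at 4 kHz with a 20 ms pre-stimulus
segment, and band-passed 0.3–1000 Hz (−3 dB). The band-pass magnitude is
second-order Butterworth-style on each skirt; the order is a design choice
(only the corners are externally specified) and order 2 keeps in-band
distortion of the slow P3/P2 components negligible (gain 0.9993 at the
first DFT bin of a 640 ms record). Because a flash response ends ~450 µV
away from where it started, the generator filters an edge-padded copy
(0.5 s endpoint hold per side) so circular wrap-around ringing lands in
discarded padding rather than in the pre-stimulus baseline, and then
re-references the record to its pre-stimulus mean, as acquisition software
displays it. Residual distortion is < 0.5 µV inside the fit window and
< 3% of the component amplitude anywhere (the worst case is high-pass sag
over the sustained late plateau).

# The synthetic cohort: what it emulates and what it does not

Each record is the sum of the P3 model, a unit-peak gamma-kernel P2
(default peak 700 µV at 80 ms; order 5, τ = 20 ms), three Gabor OP bursts
at 110–130 Hz centred 20–36 ms (25–40 µV), a slow 0.25 Hz drift (5 µV) and
white noise (10 µV SD), band-passed as above. All response components are
gated to t > 0. Default study conditions: four groups (WT/HOM ×
VEH/LDOPA) with n = 11/11/13/11, recordings at 0, 5, …, 30 min,
HOM baseline attenuation ×0.75, and multiplicative amplitude-growth
trajectories reaching 1.47 (HOM+LDOPA), 1.25 (HOM+VEH), 1.16 (WT+LDOPA)
and 1.19 (WT+VEH) at 30 min along a saturating exponential time course
(τ = 12 min, the scale of intraperitoneal levodopa absorption).

Between-subject variability has two parts:

* a **lognormal baseline scaler** (CV 0.20) applied to both RmP3 and P2,
  drawn once per subject and reused across timepoints — the
  repeated-measures structure;
* a **random response slope** (`growth_sd = 0.26`): a per-subject additive
  deviation of the growth factor at 30 min, following the same saturating
  time course (so every trajectory is exactly 1 at baseline).

The slope term, not the record noise, carries the biological
heterogeneity of drug response. The record noise (10 µV) yields a
realistic per-record decomposition error (median ≈ 1–2%); the slope SD is
sized so the group SEM of the normalised 30-min change is ≈ 7–9% at
n = 11–13. A consequence worth stating plainly: with an endpoint contrast
of ~22 percentage points between the two HOM groups and per-subject
%-change SD ≈ 26 points, the realised group slope-contrast varies between
simulated cohorts with SD ≈ 10.6 points, so the within-HOM
time × treatment interaction at α = 0.01 is detected in ≈ 60% of cohorts
— not more — under these conditions. No split of the heterogeneity
between stable slopes and per-record state noise raises this
materially (state noise inflates the interaction's own error stratum and
is strictly worse). The acceptance artefacts report this measured power
as-is.

The generator does **not** emulate: photoreceptor recovery (the P3 stays
saturated for the whole record, so high-pass sag is slightly exaggerated),
eye-to-eye replication (one record per subject per timepoint; the
combining rule for two eyes is not specified in the emulated protocol),
anaesthesia pharmacokinetics, flash-intensity series, or non-stationary
noise. Passing recovery tests on these synthetics therefore demonstrates
correctness of the decomposition arithmetic and robustness to the modelled
noise — not robustness to every artefact of real recordings.

# Longitudinal statistics

**Baseline normalisation** expresses each value as
`100 × value(t)/value(0)` per subject per measure; the ratio is computed
before the scaling so baseline rows are exactly 100 in floating point.
Subjects with a missing or zero baseline are excluded with a warning.

**ROUT outliers.** The robust-fit/FDR rule reduced to a location model:
centre = median; robust scale RSDR = 68.27th percentile of the absolute
residuals with the small-sample correction N/(N−K), K = 1; two-sided t
p-values (df = N−K); Benjamini–Hochberg step-up at Q (default 1%, the
conventional default). Applied per group × timepoint × measure. On clean
Gaussian vectors (n = 12) the measured per-point false-flag rate is
≈ 0.1%, and a point 10 robust SDs out is always flagged.

**Repeated-measures ANOVA.** One between-subjects factor (a group label
or the genotype × treatment crossing) and one within-subjects factor
(time), every retained subject observed at every timepoint (subjects
missing a timepoint are listwise deleted with a warning — the classical
method, not a mixed-effects likelihood). Because the within factor is
complete, the two-stratum decomposition is exactly orthogonal even with
unequal group sizes, and the implementation computes it directly: the
between effect is tested against subjects-within-groups MS; time and
interaction against the subject × time residual MS. SS additivity and df
accounting are asserted on every construction, and the suite cross-checks
the full table against `stats::aov` with an `Error(subject)` stratum on an
unbalanced fixture. No sphericity correction is applied by default (none
is part of the emulated protocol); with a single between factor the
unbalanced-design Type I/II/III distinction is moot. A zero-SS effect
reports F = 0 even when the error MS is also zero (exactly parallel
noiseless profiles).

**Post hocs at specific times.** Groups are compared at each timepoint
with the pooled error appropriate to a mixed design,
$(MS_{subj} + (T-1)\,MS_{res})/T$, with Satterthwaite degrees of freedom,
then Sidak-adjusted, $p_{adj} = 1-(1-p)^m$, with m = the family size
(default: all requested contrast × time combinations; the default
contrast family is LDOPA vs VEH within each genotype). The hand-checked
toy table in the test suite pins both the ANOVA decomposition and the
post hoc t statistics exactly.

**Null calibration.** Under a compound-symmetric null (subject intercept
+ iid noise; 2 groups × 10 subjects × 7 timepoints) the interaction test
rejects at α = 0.05 in ≈ 5% of 2000 replicates, verified in the
acceptance suite.

# OCT sectors

A segmented layer-thickness map (µm on a grid with physical pixel pitch)
is averaged over the ETDRS outer ring: pixels with
$d_{inner}/2 \le r < d_{outer}/2$ (defaults 3–6 mm; half-open so boundary
pixels are never double-counted), split into quadrants at the 45°
diagonals. Superior is the polar-angle interval [45°, 135°); the
horizontal quadrants are labelled nasal/temporal by the eye side (default
OD). Missing pixels are ignored by the means and tracked as per-quadrant
coverage; any quadrant under 50% coverage flags the result. The combined
outer-ring mean — the default analysis quantity, with per-quadrant values
retained — is the pixel-count-weighted mean of the quadrant means.
Quadrant means are verified against an independent brute-force per-pixel
loop to machine precision, and rotation/pitch-scaling invariances are
tested. The clinical 1/3/6 mm diameters are the default; a mouse-eye
scale factor can be applied by scaling the ring diameters, which the
invariance test shows is exactly equivalent to scaling the pixel pitch.

The OCT generator produces per-layer tables (RNFL, GCIPL, INL, OPL, ONL,
and TRT as the exact sum of the components plus a constant remainder for
the unsegmented outer bands): between-subject layer SDs of 1–3 µm,
HOM-specific offsets confined to the outer retina (OPL −1.5 µm, ONL
−4 µm), a global −0.5 to −1.5 µm thinning at the 30-min scan in every
group (the anaesthesia-related drift the normalised analysis must
separate from drug effects), and a 0.6 µm within-subject measurement SD,
appropriate for sector means from registered follow-up scans.

# Problem sizes and numerical choices

The shipped test-suite and acceptance-script sizes are: 100 waveforms for
recovery medians; 20 fixtures for the grid oracle; 2000 replicates for
null calibration and for the ROUT false-flag rate; 500 cohorts
(measure-level) for interaction power; one full waveform cohort (46
subjects × 7 timepoints) for end-to-end effect recovery; 20 random maps
for the sector oracle. The full-waveform path is used wherever a single
cohort suffices; large-replicate statistical loops use the measure-level
generator, whose measurement-error CV (0.02) is set from the
decomposition error measured on the waveform path. Degenerate inputs are
handled explicitly: records with no negative deflection beyond 3× the
pre-stimulus noise SD raise "no measurable a-wave"; an all-constant
vector yields an empty outlier report; a flat trace yields a
boundary-flagged zero P2; exactly parallel noiseless profiles yield
F = 0, not NaN.

# Worked example

```{r example, eval = FALSE}
library(ergoct)

run <- full_run(out_dir = "ergoct_demo", seed = 1)

# per-record decomposition
head(run$decomposition)

# drug-effect analysis of normalised RmP3
print(run$analyses$rm_p3_uV$norm_anova)
print(run$analyses$rm_p3_uV$posthoc)

# group trajectories
plot_group_trajectories(run$analyses$rm_p3_uV$norm_summary,
                        main = "RmP3, % of baseline", ylab = "%")
```

# Known limitations

* RmP3 carries a small negative bias (~1%) from residual b-wave intrusion
  and filter distortion; the documented budget in the tests is 2%
  noiseless and 5% median under default noise.
* `S` and `t_d` from a single flash energy should be treated as nuisance
  parameters, not endpoints.
* The ANOVA layer is the classical two-stratum method by design; data
  with informatively missing timepoints need a mixed-effects approach
  outside this package's scope.
* Under the default heterogeneity calibration the within-HOM interaction
  power at α = 0.01 is ≈ 60% (see the synthetic-cohort section); screens
  designed around this endpoint should plan sample sizes accordingly.
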