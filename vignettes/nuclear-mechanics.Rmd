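---
title: "Quantifying oocyte nuclear mechanics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oocyte nuclear mechanics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmech)
```

This vignette documents the models behind `nucmech`, the parameters that
matter, the numerical choices where behaviour could legitimately differ
between implementations, and what the synthetic-data generators do and do
not emulate. It states no empirical result beyond what the package's test
suite and acceptance script themselves compute.

## 1. The measurement problem

During *C. elegans* oogenesis, meiotic nuclei are loaded by
cytoskeletal forces transmitted through LINC complexes (SUN-1/ZYG-12) at
the nuclear envelope (NE). When the lamina (LMN-1) is depleted, these
forces polarize the LINC complexes into a cap and can collapse the
nucleus. The package quantifies both sides of this phenomenon:

* **mechanics** — isolated nuclei are driven through a mechano-node-pore
  sensing (mechano-NPS) microfluidic channel; the current record yields a
  diameter, the applied strain, and a deformability index per nucleus;
* **imaging** — fluorescence rings around nuclei yield clustering and
  polarization statistics; time-lapse series yield patch speeds and
  collapse rates; whole-gonad layouts yield per-zone fractions of
  collapsed / paired / synapsed nuclei.

No raw instrument data ships with the package: every input format has a
seeded generator with known ground truth, so the full pipeline is testable
end to end.

## 2. Mechano-NPS

### 2.1 Channel model

`default_geometry()` carries the device dimensions: a 9.9-µm-high channel
with a 700.4 × 5.9 µm sizing segment, an 80.4 × 50.4 µm node, and a
700.4 × 2.9 µm contraction segment, driven at 6 V and 7 kPa. A nucleus of
diameter $d_n$ entering the contraction segment of width $w_c$ experiences
the fixed strain

$$\varepsilon = \frac{d_n - w_c}{d_n}, \qquad d_n > w_c,$$

and $\varepsilon = 0$ otherwise; undeformed nuclei carry no stiffness
signal and are excluded from deformability summaries.

### 2.2 Sizing relation

The blockade of a particle in a rectangular segment of width $w$, height
$h$ and length $L$ uses the canonical resistive-pulse relation with the
standard large-particle correction,

$$\frac{\Delta I}{I} \;=\; c \cdot \frac{d^3}{D_e^2\,L}\cdot
\frac{1}{1 - 0.8\,(d/D_e)^3},
\qquad D_e = \sqrt{4wh/\pi},$$

where $D_e$ is the equal-area effective diameter and $c$ a calibration
constant (default 1) fitted from beads of certified diameter by
`calibrate_with_beads()`. Sizing inverts the strictly monotone forward
relation by bracketed root finding (`uniroot`, tolerance $10^{-9}$ µm).
The relation is exposed as `relative_blockade()` so a recalibrated or
alternative sizing law can be audited directly.

### 2.3 Transit-time model and wCDI

In the simulator a particle crosses the sizing segment in
$t_s = L_s/v$ at the free-flow speed $v$ and the contraction segment in

$$t_c = \frac{L_c}{v}\Bigl(1 + k\,\frac{\varepsilon}{1 + s}\Bigr),$$

with strain gain $k$ (default 2) and softness $s \ge 0$ ($s = 0$ rigid).
This is the simplest monotone map with the correct physics: stiffer
objects take strictly longer to traverse the contraction segment, rigid
particles below the contraction width transit at free-flow speed, and the
slow-down grows with the applied strain. Quantitative constants of this
map are not asserted anywhere; analyses bind only to the ordering.

The whole-cell deformability index is a pluggable strategy
(`compute_wcdi(formula = ...)`). The shipped default,

$$\mathrm{wCDI} = \frac{L_c\,h\,t_s}{d_n^2\,t_c},$$

is dimensionless, decreasing in $t_c$ at fixed size (softer = larger
wCDI, i.e. inversely related to the Young's modulus) and size-normalized
through $d_n^2$. Because the normalization is not perfect — wCDI retains
residual diameter dependence through $d_n^{-2}$ and through
$\varepsilon(d_n)$ in $t_c$ — group comparisons should either match the
diameter distributions between conditions or rely on large samples; the
package's own checks compare populations that differ only in softness.

### 2.4 Event detection — numerical choices

* **Smoothing.** Rectangular (boxcar) moving average over windows fully
  inside the trace, then decimation. Defaults: window 5 samples, factor 1.
  The preprocessing equals a brute-force convolution-plus-stride oracle
  sample for sample (tested).
* **Baseline.** Median of the samples in the upper half of the current
  range — pulses are downward and sparse, so the range cut excludes them.
  Re-estimated after preprocessing.
* **Noise scale.** Median absolute deviation of the full trace; robust to
  the pulses contaminating an SD estimate.
* **Threshold.** Samples below baseline − 5·MAD start a run (config
  `threshold_k`).
* **Sub-pulse segmentation.** Runs separated by a recovery shorter than
  half the preceding run are merged into one event: the node crossing is
  an order of magnitude shorter than either flanking segment, while
  separate transits are spaced much farther apart. The first run of an
  event is the sizing sub-pulse, the last is the contraction sub-pulse.
* **Depth.** $\Delta I_S$ = baseline minus the mean of the central 50% of
  the sizing run (plateau mean, not minimum), for noise robustness.
* **Edge cases.** Events touching the trace edges are dropped with a
  warning; single-run events (no contraction sub-pulse) are flagged
  `ok = FALSE` and excluded from deformability summaries.

### 2.5 Free parameters of the acquisition

The acquisition electronics are not part of the measurement definition, so
flow speed (default 1 cm/s), sampling rate (default 10 kHz) and baseline
current (default 250 nA) are free simulator parameters. The defaults give
sizing pulses of roughly 70 ms and 0.1–0.3 nA for 3–4 µm nuclei — the
scale of the published current records — and place ≥ 500 samples per
sub-pulse, far above the ≥ 20-sample floor the simulator enforces.

## 3. NE imaging

### 3.1 Ring model and sampling

`simulate_ring_image()` renders an angular intensity model — constant base,
`n_patches` von Mises bumps (patch positions uniform, amplitude equal to
the base), and one polar-cap bump — onto a circle with a Gaussian radial
profile (FWHM = `ring_width_px`). Angles are degrees in [0°, 360°),
counterclockwise from the +x image axis with y pointing down.
`sample_ring_profile()` reverses this: bilinear samples across the ring
width, averaged radially, background (image intensity mode) subtracted and
floored at 0. In the original experiments the periphery was traced by hand in an interactive
tool; the parametric circle (optionally refined by `fit_ring_center()`,
which maximizes mean ring intensity over a small search grid) replaces the
human step while measuring the same quantity.

### 3.2 Clustering index

`clustering_index()` is the coefficient of variation — sample
($n-1$) SD over mean — of the peripheral intensity. The sample SD is used
because angular sample counts are small; the choice is documented so it is
auditable. The index is invariant to intensity scaling and circular
rotation (tested properties).

### 3.3 Polarization profile

`polarization_profile()` rotates the brightest point to 180° and divides
by the value at the post-rotation 0° position, which therefore equals 1
exactly. Numerical choices:

* the argmax is found on a 5° circular moving average (raw values are used
  for normalization) so single-pixel noise cannot select the peak;
* ties are broken toward the smallest angle;
* the 0° normalization uses the single post-rotation 0° sample (the
  convention leaves open whether a local mean is used; a single sample
  keeps "value at 0° = 1" an identity);
* with `fold = TRUE`, intensities at $\theta$ and $360° - \theta$ are
  averaged onto [0°, 180°], exploiting the symmetry about the peak.

`peak_region_stat()` averages the normalized profile over the closed
170°–190° window (mapped to [170°, 180°] for folded profiles); group
comparisons of the per-nucleus statistics are delegated to the statistics
module.

### 3.4 Patch tracking

`link_tracks()` is greedy nearest-neighbour frame-to-frame linking under a
maximum displacement, after subtracting a reference drift (a per-frame
vector or a per-frame table of cumulative offsets — only the invariance
contract of drift correction is reproduced, not any proprietary
algorithm). Greedy linking suits sparse patches on a nuclear surface; a
gap parameter allows short detection dropouts. `track_mean_speed()` is
the mean 3D displacement per elapsed time; singleton tracks are `NA`.
The default frame interval in the examples is 5 s, matching the imaging
cadence used for LINC-patch mobility.

### 3.5 Volume

`segment_nucleus_volume()` thresholds the stack (global Otsu over all
voxels — a per-slice threshold would bias slices with little foreground —
or a fixed value), labels 6-connected 3D components, and multiplies voxel
counts by the voxel volume. Components touching the stack boundary are
flagged as truncated. On analytic spheres the estimate converges to
$\tfrac{4}{3}\pi r^3$ as the grid is refined (tested).

### 3.6 Collapse dynamics

"Size" of the NE and the chromosomal (SC) signal is the equivalent
diameter of the segmented object; the normalized analysis is insensitive
to this choice (diameter vs perimeter vs area changes absolute rates
only). `align_collapse_series()` sets the contact point either from an
explicit annotation — in the source experiments contact is identified in
the images, making it an input — or automatically as the first frame with
$\mathrm{NE} - \mathrm{SC} \le$ `contact_tol`. Both series are divided by
their final-frame values (final frame = 1 exactly) and time is re-indexed
relative to contact. `collapse_rates()` fits ordinary least-squares
slopes of normalized NE size against time separately before and after
contact (the contact frame belongs to both fits). To compare recovered
rates with ground truth in physical units, multiply the normalized rate by
the final-frame size — this cancels the normalization denominator exactly.

The collapse generator defaults describe a diplotene collapse: NE from
3.5 µm at −0.05 µm/frame to contact with a 1.5 µm SC at frame 41, then
−0.08 µm/frame for both (faster post-contact shrinkage), 10 s frames, 52
frames, and measurement noise of 0.07 µm (2% of the initial NE size).

## 4. Germline zone scoring

The gonad axis [0, L] is cut into equal-length zones — half-open on the
right, last zone closed, so every position belongs to exactly one zone
deterministically. Pairing is scored from HIM-8 focus counts (≤ 1 focus =
paired; zero counts score as paired but are flagged for review as likely
detection failures). Complete synapsis is scored as SYP-1/HTP-3
colocalization ≥ 0.95 (configurable; the quantification rule for
"complete" is not fixed by the source, so the threshold is a parameter,
never asserted). `zone_fractions()` reports the pooled per-zone fraction
plus the unweighted mean ± sample SD across animals (three animals per
condition in the emulated design); empty zones are reported as missing,
not zero. `compare_zone_proportions()` runs a per-zone 2×2 proportion
test — chi-square with continuity correction, or Fisher's exact test when
any expected count is below 5 — and adjusts across zones by
Benjamini-Hochberg.

For real data the "collapsed" call would come from volume and chromatin
morphology relative to neighbours; in synthetic mode the generator flag is
the ground truth, and the predicate argument of `zone_fractions()` accepts
any function of the layout so a volume-based criterion can be plugged in.

## 5. Statistics

* `bh_adjust()` — step-up Benjamini-Hochberg, implemented from the
  definition and cross-checked in the tests against `stats::p.adjust` and
  an exhaustive oracle for up to five hypotheses. Note the step-up
  adjustment is *not* idempotent (re-adjusting adjusted values rescales by
  $m/i$ again); the tested invariants are pointwise domination, capping at
  1, and order preservation.
* `welch_anova()` — Welch's heteroscedastic F* with Satterthwaite-type
  denominator df, implemented from the formulas and cross-checked against
  `stats::oneway.test`; for two groups it equals the squared Welch t
  statistic.
* `games_howell()` — pairwise comparisons with per-pair Welch df and the
  studentized-range distribution (`ptukey` with the full group count);
  validated against an independent reference implementation on a fixed
  dataset and by a familywise-error simulation under the null.
* `standard_tests()` — thin dispatch to the base-R Mann-Whitney, one-way
  ANOVA, BH-adjusted pairwise t tests, Welch t, and two-way ANOVA.
* `power_two_groups()` — exact two-sample t-test power from the noncentral
  t distribution with Cohen's d effect sizes.

## 6. What the generators emulate — and what they do not

The simulators reproduce the *statistical structure* the analysis code
must handle: pulse trains with sizing/node/contraction sub-pulses and
i.i.d. Gaussian current noise; rings with patchy (von Mises) and polarized
(cap) intensity plus pixel noise; collapse series with a rate change at
contact; layouts with zone-dependent status probabilities; detections with
common stage drift. They deliberately do **not** model: 1/f noise or
baseline drift in the current (an optional concern for real traces, where
the MAD-based threshold would need a detrending step), electrode
electrochemistry or pressure-flow profiles, particle rotation or
deformation dynamics inside the contraction segment, point-spread-function
blur, photobleaching, or nucleus-to-nucleus background variation. Passing
tests therefore demonstrate correctness of the measurement logic under
idealized noise, not robustness to every instrumental artefact.

Problem sizes used by the test-suite simulations — e.g. 40–100 transits
per trace, 101–121 px ring images, 52-frame collapse series, 600-nucleus
layouts, and $5\,000$–$10\,000$-rep statistical nulls — were chosen so
each check is decisively powered at its stated tolerance while the whole
suite stays lightweight.

## 7. Known limitations

* The wCDI formula is the package's own size-normalized index with the
  required monotonicity, not necessarily identical to the definition used
  by any particular instrument software; all conclusions the package draws
  from wCDI are ordinal, and the formula is replaceable via the `formula`
  argument without touching any other code.
* The sizing relation's constant is device-specific; absolute diameters
  should always follow a bead calibration (`calibrate_with_beads()`).
* Event detection assumes non-overlapping transits; coincident particles
  are not resolved (the simulator refuses to generate them).
* Greedy linking can swap identities when inter-particle spacing
  approaches the per-frame displacement; the tested guarantee is ≥ 95%
  link purity at spacing > 3× displacement.
* The contact-point detector is a simple threshold on NE − SC; for noisy
  real series, prefer an image-based contact annotation passed as
  `contact_frame`.
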