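---
title: "Prospective optical gating and cardiac phenotyping: models and methods"
author: "cardiogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospective optical gating and cardiac phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiogate)
```

## The problem

Laser micro-ablation of the zebrafish embryonic ventricle requires hitting a
~50 µm moving target: with the embryo on its side the atrium and ventricle
overlap in projection, and the heart beats at 2–3 Hz. The solution is
*prospective optical gating*: estimate the cardiac phase of each incoming
video frame, predict when the heart will next reach a user-chosen phase
(end-diastole, when the ventricle is at its largest and most separated from
the atrium), and fire the laser at exactly that instant. This package
implements that gating loop together with the downstream phenotyping used to
quantify the injury and its recovery: heart rate (HR), area-based ejection
fraction (EF), ventricle diastolic area (VDA), caudal-vein blood-flow
velocity (CVBF), and 3-D counts of total (VCt) and mitotic (VCm)
ventricular cardiomyocyte nuclei and TUNEL puncta in confocal z-stacks.

No public dataset accompanies this kind of experiment, so the package ships
a synthetic-data module that renders every input with exact ground truth.
All tests and the acceptance script run against those simulations.

## The gating model

**Phase estimation.** A `ReferenceSet` holds the frames of one cardiac
cycle, with phases assigned uniformly by time: frame at time $t$ within a
cycle of period $T$ carries phase $\phi = 2\pi t / T$, phase 0 at the
anchor (end-diastole). An incoming frame is compared against every
reference frame with zero-normalized cross-correlation (ZNCC),

$$ s_{j} = \frac{\sum_p (I_p - \bar I)(R_{j,p} - \bar R_j)}
  {\|I - \bar I\|\,\|R_j - \bar R_j\|}, $$

which is invariant to affine drift of the illumination. The best-matching
reference phase is refined to sub-frame resolution by fitting a parabola
through the similarity of the best match and its two circular neighbours —
standard sub-sample peak localization. Confidence multiplies the best score
by the margin over the best *non-adjacent* competitor (adjacent reference
phases are legitimately similar), so it is monotone in that margin; pure
noise scores near zero and is excluded by the confidence floor.

**Period estimation** uses the same metric across time: the mean ZNCC of
frame pairs at lag $L$ peaks when $L$ matches the period. The smallest-lag
local maximum within 5% of the global maximum is taken (a curve of a
periodic signal also peaks at every integer multiple of the period), then
refined quadratically. Flat self-similarity curves — frozen or paused
videos — raise an "aperiodic input" error rather than returning a number.

**Prediction.** Phase is locally linear in time for a steadily beating
heart, so the last $w$ confident estimates (default $w = 8$, about
two-thirds of a cycle at the standard operating point) are circularly
unwrapped and least-squares fitted: $\hat\phi(t) = a + bt$. The next
crossing of target phase $\theta$ after time $t_0$ is

$$ t^\ast = \frac{\theta + 2\pi k - a}{b}, \qquad
   k = \min \{ k : t^\ast > t_0 \}, $$

and the trigger is emitted at $t^\ast - \ell$ where $\ell$ is the
(hardware-specific, user-configured) system latency. Triggers are
*withheld*, not raised as errors, when the fitted rate falls below a slope
floor (default $2\pi/4$ rad/s, i.e. periods above 4 s — asystole or pause)
or the fit residual exceeds tolerance (arrhythmia): a safety path — firing
into a paused heart would injure whatever drifted into the beam.

**The gating loop** re-predicts at every frame and commits a trigger only
when the predicted crossing arrives before the next frame (plus a 10%
inter-frame guard, since a crossing that lands a fraction of a millisecond
past the frame boundary would otherwise be missed from both sides — the
final prediction for a crossing is the most informed one). Fires are spaced
by a refractory interval, default 60 s, matching the multi-pulse protocol
of up to 5 pulses at 1-minute intervals; tests shorten it to keep videos
small, which changes spacing, not logic.

## Functional phenotyping

**Segmentation** is deliberately simple and fully deterministic: Otsu
threshold, largest connected component, hole fill, area = pixel count
$\times$ pixel size². The threshold adapts to each frame's intensity range,
making the whole pipeline invariant to global intensity scaling. Manual
outlining (the interactive-software workflow this replaces) is not
reproducible in software tests.

**Beats** are diastolic maxima of the area signal, found by peak detection
with a minimum peak distance of 0.6 × the period (estimated from the area
autocorrelation when not supplied). Two deliberate refinements: pixel-count
areas are quantized, so a diastolic plateau of tied values is centred
rather than taking its first edge (otherwise HR inherits half-frame
jitter); and peaks within 0.3 period of the series ends are discarded —
a truncated edge beat leaves only a rasterization micro-peak that would
corrupt the first inter-beat interval. HR = 60000 / mean inter-peak
interval (ms). EF per beat uses the within-beat extrema,
$\mathrm{EF} = (A_d - A_s)/A_d \times 100$, then averages across beats —
the area-based definition, with per-beat extrema chosen for robustness to
drift. VDA is the mean per-beat $A_d$.

**Flow velocimetry** mirrors the manual frame-by-frame protocol: bright
blobs are detected per frame (Otsu + size window, intensity-weighted
centroids), linked by greedy nearest-neighbour matching with a gating
distance of 1.5 × the expected per-frame displacement, and the four longest
tracks with at least ten positions are averaged:
$v = \overline{\Delta r} \cdot \mathrm{fps} \cdot \mathrm{px}$. Net
displacement along the linked path is used (path-length vs net-displacement
is unstated in the manual protocol; for straight vessel flow they agree).

## 3-D counting

Counting runs on named-channel z-stacks (GFP myocardium, DAPI nuclei,
optional PHH3 and TUNEL). The myocardial mask is Otsu + 3×3×3 closing +
largest 3-D connected component: in isolated-heart stacks the atrium and
bulbus are disconnected satellites, so the largest-component rule is the
automatic stand-in for their manual exclusion. DAPI is thresholded inside
the mask and labeled with 26-connectivity — one label per nucleus even when
it spans several 3 µm slices, the software equivalent of tagging each
nucleus once while scrolling through the stack. Components are filtered to
a volume window derived from the configured nucleus radius ±50% (debris
below, merged blobs above; merges are reported). A counted nucleus is
mitotic when its mean PHH3 intensity exceeds threshold — colocalization by
construction, so VCm ≤ VCt always. TUNEL puncta are small 3-D components
inside the once-dilated heart region. No watershed splitting is applied by
default: the generator guarantees separations at which it is unnecessary,
and on real data it should be enabled deliberately, not silently.

3-D connected-component labeling is not available in the installed imaging
stack, so the package implements it directly: foreground voxels become
vertices of an adjacency graph (13 positive offsets for 26-connectivity)
whose connected components are the labels.

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are not tuned per
test.

* **Heart video**: 400 ms period (150 bpm, the control regime), 30 fps,
  diastolic area 10.1 × 10³ µm², EF 20%, 2.5 µm/px on a 96 × 96 field,
  additive Gaussian intensity noise σ = 0.05 (≈ 7% of the
  foreground–background contrast) as the default corruption. Area
  oscillates sinusoidally *in area* between $A_d$ and
  $A_s = A_d(1-\mathrm{EF}/100)$, so the true EF maps linearly onto the
  envelope and recovery is analytically checkable. The injury response is a
  configurable frozen pause (2–4 s) followed by a longer period
  (bradycardia), emulating the observed post-laser phenomenology.
* **Phase identifiability**: a purely area-modulated ellipse is identical
  at phases $\phi$ and $2\pi - \phi$, which would make image-based phase
  matching ill-posed by construction. Real hearts are not
  expansion/contraction symmetric, so the renderer modulates the ellipse
  aspect ratio by $1 + 0.15\sin\phi$ (area unchanged, exact): shape now
  distinguishes filling from emptying, as conformational change does in
  vivo.
* **Vessel video**: discs of 3 µm radius travel along the vessel axis at
  constant velocity (default 300 µm/s, the control flow regime) in distinct
  lanes, wrapping deterministically at the field edge; 30 fps, 1 µm/px.
* **Z-stacks**: a filled ellipsoidal "ventricle" in GFP at 3 µm z-steps,
  238 in-mask DAPI nuclei (the control-mean total count), 30 out-of-mask
  nuclei, a 2.3% PHH3-positive subset (≈ 5 mitotic nuclei, the control
  regime) and 5 TUNEL puncta (the post-injury level). Nuclei are hard-core
  sampled with a 10.5 µm minimum separation: with 1.5 × 1.5 × 3 µm voxels,
  two 2.5 µm-radius spheres can bridge across adjacent z-slices under
  26-connectivity whenever centres are closer than roughly
  $2r + \Delta z + \sqrt2\,\mathrm{px} \approx 10.1$ µm, so the default
  stays just above that geometric bound — separations the volume filter
  and (optional) watershed would otherwise have to resolve.

What the simulations do **not** model: myocardial texture, the optical
point-spread function, erythrocyte deformation, pulsatile flow, stain
background gradients, and anatomically realistic chamber shapes. Passing
tests therefore demonstrate correctness of the *algorithms* under known
conditions, not segmentation robustness on real microscopy; on real data
the segmentation and threshold configuration are the components to
re-validate first.

## Numerical choices

* Phases in radians in $[0, 2\pi)$, phase 0 at the reference anchor; time
  in ms; frames 1-indexed (R convention).
* Quadratic peak interpolation offsets are clamped to ±0.5 sample; an
  exact reference hit (ZNCC = 1) skips refinement so matching a reference
  frame returns its phase identically.
* The trigger equation is solved in closed form; a property test checks it
  against a 0.01 ms brute-force scan of the fitted phase line (agreement
  within 0.02 ms over 1000 random fits).
* Degenerate inputs fail loudly and early: EF 0 videos have no
  identifiable end-diastole (error), frozen videos are aperiodic (error),
  blank frames are segmentation errors with the frame index, infeasible
  nucleus packings are packing errors. Low matching confidence is *not* an
  error — it is reported and gated.
* The sinusoidal area model means the global extrema equal the per-beat
  extrema; on real data with drift the per-beat definition is the robust
  one.

## Problem sizes

Tests and the acceptance script use 90–400 frame videos, 100 seeded noisy
gating runs, a 5 × 4 × 2 HR/EF/noise recovery grid, 5 flow regimes, 25
noisy stack re-renders for the VCt reproducibility envelope (compared
against the ±4.5% intra-observer variation of the manual count), 2000 null
ANOVA simulations for type-I calibration, and 1000 random fits for the
trigger-time oracle. These sizes give stable estimates of every reported
quantity; all are configurable upward.

## Known limitations

* The gating realization here is one concrete implementation of the
  published idea; the original instrument's software is described in prior
  work and was not available for comparison.
* Linear phase extrapolation assumes a locally constant heart rate; it
  adapts across the sliding window but will lag abrupt rate changes
  (the residual gate withholds triggers in that case).
* Area-based EF has no volumetric correction; it is the 2-D projection
  definition, and the ellipse simulator makes the same assumption (flagged
  as a stand-in — chamber geometry behind area-based EF is unstated in the
  measurement protocol it follows).
* The repeated-measures ANOVA requires complete cells; unbalanced designs
  error out instead of silently dropping subjects.
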