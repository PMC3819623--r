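# cardiogate

Prospective optical gating and quantitative phenotyping for the beating
embryonic zebrafish heart.

Laser micro-ablation of the embryonic ventricle needs the pulse to land at
a chosen cardiac phase — end-diastole, when the ventricle is maximally
filled and clear of the overlapping atrium. `cardiogate` implements the
software side of that experiment:

* **gating** — estimate the cardiac phase of each video frame by
  zero-normalized cross-correlation against a one-cycle reference set,
  fit the phase-vs-time line over a sliding window, and predict the next
  target-phase crossing so a trigger can be emitted at `t* − latency`.
  Pauses and arrhythmic stretches produce *withheld* events, never fires.
* **cardiofunc** — heart rate (bpm), area-based ejection fraction
  `EF = (Ad − As)/Ad × 100` (%), and ventricle diastolic area (µm²) from
  automatic per-frame ventricle segmentation.
* **flow** — caudal-vein blood-flow velocity (µm/s) by erythrocyte
  detection and gated nearest-neighbour tracking (four cells over ten
  frames, as in the manual protocol).
* **cellcount** — VCt / VCm (total and mitotic ventricular cardiomyocyte
  nuclei: DAPI inside the GFP myocardial mask, PHH3-positive subset) and
  TUNEL puncta, via 3-D connected-component labeling of confocal z-stacks.
* **report** — group summaries (mean ± SEM) and one-way / two-way
  repeated-measures ANOVA with Bonferroni post-hoc comparisons.
* **synthetic data** — renders beating-heart videos (including the
  post-injury pause + bradycardia response), vessel videos and
  immunostained z-stacks with exact ground truth, so everything above is
  testable without external data.

## Worked example

```r
library(cardiogate)

# a control-regime heart: 400 ms period (150 bpm), EF 20%, VDA 10100 um^2
sim  <- simulateHeartVideo(heartSimParams(nFrames = 150, noiseSigma = 0))
sim$video
#> VideoSequence: 150 frames of 96 x 96 px | 30 fps | 2.5 um/px | 4966.7 ms span

# prospective gating at end-diastole
refs <- buildReference(sim$video, estimatePeriod(sim$video), 1, "end-diastole")
tr   <- gateStream(sim$video, refs, gateConfig(nPulses = 10, refractoryS = 0.5))
round(subset(tr, !withheld)$fire_time_ms, 3)
#> [1]  400.043 1200.043 2000.043 2800.043 3600.043 4400.043

# every fire is a true end-diastole crossing (multiples of the 400 ms
# period), spaced by the 0.5 s refractory interval; against the
# generator's ground truth the worst timing error here is 0.043 ms.

cardiacReport(sim$video)
#>   hr_bpm   ef_pct vda_um2 n_beats
#> 1    150 19.80198   10100      11
```

150 bpm, EF 19.8% and VDA 10100 µm² recover the generator's truth
(150 bpm / 20% / 10100 µm²); the 0.2-point EF gap is pixel-quantization of
the segmented area. Equivalent one-liners exist for the other assays:
`caudalVeinFlow(video)` and `countStack(scene)`.

A command-line interface wrapping these functions is installed at
`inst/cli/cardiogate.R`:

```sh
Rscript inst/cli/cardiogate.R simulate --kind heart --seed 2 --out sim.tif
Rscript inst/cli/cardiogate.R gate --video sim.tif --target end-diastole \
    --pulses 5 --refractory-s 60 --out triggers.csv
Rscript inst/cli/cardiogate.R quantify --video sim.tif --out report.csv
```

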