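# eelsonar

Automatic detection, identification and counting of anguilliform fish
(eels) in acoustic-camera video.

High-frequency imaging sonars ("acoustic cameras" such as ARIS or BlueView
units) produce video-like echo images that work in turbid or dark water,
which makes them the standard tool for monitoring silver-eel runs at
hydropower intakes and estuary channels. Reading those recordings by hand
does not scale: a migration season yields hundreds of hours of video per
camera. `eelsonar` implements a rule-based pipeline that finds elongated,
undulating targets in such video and counts them, together with the
evaluation statistics used to judge the counts against operator reference
reads and a fully ground-truthed synthetic sonar-scene generator, so every
stage is testable without field recordings.

## The method

The pipeline mirrors how an experienced operator works, stage by stage:

1. **Frame screening.** For every frame the singular values
   σ₁ ≥ σ₂ ≥ σ₃ of the frame matrix are compared with those of an empty
   reference frame: rₖ(t) = σₖ(frame t) / σₖ(reference), k = 2, 3. A
   stationary speckle background is near rank one, so σ₂ and σ₃ respond
   selectively to elongated structure crossing the field of view. Frames
   with r₂ or r₃ above a threshold form the *intervals of interest*; only
   those are processed further.
2. **Candidate detection.** A 40 mm x 30 mm mean filter, an adaptive
   Gaussian-mixture background model (variance threshold 1.5 x Ī, history
   14 x fps, where Ī is the mean intensity of the empty reference image),
   a 15 x 15 px dilation that merges fragmented echoes into one region,
   and a size filter that drops components whose fitted-ellipse major axis
   is shorter than 25% of the operator-set minimum eel length L_min.
3. **Morphology.** Per candidate: area (mm²), ellipse orientation and
   eccentricity e = √(1 − (b/a)²); body length as the geodesic length of
   the reconstructed skeleton (fragment skeletons greedily bridged across
   gaps); and the eccentricities of three k-means body sections, which
   separate a serpentine body (straight sections, curved whole) from a
   compact one.
4. **Tracking.** Frame-to-frame association inside a circle of diameter
   1.5 x L_min (radius scaled by the number of skipped frames) with an
   orientation-consistency gate θ_diff < 25°.
5. **Classification.** A track is *anguilliform* iff at least five of its
   frames pass all frame rules (length ≥ 0.40 L_min, a minimum-area rule,
   eccentricity ≥ 0.90) and the track passes the track rules (mean travel
   distance ≥ L_min/fps mm per frame, direction always along the current,
   minimum and mean eccentricity above their length-class thresholds).
   Positives are written to a detections CSV, one row per counted fish.

The evaluation module scores detections against operator reference counts
without true negatives: recall = TP/(TP+FN), precision = TP/(TP+FP),
F1 = 2RP/(R+P); *identification precision* TP/(TP+FP−FP_tracking), which
excludes duplicate-count errors; per-category FP percentages; metrics
stratified by detection range or fish length; and bootstrap regression of
automatic on reference hourly counts (100 replicates at 70%, replicate
slopes tested against the 1:1 line).

## Worked example

```r
library(eelsonar)

cfg <- recording_config(pixel_res_mm = 10, fps = 7, ref_mean_intensity = 20,
                        min_eel_length_cm = 60, window_start_m = 1,
                        window_stop_m = 3, camera_label = "synthetic")
scene <- make_scene(cfg, n_frames = 120,
                    events = list(eel_event(780, entry_frame = 10, y_px = 60),
                                  eel_event(650, entry_frame = 60, y_px = 120),
                                  fish_event(300, entry_frame = 35, y_px = 160)),
                    noise_sd = 4, seed = 42)
run <- run_pipeline(scene$sequence, pipeline_params(), video = "demo")
print(run)
#> <eel_run> 120 frames -> 81 of interest -> 99 candidates -> 5 tracks -> 2 eels

rec <- run$records[[1]]
sprintf("first eel: mean passage %.2f s, %d detections, median length %.0f mm",
        rec$mean_passage_time_s, rec$n_detections, median(rec$lengths_mm))
#> "first eel: mean passage 3.14 s, 25 detections, median length 768 mm"

report <- evaluate_detections(run$records, truth_to_reference_counts(scene),
                              time_tolerance_s = 3)
print(report)
#> <eval> TP 2 FN 0 FP 0 | recall 100.0% precision 100.0% F1 100.0%
#>   identification precision 100.0%
```

Both planted eels (780 mm and 650 mm) are screened, segmented, tracked and
classified as anguilliform — the 768 mm median recovered length is the
first eel's skeleton estimate — while the 300 mm compact fish is tracked
but rejected by the eccentricity and travel rules. The two predictions
match the generator's ground-truth pass log exactly.

A command-line front end wrapping the same functions ships in
`inst/cli/eelsonar.R` with `run`, `simulate`, `evaluate` and `tune`
subcommands; see the header of that file for usage.

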