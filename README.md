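# motomap

Quantification tools for motor-endplate-guided intramuscular tracer
injections: how much of a muscle's motor-endplate (MEP) region does the
tracer's diffusion volume cover, and how many spinal motor neurons does the
injection label retrogradely?

Retrograde tracers (such as fluorophore-conjugated cholera toxin subunit B)
enter motor axons at the neuromuscular junction, so labeling efficiency is
governed by the overlap between the tracer diffusion region and the
MEP-bearing lamella of the muscle. `motomap` implements the two
quantification pipelines of such an experiment and a synthetic-data
generator that makes both fully testable without any real acquisitions:

* **synthetic scenes** — stylized 3D MEP distributions (an "M"-shaped
  lamellar band for the gastrocnemius, a triangular-pyramid arrangement for
  the tibialis anterior), injection plans for the volumetric (**3D**) and
  surface-guided (**2D**) strategies, Gaussian tracer diffusion confined by
  the fascia, two-channel 60-µm maximum-intensity section images, and
  spinal-cord stacks of bright somata — all with exact ground truth;
* **coverage** — segmentation of the tracer channel (binarization + hole
  filling) and the MEP channel (median prefilter + binarization), and the
  coverage statistic

  ```
  coverage = |MEP ∧ CTB| / |MEP|
  ```

  the fraction of MEP-signal pixels inside the tracer region, profiled per
  section depth with an unweighted mean across depths;
* **neurons** — an open smoothed-local-maxima spot detector for 3D cord
  stacks (deterministic tie-breaking, sub-voxel centroids), soma counting,
  and rostro-caudal / medio-lateral / ventro-dorsal pool extents;
* **stats** — the gated two-group comparison used for all reported
  contrasts (Shapiro–Wilk → Levene → pooled t / Welch t / Mann–Whitney U),
  mean ± SEM summaries and percent improvement;
* **pipeline / CLI** — `run_pipeline()` chains simulation → coverage →
  neuron mapping → statistics reproducibly (TIFF/CSV/JSON/YAML artifacts,
  config hash, per-image threshold audit); `inst/cli/motomap` exposes
  `simulate`, `coverage`, `neurons`, `stats` and `pipeline` subcommands.

## Worked example

Simulate an injected gastrocnemius, section it through the endplate-bearing
depths, and measure the coverage profile:

```r
library(motomap)
scene <- generate_mep_map("gastrocnemius", n_points = 2000, seed = 7)
plan  <- make_injection_plan(scene, "3D")
field <- simulate_tracer_diffusion(plan, scene$geometry)
secs  <- render_section_images(field, scene,
                               mep_section_depths(scene, 5), seed = 7)
coverage_profile(secs)
#> <coverage_result>
#>  depth_um mep_pixels mep_pixels_in_ctb coverage tracer_threshold mep_threshold
#>      1250        300               223   0.7433          0.15523        0.4225
#>      1550        467               227   0.4861          0.16104        0.3941
#>      1950        353               233   0.6601          0.14792        0.4245
#>      2250        513               127   0.2476          0.14264        0.4285
#>      3050        119                22   0.1849          0.08646        0.4121
#> mean coverage: 0.4644
```

Each row is one 60-µm section: how many MEP pixels it contains, how many of
those fall inside the segmented tracer region, their ratio (the coverage),
and the automatically selected binarization thresholds kept for audit. The
mean across depths (0.46 here) is the per-muscle summary; rerunning with
`make_injection_plan(scene, "2D")` on the same scene gives a markedly lower
mean, the simulated counterpart of the advantage of volumetric injection
planning.

Count labeled motoneurons in a synthetic cord stack and measure the pool:

```r
cord  <- render_cord_scene(200, seed = 7)
spots <- detect_spots(cord$volume, cord$voxel_size_um)
count_neurons(spots)
#> [1] 198
pool_extent(spots)
#> <pool_extent> (minmax) R-C 2165.5, M-L 257.8, V-D 187.5 um
percent_improvement(183, 109)
#> [1] 67.89
```

198 of 200 rendered somata are recovered (two sat closer than the
detector's minimum separation), the pool extents reproduce the generator's
2200 × 260 × 190 µm box, and `percent_improvement()` shows the headline
arithmetic applied to two mean neuron counts.

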