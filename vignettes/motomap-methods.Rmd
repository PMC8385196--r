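---
title: "motomap: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motomap: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retrograde tracers injected into a skeletal muscle reach spinal motor
neurons through the motor endplates (MEPs), the neuromuscular junctions of
the muscle fibers. How many motoneurons get labeled therefore depends on how
much of the MEP-bearing region the tracer's diffusion volume actually
covers. Two injection-site planning strategies are compared throughout this
package:

* **3D strategy** — sites placed using the full volumetric MEP distribution
  of the cleared muscle (positions *and* depths follow the endplate
  lamella);
* **2D strategy** — sites placed along the MEP band visible on the muscle
  surface, all at one standard needle depth, which is all that surface
  staining can provide.

`motomap` implements the two quantification pipelines of such an
experiment — per-section tracer/MEP coverage, and 3D motoneuron counting in
cord stacks — together with a synthetic-data generator that produces both
kinds of images with known ground truth, so every stage is testable without
any real acquisitions.

## The coverage statistic

For one muscle section imaged in two channels (tracer, e.g. CTB, and MEP,
e.g. fluorescent α-bungarotoxin), both channels are binarized. The tracer
region additionally has its interior holes filled, since fluorescence
heterogeneity inside a genuinely tracer-filled region otherwise punches
spurious gaps. Coverage is then

$$
\mathrm{coverage} \;=\;
\frac{\lvert \mathrm{MEP} \wedge \mathrm{CTB} \rvert}
     {\lvert \mathrm{MEP} \rvert},
$$

the fraction of MEP-signal pixels lying inside the tracer region, computed
by elementwise mask multiplication and pixel counting. Per-muscle summaries
are the unweighted mean of the per-depth coverages. An empty MEP mask makes
the ratio undefined; `coverage_ratio()` raises an error rather than
returning 0, because 0 would assert "the tracer missed everything" where in
truth there is nothing to cover; `coverage_profile()` reports such sections
as `NA`, excludes them from the mean and warns.

Numerical choices, fixed so results are bit-reproducible:

* **Binarization.** Manual per-image thresholds (as used interactively in
  practice) are supported, but the automatic default is Otsu's criterion on
  a 256-bin histogram, applied identically to both strategies of a
  comparison. The threshold actually applied is recorded in every result
  row for audit.
* **Hole filling.** Background is 4-connected (hence foreground
  8-connected), the standard dual pairing. Filling can only turn enclosed
  background into foreground; it never removes foreground.
* **MEP prefilter.** The MEP channel is median-filtered (3×3, replicate
  padding, exact sorting-network median) before binarization to suppress
  impulse-like autofluorescence while preserving multi-pixel endplate
  puncta. No hole filling is applied to the MEP channel — endplate signal is
  punctate, not a solid region.
* **Display inversion** of binarized images is purely cosmetic and is kept
  out of every computation (`as_display()`).

## The synthetic muscle generator

The generator's purpose is to emulate the *structure* of the real data well
enough that the pipeline's behaviour on it is informative, with exact ground
truth. It is deliberately stylized; see "What the generator does not model".

**Muscle geometry.** An axis-aligned ellipsoid voxel mask (default 100-µm
voxels), extents 6×14×9 mm for the gastrocnemius and 4×12×6 mm for the
tibialis anterior (mouse-hindlimb scale). Axis order is fixed everywhere as
(depth, row, col), depth being the sectioning/needle axis.

**Endplate distributions.** Density fields on the muscle grid, normalized to
integrate to 1, from which endplate points are sampled i.i.d.:

* *Gastrocnemius (`m_sheet`)*: a lamellar band whose proximo-distal
  position and whose depth below the local surface are both modulated by a
  two-humped "M" profile across the medio-lateral axis (depth 1.2–1.5 mm
  below the surface). Crucially, the band of endplates *visible on the
  surface* is the same curve shifted proximally by `surface_offset_um`
  (default 1.5 mm): with obliquely staggered pennate fibers, the
  superficial-fiber endplates that surface staining reveals do not sit
  directly above the deep lamellar mass. This stagger is exactly the
  information a surface-guided injection lacks, and without it a simulated
  2D strategy is nearly as good as the 3D one.
* *Tibialis anterior (`triangular_pyramid`)*: density on three oblique
  planar faces descending from three shallow base vertices (0.7 mm deep) to
  a single deep apex (1.4 mm), so a surface-guided plan structurally misses
  the deep apex.

`half_thickness_um` is the nominal lamella half-width; the Gaussian profiles
use σ = half-thickness / 2.5, so ≈ 99% of sampled endplates lie within one
half-thickness of the lamella surface (the tests assert ≥ 95%).

**Injection plans.** Site counts, per-site volume (500 nl) and admissible
needle-depth ranges are fixed per (strategy, muscle):
7 sites at 1.2–1.5 mm for the gastrocnemius (3.5 µl total); 4 sites for the
tibialis anterior (2.0 µl total), of which the 3D plan places three at
0.6–0.8 mm and one at 1.3–1.5 mm while the 2D plan stays at 0.6–0.8 mm.
Within those constraints, the 3D strategy allocates sites greedily: each
site goes to the admissible voxel whose Gaussian neighbourhood (scale
`target_radius_um`, default 600 µm ≈ 1.5× the diffusion spread of one
deposit) holds the most *not-yet-covered* density, and that captured mass is
discounted before the next site. The 2D strategy places sites evenly along
the surface-visible band at the nominal mid-range depth. Naive per-voxel
density maxima were rejected for the 3D strategy: on a quasi-uniform
lamella they degenerate into tie-breaking and ignore how far a deposit
reaches.

**Tracer diffusion.** Each deposit becomes an isotropic Gaussian with
σ = `spread_um_per_500nl` × (volume/500 nl)^(1/3) (default 400 µm,
millimetre-scale diffusion regions). The fascia is a reflecting envelope:
mass outside the muscle mask is renormalized into it per site, so total
tracer mass stays proportional to total injected volume, matching the
observation that fascia confines rather than absorbs the tracer.

**Section rendering.** Sections are 60-µm maximum-intensity slabs: the
tracer channel is the slab MIP of the diffusion field, bilinearly upsampled
to 20-µm pixels; the MEP channel renders each in-slab endplate as a Gaussian
punctum (σ = 30 µm) truncated at its half-maximum contour, so the noise-free
support *is* the half-maximum truth mask. Autofluorescence is a constant
offset plus Gaussian noise and sparse impulse noise, all scaled to the
channel maximum. At 20 µm the puncta survive the 3×3 median; rendering them
at single-pixel scale makes both the median filter and Otsu collapse, which
is a property of sampling, not of the anatomy.

**Cord scenes.** Somata are sampled uniformly in an axis-aligned pool box
(defaults 2200 × 260 × 190 µm — an elongated rostro-caudal motoneuron
column) with rejection sampling enforcing a minimum centroid separation of
one soma diameter (20 µm); each soma is a 3D Gaussian blob whose brightest
voxel equals the requested peak, over Gaussian background noise; the nominal
SNR is peak/background-SD. The default voxel size is 5 µm isotropic (the
axial step of the light-sheet acquisition it emulates).

## Spot detection

`detect_spots()` is an open smoothed-local-maxima detector standing in for
closed commercial spot modules whose parameters are not publishable:
Gaussian smoothing with σ = diameter/4 per axis, candidate voxels above a
threshold (default: background median + 8 × MAD-based SD of the smoothed
volume) that are ≥ all 26 neighbours, greedy minimum-separation enforcement
(brightest first, exact ties to the lexicographically smaller voxel index,
making detection deterministic), and sub-voxel centroids as
intensity-weighted centroids of a diameter-sized window. The contract is
recovery on ground truth: at SNR ≥ 5 and separations ≥ 1.5× diameter the
tests require counts within ±2% and mean centroid error under one voxel.

Pool extents are reported per axis either as max − min (`minmax`, the
default, matching the "range" language of distribution summaries) or as the
99th − 1st percentile; which statistic a commercial package reports is not
always documented, so both are provided.

## The adaptive two-group comparison

All two-group comparisons follow one gated flow: Shapiro–Wilk normality per
group; if either group fails at α = 0.05 → two-sided Mann–Whitney U
(exact enumeration when both n < 8 and no ties; tie-corrected normal
approximation otherwise); otherwise Levene's test (mean-centred); if it
fails → Welch's separate-variance t; otherwise the pooled-variance t. The
gate α is 0.05 per group — a convention, since gate levels are rarely
printed — and all intermediate p-values are returned so the routing is
auditable. Zero-variance groups make Shapiro–Wilk undefined and are routed
to Mann–Whitney with a warning. Simulation at n = 8 per group keeps the
overall type-I error of the *composite* procedure within [0.03, 0.07] at
nominal 0.05 (asserted over 2000 null replicates); n = 8 rather than the
experiment-scale n = 4 because normality gates at n = 4 are nearly
powerless, which would make the calibration claim vacuous.

`percent_improvement(new, ref)` = 100 × (new − ref)/ref, rounded to two
decimals half-away-from-zero, the convention used for reported percentages;
reference values must be positive.

## Problem sizes used by the tests and the acceptance script

The shipped checks use: 100-µm simulation voxels and 20-µm section pixels;
2000 endplates per muscle scene; 5 sections per muscle; 20 seeds per muscle
for the strategy-ordering claim (the acceptance script uses 10); cord
stacks of ~2.2 million voxels with 200 somata, 10 seeds (script: 5); 2000
null replicates for the test-calibration claim. These sizes were chosen so
the full distribution of each statistic, not a single run, backs every
claim.

## What the generator does not model

No fiber architecture, pennation angles or real muscle outlines; no
acetylcholinesterase chemistry; no photon statistics, optics or
depth-dependent attenuation; no section deformation or registration error;
no axonal uptake kinetics — the link from coverage to labeled-neuron count
in `run_pipeline()` is the simplest proportional one. Consequently, passing
tests demonstrate that the *quantification pipeline* is correct and that
the simulated strategy ordering is a robust property of the stated
geometry; they do not certify the anatomical magnitudes of real coverage
ratios or neuron counts, which depend on data the generator does not try to
reproduce quantitatively.

## Reproducibility

Every stochastic operation takes one integer seed and owns a private RNG
stream (the global RNG state is saved and restored), so any artifact is a
pure function of (parameters, seed). `run_pipeline()` derives stage seeds
deterministically from the master seed, writes every threshold it actually
applied, and stamps its summary with the MD5 of the location-independent
configuration; identical configurations give bit-identical bundles.
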