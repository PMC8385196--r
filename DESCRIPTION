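Package: motomap
Title: Simulation and Quantification of Motor-Endplate Coverage and
    Retrograde Motor-Neuron Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well an intramuscular tracer injection
    covers the motor-endplate (MEP) region of a skeletal muscle and how many
    spinal motor neurons it labels retrogradely. Provides a synthetic-data
    generator for muscle-section and spinal-cord fluorescence scenes with
    known ground truth (lamellar 3D MEP distributions, Gaussian tracer
    diffusion contained by fascia, 60-micron maximum-intensity-projection
    section images, motoneuron pools of bright somata), segmentation of the
    tracer and MEP channels with the binary coverage-ratio statistic and its
    per-depth profile, 3D spot detection for soma counting and pool-extent
    measurement, an adaptive two-sample comparison flow (Shapiro-Wilk and
    Levene gated t, Welch t, or Mann-Whitney tests), and a reproducible
    pipeline with TIFF/CSV/JSON/YAML interfaces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
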