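Package: occupet
Title: Simulation and Kinetic Analysis of Dynamic PET Receptor-Occupancy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing dynamic PET studies of
    striatal D2-receptor occupancy with reversible tracers such as
    11C-raclopride. Provides a synthetic-cohort generator for crossover
    challenge designs (baseline and post-drug scans under two
    pre-treatments), simplified reference tissue model (SRTM) fitting by
    the basis-function method at region and voxel level, percent change in
    binding potential (delta-BP) occupancy statistics, test-retest
    reliability metrics (intraclass correlation, Wilcoxon signed-rank,
    percent variability), a digital striatum phantom with dynamic image
    rendering, voxelwise paired contrasts with (1-p) significance maps,
    and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
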