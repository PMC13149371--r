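Package: deptrack
Title: Motion-Aware Single-Cell Tracking and Crossover-Frequency
    Estimation for Frequency-Modulated Dielectrophoresis Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-lapse microscopy of cells driven by
    frequency-modulated dielectrophoresis (DEP) on circular-hole electrode
    arrays. Builds a field-of-view mask from the first frame, detects cells
    as centroid-radius states, identifies DEP-induced rapid-motion intervals
    from frame-wise mean displacement, reconstructs single-cell trajectories
    with motion-aware adaptive-ROI association, circle-IoU validation,
    multi-frame gap recovery and linear interpolation, and estimates each
    cell's DEP crossover frequency by two complementary routes: trapped-site
    intensity deviation under frequency sweeps and Clausius-Mossotti
    zero-crossing of ring-region velocities under static frequencies.
    Includes CLEAR-style tracking evaluation (MOTA, retention curves) and a
    ground-truthed synthetic DEP experiment generator (chip geometry,
    analytic field proxy, single-shell dielectric physics, rendered frames,
    corrupted detection streams) so the whole pipeline can be validated
    without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
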