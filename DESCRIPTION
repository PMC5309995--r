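Package: nucleotool
Title: Continuous Nucleosome Occupancy Analysis from Mapped Sequencing Fragments
Version: 0.1.0
Authors@R: person("nucleotool", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for MNase-seq style nucleosome occupancy analysis built on
    continuous occupancy tracks rather than discrete peak calls. Converts mapped
    reads (single- or paired-end BED) into nucleosome-sized fragments, computes
    depth-normalised windowed occupancy tracks, averages replicates and calls
    stable versus fuzzy chromatin regions by relative error, detects differential
    occupancy between two conditions with a bounded relative-change statistic,
    estimates the nucleosome repeat length from start-to-start distance
    phasograms by peak detection and linear fitting, builds feature-aligned
    occupancy matrices with artifact filtering, aggregate (meta-)profiles with
    Savitzky-Golay smoothing, and k-means cluster maps whose ordering can be
    transferred between conditions. Includes a seed-deterministic simulator of
    nucleosome-array sequencing data with planted ground truth, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
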