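Package: spinalAFI
Title: Autofluorescent Flavoprotein Imaging Analysis of Spinal Nociceptive Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of widefield autofluorescent flavoprotein imaging
    (AFI) recordings of the spinal dorsal horn. Converts raw 16-bit
    fluorescence stacks into fractional fluorescence change (dF/F) stacks,
    segments the biphasic flavoprotein transient into light and dark phases,
    and extracts per-recording response metrics (AFI intensity and area of
    excitation). Includes the statistical pipeline for treatment time-course
    experiments comparing spinal cord stimulation against sham (relative
    responses, paired before/after tests, ordinary least-squares recovery
    slopes), group comparisons of naive versus neuropathic cohorts, and
    behavioral endpoints (ascending von Frey thresholds with the 3-of-5
    withdrawal rule, hotplate latencies censored at 30 s, repeated-measures
    analysis across post-operative days). A synthetic-data module renders
    ground-truthed AFI movies and cohort tables so every stage of the
    pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
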