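Package: cosmosbranch
Title: Single-Molecule Colocalization Kinetics of Arp2/3-Mediated Actin
    Branch Nucleation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic analysis of actin filament branch nucleation by the
    Arp2/3 complex and dimeric WASP VCA activators, as measured by
    colocalization single-molecule spectroscopy (CoSMoS). Provides a
    continuous-time Markov chain simulator of the branch-formation pathway
    with a camera observation model (frame snapping, minimum detectable
    dwell, photobleaching, localization jitter, non-specific surface
    binding); classification of coincident arrival, co-release and
    diVCA-release fates with detection-efficiency and non-specific
    corrections; maximum-likelihood fitting of left-truncated exponential
    dwell-time mixtures with bootstrap errors; photobleaching correction by
    laser-power regression; derived rate constants with propagated errors;
    a Gaussian-resampled permutation test for rate-rate correlation;
    equilibrium binding isotherms (direct and competition, by exact mass
    balance); and bulk pyrene-trace barbed-end estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
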