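Package: striosync
Title: Learning-Stage Behavior and Low-Frequency Synchronization Analysis
    for Rodent T-Maze Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chronic multi-region extracellular
    recordings (posterior striatum, dorsolateral geniculate nucleus, visual
    cortex) from rats learning a T-maze visual discrimination task.
    Provides a permutation test with pointwise and globally corrected
    significance bands for families of curves, behavioral learning-stage
    identification by Ward clustering, judgment-point detection from
    left/right trajectory bifurcation, single-unit characterization
    (spike width, long-ISI proportion, RS/FS classification,
    occupancy-normalized rate maps, stimulus selectivity, spatial
    information in bits/spike), LFP band filtering with Hilbert phase,
    Morlet wavelet power and inter-regional wavelet coherence,
    amplitude-speed correlation, and spike-LFP phase locking via the
    Rayleigh statistic with Clopper-Pearson population summaries. A
    synthetic-session generator with known ground truth (learning curves,
    bifurcating trajectories, tuned and phase-modulated spike trains,
    coherence-controlled three-region LFPs) supports end-to-end recovery
    testing of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
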