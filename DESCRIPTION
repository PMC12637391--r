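Package: sepdecomp
Title: Simulation and Decomposition of Whisker-Flick Somatosensory Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale biophysical forward modeling of the rodent whisker-flick
    somatosensory evoked potential (SEP). Builds small layered cortical-column
    stand-in circuits driven by virtual thalamic fibers, simulates passive-cable
    membrane dynamics with integrate-and-fire somata and Ornstein-Uhlenbeck
    conductance noise, forward-models transmembrane currents into EEG (reciprocity
    lead fields) and laminar LFP (line-source approximation), and decomposes the
    evoked potential into per-population presynaptic, postsynaptic and pathway
    contributions by decoupled spike replay. Includes current-source-density
    estimation (standard CSD with Vaknin correction and step-iCSD), dipole-moment
    density and EEG self-consistency estimates, and P1/N1 waveform feature
    extraction with FWHM pathway attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
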