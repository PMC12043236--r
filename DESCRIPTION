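Package: vepsim
Title: Virtual Epileptic Patient Cohorts: Simulation and Evaluation of SEEG Seizure Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and evaluates virtual epileptic patient cohorts:
    whole-brain network simulation of spontaneous seizures,
    stimulation-induced seizures and interictal spikes with the Epileptor
    neural mass model and a stimulation-extended Epileptor, projected to
    stereo-EEG (SEEG) sensors through a distance- and area-based gain
    matrix. Includes a synthetic-anatomy fixture generator (parcellation
    geometry, connectomes, SEEG implantations), a biphasic pulse-train and
    point-source electric-field model for SEEG stimulation, BIDS-iEEG
    style BrainVision output, and an evaluation suite (seizure-mask
    metrics, interictal spike statistics, permutation tests) for comparing
    simulated against reference recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
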