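Package: prfmeg
Title: Forward Modeling of MEG Event-Related Fields from fMRI Population Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts millisecond-resolved MEG event-related field (ERF)
    responses from fMRI-estimated population receptive fields (pRFs). Provides
    binarized stimulus-aperture generators for pRF-mapping bar sweeps and an
    18-stimulus MEG set, 2D-Gaussian pRF models with two-gamma HRF convolution
    and coarse-to-fine fitting, stimulus-overlap prediction of cortical
    responses, lead-field (gain matrix) projection to sensor space, split-half
    cross-validated time-resolved variance-explained fitting with pooled sensor
    averages and sensor groups, a polar-angle perturbation analysis, and a
    synthetic-data generator with known ground truth so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, methods, Matrix, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
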