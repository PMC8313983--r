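Package: plscm
Title: Partial Least Squares Class-Modelling with Model Inversion and Repair Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Binary class-modelling by partial least squares regression on a
    -1/+1 coded class response (PLS-CM). Per-class probability distributions
    (normal, triangular or four-parameter beta) are fitted to the predicted
    responses and decision thresholds are solved for prescribed sensitivity
    and specificity, including the balanced threshold at which the two are
    equal. The fitted PLS model is inverted algebraically at any threshold:
    the class-model boundary is characterized as hyperplanes in the latent
    and input spaces through their null-space bases, boundary points are
    sampled and screened against Hotelling T2 and Q-residual limits and the
    training-variable domain, and discretized trajectories along the normal
    direction move a rejected object into the class-model, indicating how the
    input variables must change together. Includes a synthetic two-class
    generator so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
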