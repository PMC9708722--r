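Package: glymphnet
Title: Glymphatic DTI-ALPS, Structural Connectomes, and Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking glymphatic function, brain structural
    networks, and cognition. Computes the DTI-ALPS (Diffusion Tensor Image
    Analysis Along the Perivascular Space) index from diffusion tensor fits,
    reconstructs structural connectomes with FACT deterministic tractography
    over a parcellation, derives graph-topology measures (global/local
    efficiency, characteristic path length, clustering, small-worldness with
    degree-preserving nulls), and runs the cohort statistics layer: group
    comparisons, correlations, logistic and linear regression with collinearity
    diagnostics, and percentile-bootstrap mediation of the ALPS -> global
    efficiency -> cognition pathway. Includes synthetic diffusion phantoms
    (Stejskal-Tanner forward model, Rician noise) and cohort simulators with
    known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
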