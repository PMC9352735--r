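Package: spiralpath
Title: Encoding and Decoding of Curvilinear Self-Motion from Spiral-Space Optic Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates optic flow generated by observers travelling along
    circular paths over a dotted ground plane or through a 3D dot cloud, and
    passes it through a template-matching neural model of primate areas MT and
    MSTd: speed- and direction-tuned MT units with leaky-integrator dynamics
    and synaptic depression feed a bank of MSTd units tuned to radial, spiral,
    and concentric flow patterns ("spiral space") at a grid of preferred
    centers of motion. Sparse linear decoders (lasso with the one-standard-
    error rule) and a linear support-vector classifier recover gaze offset,
    path curvature, and path sign from the MSTd population activity. Includes
    sub-population decoding models, AIC-based model comparison, bootstrap
    error estimates, and regression-weight tuning summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
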