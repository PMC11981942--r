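Package: cortexcore
Title: Dynamic Encoding Models of Mouse Visual Cortex with Transferable
    Recurrent Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and interrogates dynamic encoding models of
    mouse visual cortex at desk scale. The model comprises four modules: a
    gaze-corrected perspective front-end (azimuthal-equidistant retinal ray
    tracing through a monitor plane), a behavioural modulation LSTM, a
    recurrent convolutional core (causal 3D-convolution DenseNet feeding
    Conv-LSTM cells, with an optional convolutional-transformer variant),
    and factorized per-neuron readouts trained under a Poisson likelihood.
    Includes frozen-core transfer to new sessions, noise-ceiling-corrected
    evaluation (CC_norm), parametric stimulus generators (directional pink
    noise, Gabor trials, Gaussian dots, kinematograms), in-silico
    orientation/direction/spatial tuning estimation, readout-barcode
    classification with nested cross-validation, and a ground-truth
    simulator of recording sessions so that every analysis is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    glmnet,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
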