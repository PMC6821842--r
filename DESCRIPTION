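Package: facespace
Title: Face-Space Geometry of Intracranial Recordings and Convolutional Network Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the representational geometry of face-selective
    intracranial EEG responses with the layer-wise activation geometry of deep
    convolutional networks. Implements high-frequency amplitude (HFA) estimation by
    multi-band Hilbert envelopes, screening of visually responsive and face-selective
    contacts, exemplar selectivity indices, greedy template-matching decoding of face
    exemplars, representational similarity analysis across network layers with
    permutation and FDR inference, Fisher-z weighted pooling across stimulus sets,
    low-level image-parameter controls and partial correlations, image manipulation
    impact tests, leave-one-out search for single model units predicting single
    contacts, and receptive-field visualization by deconvolution and activation
    maximization. Ships a synthetic-data generator (task protocols, procedural face
    stimuli, forward-modelled recordings, layer-activation stacks, toy convolutional
    networks) with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    pracma,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
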