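Package: olfconn
Title: Quantitative Analysis of Olfactory Projection-Neuron Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of neuron skeletons and polyadic
    chemical synapses in the insect olfactory system. Builds probabilistic
    glomerulus atlases from 3D Gaussian kernel density estimates and scores
    fractional dendritic innervation; classifies projection neurons into uni-
    and multiglomerular groups from sorted innervation traces; splits neurons
    into axon and dendrite with centrifugal synapse flow centrality and
    quantifies polarization with an entropy-based segregation index; predicts
    connectivity from morphology with overlap scores, potential contact sites
    and presynapses-within-range; and analyses weighted directed synapse
    graphs with weighted reciprocity, local reaching centrality and modularity
    community detection. Includes a parameterized synthetic-brain generator
    with planted ground truth so every stage can be validated without
    electron-microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
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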