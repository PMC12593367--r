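Package: crystalgch
Title: Adapted Similarity Kernels and Generalized Convex Hull Analysis for
    Molecular Crystal Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing crystal structure prediction landscapes of
    molecular crystals. Implements SOAP atomic-environment power spectra, the
    analogous-atom adapted global similarity kernel (restricting atom-atom
    comparisons to atoms equivalent under the molecular point group) alongside
    the conventional average kernel, kernel principal component analysis,
    generalized convex hull construction with dressed energies, candidate-pool
    selection with energy-noise resampling, descriptor interpretability
    scoring (density regression, linear support-vector classification of
    structural classes), and lattice-energy prediction by Gaussian process
    regression over precomputed kernels. Includes a synthetic-landscape
    generator so every stage can be exercised without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    e1071,
    boot,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
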