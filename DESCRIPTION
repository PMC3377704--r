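Package: netcompress
Title: Lossless Power-Graph Compression as a Structure Statistic for
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Losslessly compresses undirected interaction networks into
    power graphs, in which cliques, bicliques and stars are abstracted
    into single power edges, and uses the achieved edge reduction --
    normalized against an ensemble of degree-preserving randomly rewired
    networks -- as a quality and structure statistic. Includes
    Erdos-Renyi and degree-biased edge/node noise models for
    false-positive and false-negative simulation, confidence-score
    slicing of scored networks, clique removal, power-edge motif
    spectra, annotation assortativity with a randomized baseline, and a
    synthetic generator of networks with planted motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
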