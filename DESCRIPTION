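Package: traitnet
Title: Plant Trait Networks and Trait Comparisons Along Elevation Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trait-based comparison of spring ephemeral and
    non-ephemeral understory herbs along an elevation gradient: importance
    values from quadrat surveys, normality-gated two-group trait tests and
    PCA, linear models of traits on plant type, elevation and their
    interaction, Blomberg's K phylogenetic signal with a tip-shuffle
    permutation null, and thresholded Spearman plant trait networks with
    degree, edge density, modularity and relative-importance statistics.
    Includes a synthetic-data generator with known ground truth (planted
    phylogenetic signal, correlated trait modules, group offsets and
    elevation slopes) so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    withr,
    mclust,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
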