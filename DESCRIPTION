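Package: interactomr
Title: Disease Interactome Modules, Network Proximity, Colocalisation
    and Mendelian Randomisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying genetic and network-level commonality
    between two complex traits. Partitions protein-protein interaction
    networks into functional modules by molecular complex detection
    (MCODE), Markov clustering (MCL) and fast-greedy modularity, selects
    the partitioning method by minimum network structure entropy and
    identifies each disease's main module; quantifies the topological
    relationship of two target sets via closest network distance, the
    separation score s_AB and a degree-preserving permutation z-score;
    filters cross-trait shared SNPs with CPASSOC-style S_Hom/S_Het
    statistics and PLINK-style clumping; performs Bayesian colocalisation
    (posterior probabilities PPH0-PPH4); and runs two-sample univariable
    and multivariable Mendelian randomisation with IVW, MR-Egger,
    weighted median, weighted mode, Cochran's Q, leave-one-out and
    MR-PRESSO sensitivity analyses. Includes synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
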