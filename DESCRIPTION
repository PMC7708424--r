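Package: proxyNet
Title: Network and Pathway Expansion of Genetic Disease Associations
    Against Clinical Drug-Target Outcomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates whether network and pathway expansion of
    high-confidence genetic disease associations retrieves clinically
    successful drug targets. Implements guilt-by-association proxy gene
    expansion over protein complexes, ligand-receptor pairs, interactome
    neighborhoods and pathway topology; insulated heat diffusion
    (random walk with restart) with permutation-calibrated module
    extraction; sum-of-chi-squared gene scores with a weighted
    chi-squared null driven by LD eigenvalues, gene fusion and empirical
    pathway enrichment; and Haldane-corrected stratified
    Cochran-Mantel-Haenszel enrichment of proxy genes among succeeded
    versus clinically failed drug targets. A synthetic-world generator
    emulates the statistical structure of the required inputs
    (scale-free interactome, planted disease modules, colocalization
    records, hub-biased trial outcomes, LD-correlated variant
    statistics) so the full pipeline runs end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
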