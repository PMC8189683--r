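Package: genecontext
Title: Gene Neighbourhood Conservation Analysis and Visualization
Version: 0.1.0
Authors@R: person("Genecontext", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyse conservation of gene neighbourhoods across annotated
    prokaryotic genome assemblies. Given a list of query protein accessions
    and locally stored assemblies (RefSeq-dialect GFF3 annotation plus
    protein FASTA), the package locates each query gene, extracts a fixed
    number of flanking genes on either side, clusters all
    neighbourhood-encoded proteins into homologous groups by single-linkage
    over significant pairwise similarity (a built-in Smith-Waterman scorer
    or an external iterative profile search), and renders the conservation
    pattern as a to-scale SVG gene-arrow diagram, a tab-separated legend
    table, and a phylogenetic tree annotated with colour- and number-coded
    pennant flags. A deterministic fixture generator produces synthetic
    assemblies with planted homologous families so that every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    phangorn,
    grDevices,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    withr
Config/testthat/edition: 3
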