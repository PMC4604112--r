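Package: chemorep
Title: Chemosensory Receptor Gene Repertoire Mining from Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines chemosensory GPCR gene families (olfactory receptors, trace
    amine-associated receptors, vomeronasal and taste receptors, and the
    gustducin alpha-subunit) from draft genome assemblies. Provides a
    translated seed-and-extend homology search with Karlin-Altschul e-values,
    merging of same-orientation hits, reciprocal best-hit family filtering,
    frameshift-aware reconstruction of candidate coding sequences, and
    classification of each locus as intact, truncated or pseudogene from
    premature stop codons, frameshifting indels, complete loss of
    transmembrane regions, and scaffold-edge context. Multi-exon genes are
    audited for exon loss and genomic inversion via exon presence maps and
    windowed-identity dot plots; olfactory receptors are placed into class I
    or class II on neighbor-joining trees; pairwise dN/dS and in-silico PCR
    with degenerate primers round out the toolkit. A synthetic-genome
    simulator with planted truth tables makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
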