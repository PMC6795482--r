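Package: centrokaryo
Title: Karyotype Evolution and Centromere Repositioning Inference from
    Annotated Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct karyotype evolution from annotated genome
    assemblies: calling pericentromeric heterochromatin boundaries and interior
    paleocentromere islands from windowed repeat-density and H3K9me3 tracks,
    discovering centromere-associated tandem satellites and decomposing
    higher-order repeat units, mapping one-to-one orthologs by reciprocal best
    hits, detecting ancestral pericentromere 'seed regions' as clustered
    ortholog runs, and classifying centromere transitions between species
    (conserved, pericentric inversion, repositioning, fusion). A synthetic
    multi-species karyotype simulator with logged evolutionary events provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
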