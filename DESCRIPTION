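Package: psychrocomp
Title: Comparative Genomics of Cold-Adapted Marine Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for comparative-genomics inference of cold and
    marine adaptation in bacterial genome collections: all-vs-all protein
    similarity with an affine-gap local aligner and Karlin-Altschul E-values,
    reciprocal-best-hit orthology and nested core/clade/pair/strain-specific
    CDS partitioning, taxonomy-rule lateral gene transfer calling against a
    reference panel, proteome amino-acid composition and GC-content statistics
    with cold-versus-warm group contrasts (Welch t-tests), Kimura
    two-parameter distances with neighbor-joining trees and bootstrap support,
    and a seeded synthetic genome-collection generator with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
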