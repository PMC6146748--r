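Package: halomag
Title: Post-Binning Ecological Genomics of Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-binning analysis of metagenome-assembled
    genomes (MAGs) from hypersaline and soda-lake sediment communities:
    quality tiering from completeness/contamination estimates, fragment-based
    average nucleotide identity (ANI) and conserved-DNA species delineation,
    read-recruitment abundance normalised as reads per kilobase of genome per
    gigabase of mapped reads (RPKG), a rank-based salinity-preference score,
    proteome isoelectric-point profiling for detecting acid-shifted ("salt-in")
    proteomes, and KEGG-Orthology marker screening for pathway presence
    (Wood-Ljungdahl and related). A synthetic-data module generates genomes,
    divergent genome pairs, community read sets, proteomes and annotation
    tables with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
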