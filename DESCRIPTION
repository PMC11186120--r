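Package: ssrmine
Title: Prime-Encoded Mining of Micro- and Minisatellites with Coding-Region
    and Group-Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects perfect simple sequence repeats (SSRs, microsatellites)
    and minisatellites in nucleotide sequences by encoding bases as prime
    integers and scanning runs of equal sliding-window products, removes
    cross-motif redundancy, merges nearby tracts into compound SSRs, reads
    FASTA and GenBank inputs, intersects repeats with CDS features to build
    coding-SSR tables, counts per-gene SSR abundance across genome cohorts,
    and screens for group-differential repeat polymorphism with
    Shapiro-Wilk, Kruskal-Wallis, ANOVA and Tukey tests. Includes a
    synthetic-genome generator with planted repeats for end-to-end
    validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
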