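Package: seroscan
Title: Classification and Modular Annotation of Lepidopteran Seroin Silk Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based analysis of seroins, the small secreted silk-gland
    proteins of Lepidoptera. Classifies proteins into the three seroin
    classes (Sn1, Sn2, Sn3) from explicit diagnostic rules, detects the
    signal peptide and segments mature proteins into alternating
    charged/Ala-Ser-Glu-Asp-rich B modules and Pro-rich C linkers, calls
    splice versions from module presence, groups same-species isoforms into
    genes, builds and parses seroin nomenclature, summarizes within- and
    between-class similarity with a neighbor-joining sanity tree, and
    counts class-specific reads by six-frame translated local alignment
    under Karlin-Altschul E-value statistics. Ships a ground-truthed
    synthetic seroin generator so the whole pipeline is exercisable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
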