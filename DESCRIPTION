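Package: bxbtag
Title: Design and In Silico Validation of Bxb1-Mediated CRISPR Knock-In Tagging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing protein-tagging knock-ins that combine
    CRISPR-Cas9 homology-directed repair of an attP-bearing single-stranded
    oligodeoxynucleotide (ssODN) with Bxb1 serine-integrase cassette delivery.
    Provides a registry of attachment-site variants with heterotypic
    compatibility rules, an in-silico recombination engine (single-circle
    integration and dual-cassette exchange with backbone excision), an ssODN
    designer with reading-frame spacer arithmetic and sgRNA re-cutting checks,
    donor-plasmid validation and Type IIS excision/circularization, predicted
    allele-set construction with fusion open-reading-frame verification, a
    long-read allele classifier with alignment-score assignment and reporting,
    and a deterministic synthetic-fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
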