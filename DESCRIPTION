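Package: anatomap
Title: Lexical Mapping of Anatomical Annotation Terms to Anatomy Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating how well free-text anatomical annotation
    terms map lexically onto anatomy ontologies. Reads OBO flat files and
    builds a searchable lexical index over labels and synonyms; normalizes
    curated annotation terms (species-name stripping, whitespace and
    punctuation unification, case folding, British-to-American spelling);
    matches terms exactly and phonetically via a Double Metaphone encoder,
    with optional singular/plural, adjectival, and shorthand variant stages;
    decomposes composite annotations ("liver/kidney", "bone marrow, flushed
    from femur") into components matched as cross-products; and scores
    outcomes against a curated gold standard with confusion matrices,
    precision, recall, and coverage. A synthetic-corpus generator produces
    toy ontologies and corrupted annotation lists with known gold mappings
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
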