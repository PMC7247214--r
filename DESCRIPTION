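Package: polyqevo
Title: Evolutionary Stability Analysis of Polyglutamine Regions in Ortholog Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polyglutamine (polyQ) regions in aligned sets of
    orthologous proteins with the 4-in-6 glutamine density rule, classifies
    each alignment column by glutamine conservation, and assigns every
    orthologous polyQ region one of five evolutionary stability categories
    (stable, inserted, mutated, undefined, uncategorized). Downstream
    profilers compute CAG/CAA glutamine codon usage per region and category,
    leucine/proline flanking-context profiles, aggregation of externally
    predicted secondary structure around the repeats, and high-confidence
    protein-protein interactor counts from STRING-style links tables.
    Includes a synthetic ortholog-set generator that plants ground-truth
    categories, codon-usage fractions, context enrichments and interactor
    distributions for end-to-end validation, and a pipeline driver that runs
    every stage over a directory of alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
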