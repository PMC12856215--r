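Package: clipsplice
Title: CLIP Binding-Site Enrichment at Differential Alternative Splicing Events
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links splicing-factor binding sites from replicated CLIP-seq
    experiments to differential alternative-splicing events called from
    RNA-seq. Provides BED-convention genomic-interval algebra, three
    replicate-consensus recipes for PAR-CLIP, HITS-CLIP and FLASH-CLIP
    interval files, rMATS-dialect splice-event tables with significance
    filtering and splicing-associated region extraction, a strand-specific
    feature-type-preserving permutation test with Monte Carlo p-values,
    condition-dependency set logic for differential expression and splicing
    gene networks, qPCR cycle-threshold statistics (delta-Ct expression,
    exon inclusion/exclusion ratios, percent enrichment of input), and a
    synthetic-data generator so the whole pipeline is testable without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
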