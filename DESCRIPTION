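Package: trnaswitch
Title: tRNA m1A58 Quantification and Synonymous Codon-Switch Design
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying translational control by the tRNA
    N1-methyladenosine modification at position 58 (m1A58). Provides a tRNA
    reference model with T-loop motif localisation and codon-anticodon
    decoding rules, a synthetic tRNA-seq pileup generator with a reverse
    transcription misincorporation/stop error model and known m1A58
    stoichiometry, estimation of per-tRNA m1A58 levels and wild-type versus
    knockout deltas with sensitivity ranking, codon usage profiling of coding
    sequences, and automated synonymous codon-switch redesign of a CDS that
    replaces codons decoded by modification-sensitive tRNAs with codons
    decoded by insensitive tRNAs while preserving the protein exactly.
License: MIT + file LICENSE
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
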