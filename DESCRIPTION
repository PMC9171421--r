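Package: orfdominance
Title: ORF Dominance and Protein-Coding Potential of Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enumerates open reading frames (ORFs) in the three forward
    reading frames of transcript sequences and computes the ORF dominance
    score, the fraction of the longest ORF in the summed length of all
    putative ORFs. Provides the derived population-level statistics for
    labeled coding/noncoding transcript sets: binned relative-frequency
    distributions, the protein-coding potential F(x) with its linear fit,
    histogram overlap scores, and the per-bin frequency of negatively
    selected transcripts from Ka/Ks tables. Includes uniform-random and
    shuffle null-sequence controls, a labeled synthetic fixture generator,
    a viral ORF score for annotated (+)ssRNA genomes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
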