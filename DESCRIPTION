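Package: readthroughx
Title: Functional Translational Readthrough Analysis of Stop Codon Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing functional translational readthrough of
    eukaryotic transcripts. Extracts stop codon contexts (SCCs) and
    downstream readthrough extensions from transcript sequences, fits a
    positional linear-regression readthrough-propensity (RTP) model and
    derives the high-readthrough consensus motif, scores hidden C-terminal
    peroxisomal targeting signals (PTS1) in readthrough extensions with a
    position-weight-matrix model, ranks candidate transcripts by the
    RTP x PTS1 product score, quantifies readthrough from dual-reporter,
    western-densitometry and peroxisomal-import measurements, and
    identifies the amino acid incorporated at the stop codon from peptide
    mass-spectrometric evidence (variant proteoform databases, in-silico
    tryptic digestion, ppm precursor and b/y fragment-ion matching).
    Includes seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
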