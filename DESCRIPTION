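Package: msdinmine
Title: Genome-Guided Discovery of MSDIN Cyclic Peptides in Amanita
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptidogenomics toolkit for the MSDIN gene family of lethal
    Amanita mushrooms. Mines precursor peptides (leader / core / recognition)
    from protein or six-frame-translated genome sequences, enumerates
    candidate cyclic-peptide species over posttranslational modification
    states (hydroxylation, sulfoxidation, tryptathionine bridge) and adducts,
    matches theoretical masses against MS1 peak lists at ppm accuracy,
    annotates MS/MS spectra with y-, b- and immonium ions to confirm core
    sequences, and ships a seeded synthetic-data generator (genomes,
    transcriptomes, MS1/MS2 peak lists) so the whole pipeline runs and tests
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
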