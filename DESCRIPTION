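Package: champtools
Title: In Silico Terminomics with Charge-Based Terminal Peptide Isolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for protein terminomics analysis built around one-step
    chromatographic isolation of terminal peptides (CHAMP-N, CHAMP-NC and
    CHAMP-C). Provides in-silico protease digestion (LysargiNase, trypsin,
    V8/Glu-C) with missed cleavages and semi-specific N-terminal-free
    expansion, a charge/orientation retention model for strong cation
    exchange and a carboxylate rule for metal-oxide ligand exchange,
    annotation of neo-N-termini (acetylation classes, signal/transit
    peptide cleavage-site matching, near-cognate start codons,
    exopeptidase ladders), summary metrics (intensity-based selectivity,
    Z distributions, replicate RSD, method and fraction overlaps), and a
    fully seeded synthetic-study generator with exported ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
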