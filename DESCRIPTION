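Package: allodyn
Title: Allosteric Site Ranking from Dynamical Correlations in Receptor Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate allosteric sites in G protein-coupled
    receptors (GPCRs) from conformational ensembles.  A collective
    activation variable (the difference between the TM2-TM6 and TM3-TM7
    C-alpha distances) is computed per frame, every inter-residue C-alpha
    distance is correlated with it across the ensemble, and candidate
    binding sites are scored by the mean absolute coupling of their
    internal distances and ranked.  Includes readers for multi-model PDB
    ensembles and Mdpocket/fpocket dummy-atom output, a C-alpha elastic
    network generator of harmonic conformational ensembles, and a
    synthetic two-state toy-receptor generator with planted coupling
    signal for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
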