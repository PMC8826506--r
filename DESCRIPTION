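Package: t1revo
Title: Functional and Phylogenetic Analysis of T1R Taste Receptor Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for heterologous-expression assays of
    T1R1-T1R3 taste receptors and their evolution across hummingbirds.
    Calls receptor agonists from plate-luminescence records (Welch
    one-tailed tests against untransfected controls with Holm step-down
    correction), builds sucralose-normalized response profiles, fits
    Hill dose-response curves, tests sugar-amino-acid synergy against an
    additive-response proxy, computes a sugar-versus-amino-acid response
    index and reconstructs its ancestral states under Brownian motion on
    a dS-scaled phylogeny, runs phylogenetic PCA, screens ancestral
    sequence differences with a three-criterion (radical / BLOSUM62 /
    conservation) filter to nominate chimeric-receptor residues, and
    compares drinking-bout length distributions with two-sample
    Kolmogorov-Smirnov tests. A synthetic-data module generates every
    input with known ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
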