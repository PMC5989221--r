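Package: replidyn
Title: Stochastic Replication Kinetics and Evolution of Origin Repertoires in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure, model and compare temporal programs of genome
    replication across yeast species. Builds mean replication time (Trep) and
    marker frequency analysis (MFA) profiles from windowed sequencing counts,
    calls active replication origins from second-derivative peaks co-detected
    in both profiles, fits a one-dimensional nucleation-growth model of
    stochastic origin firing to time-course copy-number data (firing rates,
    fork speed, simulation-based efficiencies), compares timing programs
    between genomes through synteny-based projection with randomized-offset
    nulls, assembles cross-species families of orthologous origins with a
    constrained positional randomization null, reconstructs origin gain/loss
    history on a rooted species tree by weighted parsimony, and computes
    physical and functional property statistics of conserved, gained and lost
    origins. A synthetic-data generator produces all inputs with known ground
    truth: single-cell replication kinetics, windowed read counts for
    time-course and MFA designs, and multi-species origin repertoires evolved
    along a phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
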