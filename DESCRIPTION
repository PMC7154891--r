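Package: gcstar
Title: Non-Stationary GC Content Evolution on Phylogenies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood fitting of non-homogeneous, non-stationary
    nucleotide substitution models in which each branch class of a fixed
    rooted phylogeny has its own equilibrium GC content (GC*, the theta
    parameter of a Tamura-92-type model), with discrete-gamma rate
    heterogeneity, optional invariant sites and a free root composition.
    Includes a hierarchical model ladder compared by likelihood-ratio
    tests, reconstruction of ancestral GC content at nodes and GC* along
    branches, organellar genome feature extraction (GC content, non-coding
    fraction, maximal exact repeats of all four orientations), and
    phylogenetically independent contrasts ("crunch"), PGLS and mediation
    tests over genome features. Synthetic-data generators simulate
    alignments under the branch-class model, Brownian-motion trait sets
    with planted mediation chains, and annotated genomes with planted
    repeats, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, seqinr, stats, utils
Suggests: testthat (>= 3.0.0), withr, Matrix, phangorn, nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
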