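Package: gapadj
Title: Ancestral Genome Reconstruction from Gapped Adjacencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synteny-based reconstruction of ancestral gene orders on a
    species phylogeny. Conserved relations between markers are scored as
    gapped adjacencies (pairs of signed genes separated by a bounded number
    of marker extremities), a dynamic program over the species tree computes
    the maximum achievable conservation of each candidate adjacency over all
    ancestral labelings, and Contiguous Ancestral Regions (CARs) are
    assembled by an iterative threshold-filtered traveling-salesman chaining
    of CAR extremities. The evolutionary model supports rearrangements,
    gene losses and whole-genome duplications (WGD); single-child WGD nodes
    in the tree carry pre-duplication genomes. Includes a genome
    rearrangement simulator (inversions, translocations, fusions, fissions,
    losses, WGD) and evaluation metrics comparing inferred CAR sets with a
    known ancestor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
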