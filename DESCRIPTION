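Package: dcjmetric
Title: Genomic Distances with Unequal Gene Content under the Double Cut and Join Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compute genome rearrangement distances between signed,
    multichromosomal genomes with unequal marker content and no duplicated
    markers.  The package builds the labeled adjacency graph of two genomes,
    derives the classical DCJ (double cut and join) distance and tight
    component-wise upper bounds for the DCJ-indel and DCJ-substitution
    distances from run counts and their indel/substitution potentials, and
    implements an a-posteriori metric correction m(A,B) = d(A,B) + k*u(A,B)
    that restores the triangle inequality by surcharging content-modifying
    operations per affected marker.  Brute-force search oracles (exact
    weighted sorting distance, in-component optimal-DCJ sorting, exhaustive
    triple scans) validate the closed-form potentials and the minimal
    surcharge constants at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
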