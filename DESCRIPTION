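Package: bpgeom
Title: Base-Pair Geometry, Hydrogen-Bond Networks and Hoogsteen
    Classification for DNA Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Occupancy-aware analysis of nucleic-acid crystal structures:
    reads PDB/mmCIF coordinates, expands alternate-location groups into
    single-conformer models, computes per-nucleotide and per-pair geometric
    parameters (glycosidic torsion and syn/anti state, base reference
    frames, lambda pivot angles, C1'-C1' distance, shear and companion
    pair parameters), enumerates direct, bifurcated and water-mediated
    hydrogen bonds and ion coordination shells, measures pi-pi and
    methyl-pi stacking, and classifies base pairs into Watson-Crick,
    asymmetric Watson-Crick, cis Watson-Crick/Hoogsteen (direct or
    water-mediated) and non-canonical geometries.  Includes a generator
    of idealized B-form duplex fixtures with controllable pair
    parameters, altloc/occupancy plans, bridging waters and noise, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
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
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
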