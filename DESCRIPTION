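Package: ufsrat
Title: Ultra-Fast Shape Recognition with Atom Types for Ligand-Based
    Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free 3D molecular similarity screening using
    typed-atom distance-distribution moments. Each molecule is encoded
    as 48 descriptors: the mean, variance and skew of Euclidean distance
    distributions from four reference points, computed for four atom
    channels (all heavy atoms, hydrophobic, hydrogen-bond acceptor and
    hydrogen-bond donor). Includes MDL SD/SDF V2000 reading and writing,
    a configurable atom-typing rule table, a 0-1 similarity score with
    per-channel weights, a compact one-file binary descriptor database
    with linear-scan top-N retrieval, a Lipinski drug-likeness filter,
    an enrichment-factor benchmark harness for labelled active/decoy
    libraries, and a deterministic synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    jsonlite,
    withr
Config/testthat/edition: 3
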